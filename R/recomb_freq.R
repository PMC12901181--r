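# Quantification layer of the in vivo recombination assay: per-replicate
# excision/insertion frequencies from colony-PCR counts (the analysis unit
# is the per-replicate proportion k/n, not pooled counts), pairwise
# Welch's t-tests, and significance letter groups.

#' Build a validated assay replicate table
#'
#' @param construct_id Construct label (one per table).
#' @param event_type `"excision"`, `"insertion_5p"` or `"insertion_3p"`.
#' @param k_positive Integer vector: colonies with the event-specific
#'   band, one entry per replicate.
#' @param n_colonies Colonies screened per replicate (default 30;
#'   recycled against `k_positive`).
#' @return Data frame with one row per replicate.
#' @export
assay_replicates <- function(construct_id, event_type, k_positive,
                             n_colonies = 30L) {
  event_type <- match.arg(event_type,
                          c("excision", "insertion_5p", "insertion_3p"))
  k <- as.integer(k_positive)
  n <- as.integer(rep_len(n_colonies, length(k)))
  if (any(n < 1L)) stop("n_colonies must be >= 1")
  if (any(k < 0L | k > n)) {
    stop("k_positive must satisfy 0 <= k <= n_colonies")
  }
  data.frame(
    construct_id = construct_id, event_type = event_type,
    replicate = seq_along(k), n_colonies = n, k_positive = k,
    stringsAsFactors = FALSE
  )
}

#' Read an assay replicate table from CSV
#'
#' Expected columns: `construct_id`, `event_type`, `replicate`,
#' `n_colonies`, `k_positive`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_assay_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "event_type", "replicate", "n_colonies",
            "k_positive")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("assay CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(d$k_positive < 0 | d$k_positive > d$n_colonies)) {
    stop("k_positive must satisfy 0 <= k <= n_colonies")
  }
  d
}

#' Estimate a recombination frequency from replicates
#'
#' Mean and sample standard deviation (n-1 denominator) of the
#' per-replicate proportions k/n.
#'
#' @param replicates Data frame from [assay_replicates()] (one construct,
#'   one event type, at least two replicates).
#' @return Object of class `frequency_estimate`: `mean`, `sd`,
#'   `n_replicates`.
#' @examples
#' reps <- assay_replicates("aadB", "excision", c(24, 21, 27))
#' estimate_frequency(reps)
#' @export
estimate_frequency <- function(replicates) {
  if (nrow(replicates) < 2L) {
    stop("need at least 2 replicates to estimate mean and SD")
  }
  if (length(unique(replicates$construct_id)) != 1L ||
      length(unique(replicates$event_type)) != 1L) {
    stop("replicates must come from a single construct and event type")
  }
  p <- replicates$k_positive / replicates$n_colonies
  structure(
    list(construct_id = replicates$construct_id[1],
         event_type = replicates$event_type[1],
         mean = mean(p), sd = stats::sd(p), n_replicates = length(p)),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("%s %s: %.3f +/- %.3f (n = %d)\n", x$construct_id,
              x$event_type, x$mean, x$sd, x$n_replicates))
  invisible(x)
}

#' Welch's two-sample t-test on replicate frequencies
#'
#' Wraps [stats::t.test()] with unequal variances (Welch), adding the
#' explicit degenerate definitions the assay data require: when both
#' samples have zero variance the test statistic is undefined, so equal
#' means yield `t = 0, p = 1` and unequal means are flagged degenerate
#' (`p = 0` with a warning) -- the saturated 100%-vs-100% comparisons
#' fall in the first case.
#'
#' @param a,b Numeric vectors of per-replicate frequencies (each of
#'   length >= 2).
#' @return List with `t`, `df`, `p` and a `degenerate` flag.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  degenerate = TRUE))
    }
    warning("both samples have zero variance with unequal means: ",
            "Welch's test is undefined; reporting p = 0")
    return(list(t = if (mean(a) > mean(b)) Inf else -Inf,
                df = NA_real_, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Pairwise Welch's t-test p-value matrix
#'
#' @param groups Named list of numeric vectors (per-replicate
#'   frequencies, one entry per construct).
#' @param adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] over the pairwise p-values (default `"none"`,
#'   matching the plain pairwise reading; `"holm"` available).
#' @return Symmetric matrix of p-values (diagonal 1).
#' @export
pairwise_welch <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  stopifnot(k >= 2L, !is.null(names(groups)))
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  idx <- utils::combn(k, 2)
  pv <- apply(idx, 2, function(ij) {
    suppressWarnings(welch_t_test(groups[[ij[1]]], groups[[ij[2]]])$p)
  })
  pv <- stats::p.adjust(pv, method = adjust)
  for (c in seq_len(ncol(idx))) {
    p[idx[1, c], idx[2, c]] <- pv[c]
    p[idx[2, c], idx[1, c]] <- pv[c]
  }
  p
}

#' Significance letter groups from a pairwise p matrix
#'
#' Constructs share a letter iff no pair within the lettered set is
#' significant at `alpha`; letters are the maximal cliques of the
#' non-significance graph, ordered deterministically by their smallest
#' construct index, so a construct straddling two groups gets both
#' letters (e.g. `"ab"`).
#'
#' @param pairwise_p Symmetric p-value matrix (e.g. [pairwise_welch()]).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter assignments.
#' @export
group_letters <- function(pairwise_p, alpha = 0.05) {
  stopifnot(is.matrix(pairwise_p),
            nrow(pairwise_p) == ncol(pairwise_p))
  k <- nrow(pairwise_p)
  nms <- rownames(pairwise_p)
  if (is.null(nms)) nms <- paste0("c", seq_len(k))
  if (k == 1L) return(stats::setNames("a", nms))
  adj <- pairwise_p >= alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  ord <- order(vapply(cl, min, integer(1)),
               vapply(cl, function(v) -length(v), integer(1)),
               vapply(cl, paste, character(1), collapse = ","))
  cl <- cl[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", k), nms)
  for (i in seq_along(cl)) {
    for (v in cl[[i]]) out[v] <- paste0(out[v], letters_pool[i])
  }
  out
}

#' Frequency summary table with letter groups
#'
#' Mirrors the assay figure columns: construct, event, mean, sd, n and
#' significance letter group (computed per event type).
#'
#' @param data Replicate data frame (rows as in [assay_replicates()],
#'   several constructs allowed).
#' @param alpha Significance level for the letter groups.
#' @param adjust Multiple-testing correction (see [pairwise_welch()]).
#' @return Data frame with one row per construct x event type.
#' @export
freq_table <- function(data, alpha = 0.05, adjust = "none") {
  out <- list()
  for (ev in unique(data$event_type)) {
    d <- data[data$event_type == ev, , drop = FALSE]
    constructs <- unique(d$construct_id)
    ests <- lapply(constructs, function(cc) {
      estimate_frequency(d[d$construct_id == cc, , drop = FALSE])
    })
    letter <- if (length(constructs) >= 2L) {
      groups <- stats::setNames(lapply(constructs, function(cc) {
        dd <- d[d$construct_id == cc, ]
        dd$k_positive / dd$n_colonies
      }), constructs)
      group_letters(pairwise_welch(groups, adjust = adjust),
                    alpha = alpha)
    } else {
      stats::setNames("a", constructs)
    }
    out[[length(out) + 1L]] <- data.frame(
      construct_id = constructs, event_type = ev,
      mean = vapply(ests, `[[`, numeric(1), "mean"),
      sd = vapply(ests, `[[`, numeric(1), "sd"),
      n_replicates = vapply(ests, `[[`, numeric(1), "n_replicates"),
      letter = unname(letter[constructs]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
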