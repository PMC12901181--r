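# Cassette-array assembly. A cassette is an ORF flanked by its nearest
# upstream and downstream recombination sites; cassette boundaries are the
# crossover G positions, so consecutive cassettes tile the variable region
# and each downstream site is the next cassette's upstream site. Arrays
# are reported 5'->3' relative to the attI end.

.empty_sites_table <- function() {
  data.frame(
    seq_id = character(), site_id = character(), type = character(),
    label = character(), start = integer(), end = integer(),
    strand = character(), crossover_g = integer(), stringsAsFactors = FALSE
  )
}

#' Assemble a unified site table from detector outputs
#'
#' @param delta_sites Data frame from [find_delta_atti_cassette_sites()].
#' @param attc_sites Candidate data frame from [find_core_pairs()]
#'   (ideally filtered by fold quality, see [filter_attc_candidates()]).
#' @param atti_sites Data frame from [find_full_atti()].
#' @return Site table with columns `seq_id`, `site_id`, `type`, `label`,
#'   `start`, `end`, `strand`, `crossover_g`.
#' @export
sites_table <- function(delta_sites = NULL, attc_sites = NULL,
                        atti_sites = NULL) {
  rows <- list()
  if (!is.null(delta_sites) && nrow(delta_sites)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = delta_sites$seq_id,
      site_id = paste0("delta_", seq_len(nrow(delta_sites))),
      type = paste0("dattI", delta_sites$class_label),
      label = delta_sites$label,
      start = delta_sites$start, end = delta_sites$end,
      strand = delta_sites$strand, crossover_g = delta_sites$crossover_g,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(attc_sites) && nrow(attc_sites)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = attc_sites$seq_id,
      site_id = paste0("attc_", seq_len(nrow(attc_sites))),
      type = "attC", label = "attC",
      start = attc_sites$start, end = attc_sites$end,
      strand = "+", crossover_g = attc_sites$crossover_g,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(atti_sites) && nrow(atti_sites)) {
    rows[[length(rows) + 1L]] <- atti_sites[, colnames(.empty_sites_table())]
  }
  if (!length(rows)) return(.empty_sites_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate full attI sites by exact reference match
#'
#' @param sequence Forward-strand nucleotide string.
#' @param reference A [reference_atti()] object.
#' @param seq_id Identifier recorded for the sites.
#' @return Site table rows (see [sites_table()]).
#' @export
find_full_atti <- function(sequence, reference, seq_id = "seq") {
  hits <- scan_motif(sequence,
                     iupac_motif(paste0("attI", reference$class_label),
                                 reference$sequence),
                     strand = "both", seq_id = seq_id)
  if (!nrow(hits)) return(.empty_sites_table())
  g <- reference$crossover_g_index
  data.frame(
    seq_id = hits$seq_id,
    site_id = paste0("atti_", seq_len(nrow(hits))),
    type = paste0("attI", reference$class_label),
    label = paste0("attI", reference$class_label),
    start = hits$start, end = hits$end, strand = hits$strand,
    crossover_g = ifelse(hits$strand == "+",
                         hits$start + g - 1L,
                         hits$end - g + 1L),
    stringsAsFactors = FALSE
  )
}

#' Filter attC candidates by fold quality
#'
#' Keeps candidates whose arm-alignment stem score reaches
#' `min_stem_fraction` of the longer arm length: spurious core pairings in
#' random sequence align poorly, true inverted-repeat arms align almost
#' perfectly even with a few EHBs.
#'
#' @param candidates Data frame from [find_core_pairs()].
#' @param min_stem_fraction Minimum stem score / max(arm length)
#'   (default 0.8).
#' @param wobble Passed to [fold_arms()].
#' @return Filtered candidate data frame with a `stem_score` column.
#' @export
filter_attc_candidates <- function(candidates, min_stem_fraction = 0.8,
                                   wobble = FALSE) {
  if (!nrow(candidates)) {
    candidates$stem_score <- integer()
    return(candidates)
  }
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    fold_bottom_strand(candidates[i, ], wobble = wobble)$stem_score
  }, integer(1))
  maxarm <- pmax(nchar(candidates$arm_left), nchar(candidates$arm_right))
  keep <- scores >= min_stem_fraction * maxarm
  out <- candidates[keep, , drop = FALSE]
  out$stem_score <- scores[keep]
  rownames(out) <- NULL
  out
}

.resolve_overlaps <- function(sites) {
  if (nrow(sites) < 2L) return(sites)
  sites <- sites[order(sites$start, -(sites$end - sites$start)), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(sites))
  last <- 1L
  for (i in 2L:nrow(sites)) {
    if (sites$start[i] <= sites$end[last]) {
      keep[i] <- FALSE
      warning("overlapping sites resolved leftmost-longest: dropped ",
              sites$label[i], " at ", sites$start[i])
    } else {
      last <- i
    }
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.flip_coords <- function(df, L, cols = c("start", "end"),
                         point_cols = character()) {
  if (!nrow(df)) return(df)
  s <- df[[cols[1]]]
  e <- df[[cols[2]]]
  df[[cols[1]]] <- L - e + 1L
  df[[cols[2]]] <- L - s + 1L
  for (pc in point_cols) df[[pc]] <- L - df[[pc]] + 1L
  if ("strand" %in% names(df)) {
    df$strand <- ifelse(df$strand == "+", "-", "+")
  }
  df
}

#' Build a cassette array from detected sites and ORFs
#'
#' Each ORF flanked by a nearest upstream and downstream site forms a
#' cassette whose boundaries are the two crossover G positions. ORFs
#' without an upstream flank are reported as orphans; an ORF with an
#' upstream flank but no downstream site (contig edge) yields a cassette
#' with architecture suffix `-truncated`. If the leading attI site lies on
#' the minus strand the whole record is flipped (and the flip logged) so
#' arrays always read 5'->3' from the attI end.
#'
#' @param sites Site table from [sites_table()].
#' @param orfs ORF data frame (`orf_id`, `start`, `end`, `strand`).
#' @param sequence Forward-strand nucleotide string.
#' @param integron_id Record identifier.
#' @param class_label Integron class: `1`, `2` or `"SCI"` (taken from
#'   record metadata, never inferred from sequence).
#' @return An object of class `cassette_array` with the ordered cassette
#'   table, orphan report and resolved site table.
#' @export
build_array <- function(sites, orfs, sequence, integron_id = "integron",
                        class_label = 1) {
  L <- nchar(sequence)
  flipped <- FALSE
  atti_rows <- sites[sites$type %in% c("attI1", "attI2"), , drop = FALSE]
  if (nrow(atti_rows) && atti_rows$strand[which.min(atti_rows$start)] == "-") {
    message("build_array: leading attI on minus strand; flipping ",
            integron_id, " to normalize orientation")
    sequence <- revcomp(sequence)
    sites <- .flip_coords(sites, L, point_cols = "crossover_g")
    orfs <- .flip_coords(orfs, L)
    flipped <- TRUE
  }
  sites <- .resolve_overlaps(sites[order(sites$start), , drop = FALSE])
  orfs <- orfs[order(orfs$start), , drop = FALSE]

  cass <- list()
  orphans <- list()
  idx <- 0L
  for (k in seq_len(nrow(orfs))) {
    o <- orfs[k, ]
    up <- sites[sites$crossover_g < o$start, , drop = FALSE]
    down <- sites[sites$crossover_g > o$end, , drop = FALSE]
    if (!nrow(up)) {
      orphans[[length(orphans) + 1L]] <- o
      next
    }
    up <- up[which.max(up$crossover_g), ]
    truncated <- nrow(down) == 0L
    if (!truncated) down <- down[which.min(down$crossover_g), ]
    idx <- idx + 1L
    cass[[idx]] <- data.frame(
      index = idx, orf_id = o$orf_id,
      orf_start = o$start, orf_end = o$end, orf_strand = o$strand,
      upstream_label = up$label,
      downstream_label = if (truncated) NA_character_ else down$label,
      architecture = if (truncated) {
        paste0(up$label, "-ORF-truncated")
      } else {
        paste(up$label, "ORF", down$label, sep = "-")
      },
      cass_start = up$crossover_g,
      cass_end = if (truncated) L else down$crossover_g - 1L,
      cassette_seq = substring(sequence, up$crossover_g,
                               if (truncated) L else down$crossover_g - 1L),
      key_full = substring(sequence, o$start,
                           if (truncated) L else down$end),
      key_orf = substring(sequence, o$start, o$end),
      truncated = truncated,
      stringsAsFactors = FALSE
    )
  }
  cassettes <- if (length(cass)) do.call(rbind, cass) else
    data.frame(index = integer(), orf_id = character(),
               orf_start = integer(), orf_end = integer(),
               orf_strand = character(), upstream_label = character(),
               downstream_label = character(), architecture = character(),
               cass_start = integer(), cass_end = integer(),
               cassette_seq = character(), key_full = character(),
               key_orf = character(), truncated = logical(),
               stringsAsFactors = FALSE)
  orphans <- if (length(orphans)) do.call(rbind, orphans) else
    orfs[0, , drop = FALSE]
  structure(
    list(integron_id = integron_id, class_label = class_label,
         cassettes = cassettes, orphans = orphans, sites = sites,
         flipped = flipped, sequence = sequence),
    class = "cassette_array"
  )
}

#' @export
print.cassette_array <- function(x, ...) {
  cat(sprintf("Cassette array %s (class %s): %d cassette(s), %d orphan(s)%s\n",
              x$integron_id, x$class_label, nrow(x$cassettes),
              nrow(x$orphans), if (x$flipped) " [flipped]" else ""))
  if (nrow(x$cassettes)) cat(" ", array_string(x), "\n")
  invisible(x)
}

#' One-line array string
#'
#' @param array A `cassette_array`.
#' @return String such as `"attI1|aadB|dattI1-11"` (leading site, then
#'   alternating ORF and downstream-site labels).
#' @export
array_string <- function(array) {
  cs <- array$cassettes
  if (!nrow(cs)) return("")
  parts <- cs$upstream_label[1]
  for (i in seq_len(nrow(cs))) {
    parts <- c(parts, cs$orf_id[i],
               if (cs$truncated[i]) "truncated" else cs$downstream_label[i])
  }
  paste(parts, collapse = "|")
}

.pair_identity <- function(a, b) {
  if (a == b) return(1)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::nmatch(al) / max(nchar(a), nchar(b))
}

#' Detect tandem runs of identical cassettes
#'
#' Finds maximal runs of two or more consecutive cassettes whose keyed
#' sequences are pairwise identical at or above the threshold
#' (length-normalized global identity).
#'
#' @param array A `cassette_array` from [build_array()].
#' @param identity_threshold Fraction in (0, 1]; default 1.0 (exact),
#'   matching the strict reading of "identical" cassettes.
#' @param key `"full_cassette"` (ORF plus downstream site, the default) or
#'   `"orf"` (ORF only).
#' @return Data frame of runs: `start_index`, `run_length`, `identity`
#'   (minimum pairwise identity within the run).
#' @export
detect_tandem <- function(array, identity_threshold = 1.0,
                          key = c("full_cassette", "orf")) {
  key <- match.arg(key)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  keys <- if (key == "full_cassette") array$cassettes$key_full
          else array$cassettes$key_orf
  n <- length(keys)
  runs <- list()
  i <- 1L
  while (i <= n) {
    members <- i
    min_id <- 1
    j <- i + 1L
    while (j <= n) {
      ids <- vapply(members, function(k) .pair_identity(keys[k], keys[j]),
                    numeric(1))
      if (all(ids >= identity_threshold)) {
        members <- c(members, j)
        min_id <- min(min_id, ids)
        j <- j + 1L
      } else break
    }
    if (length(members) >= 2L) {
      runs[[length(runs) + 1L]] <- data.frame(
        start_index = i, run_length = length(members),
        identity = min_id
      )
    }
    i <- j
  }
  if (!length(runs)) {
    return(data.frame(start_index = integer(), run_length = integer(),
                      identity = numeric()))
  }
  do.call(rbind, runs)
}

#' Write per-cassette array report as TSV
#'
#' @param arrays A `cassette_array` or list of them.
#' @param path Output path.
#' @param ... Passed to [detect_tandem()].
#' @return Invisibly, `path`.
#' @export
write_array_tsv <- function(arrays, path, ...) {
  if (inherits(arrays, "cassette_array")) arrays <- list(arrays)
  rows <- lapply(arrays, function(a) {
    if (!nrow(a$cassettes)) return(NULL)
    runs <- detect_tandem(a, ...)
    tandem_flag <- rep(FALSE, nrow(a$cassettes))
    for (r in seq_len(nrow(runs))) {
      tandem_flag[runs$start_index[r]:
                    (runs$start_index[r] + runs$run_length[r] - 1L)] <- TRUE
    }
    data.frame(integron_id = a$integron_id, index = a$cassettes$index,
               orf_id = a$cassettes$orf_id,
               architecture = a$cassettes$architecture,
               tandem_flag = tandem_flag, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
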