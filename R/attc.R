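# attC site modelling. An attC site is delimited by the inverse core site
# R'' (RYYYAAC) and the core site R' (GTTRRRY) on the cassette top strand,
# 57-141 bp apart (outer span). Its bottom strand folds into a hairpin by
# pairing the R''-L'' arm against the L'-R' arm; imperfections in the
# inverted homology leave unpaired, extrahelical bases (EHBs) that the
# integrase requires for single-strand recognition. Folding here is a
# global arm alignment (Watson-Crick match +1, mismatch 0, gap -1), not a
# thermodynamic fold: the structural claims the pipeline makes concern
# pairing topology and EHBs, not free energy.

ATTC_MIN_LENGTH <- 57L
ATTC_MAX_LENGTH <- 141L

#' Find candidate attC sites from paired core motifs
#'
#' Reports every ordered (R'', R') pair on the forward strand whose outer
#' span lies within the attC length envelope. Nested and overlapping
#' candidates are all reported; downstream filtering (e.g. by fold
#' quality, see [fold_bottom_strand()]) resolves conflicts.
#'
#' Arms are delimited by reserving `loop_len` nt as the unpaired central
#' loop and splitting the remaining interior between the two arms (the
#' right arm takes the extra base when the interior is odd, so a
#' single-base bulge in the right arm is recovered intact).
#'
#' @param sequence Forward-strand nucleotide string.
#' @param min_len,max_len attC outer-span envelope (defaults 57 and 141).
#' @param loop_len Minimum unpaired central loop, in nt (default 10).
#' @param seq_id Identifier recorded for candidates.
#' @return Data frame of candidates sorted by start: core coordinates,
#'   `total_length`, `crossover_g` (first base of R'; the crossover lies
#'   between it and the following T) and the `arm_left`/`arm_right`
#'   sequences.
#' @export
find_core_pairs <- function(sequence, min_len = ATTC_MIN_LENGTH,
                            max_len = ATTC_MAX_LENGTH, loop_len = 10L,
                            seq_id = "seq") {
  motifs <- integron_motifs()
  r2 <- scan_motif(sequence, motifs$inverse_core, strand = "forward",
                   seq_id = seq_id)
  r1 <- scan_motif(sequence, motifs$core_site, strand = "forward",
                   seq_id = seq_id)
  out <- list()
  for (i in seq_len(nrow(r2))) {
    for (j in seq_len(nrow(r1))) {
      if (r1$start[j] <= r2$end[i]) next
      total <- r1$end[j] - r2$start[i] + 1L
      if (total < min_len || total > max_len) next
      interior <- r1$start[j] - r2$end[i] - 1L
      arm_ext <- max(0L, (interior - loop_len) %/% 2L)
      arm_ext_r <- max(0L, interior - loop_len - arm_ext)
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id,
        start = r2$start[i], end = r1$end[j],
        r2_start = r2$start[i], r2_end = r2$end[i],
        r1_start = r1$start[j], r1_end = r1$end[j],
        total_length = total,
        crossover_g = r1$start[j],
        r2_matched = r2$matched[i], r1_matched = r1$matched[j],
        arm_left = substring(sequence, r2$start[i], r2$end[i] + arm_ext),
        arm_right = substring(sequence, r1$start[j] - arm_ext_r, r1$end[j]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      seq_id = character(), start = integer(), end = integer(),
      r2_start = integer(), r2_end = integer(), r1_start = integer(),
      r1_end = integer(), total_length = integer(),
      crossover_g = integer(), r2_matched = character(),
      r1_matched = character(), arm_left = character(),
      arm_right = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.wc_pair <- function(a, b, wobble = FALSE) {
  ok <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (wobble) ok <- ok | (a == "G" & b == "T") | (a == "T" & b == "G")
  ok
}

#' Align two attC arms into a stem (hairpin fold)
#'
#' Global alignment of the left arm (R''->L'', 5'->3' top strand) against
#' the reversed right arm (so both read core-proximal first): a
#' complementary aligned pair scores +1, a non-complementary aligned pair
#' 0, and each unaligned (gapped) base -1. Gapped bases are the
#' extrahelical bases (EHBs). Ties are broken deterministically in favour
#' of placing gaps closest to the core-proximal end of the stem.
#'
#' @param arm_left,arm_right Arm sequences on the top strand (left arm
#'   starts with R'', right arm ends with R').
#' @param wobble Count G-T wobble pairs as paired (default `FALSE`:
#'   Watson-Crick only).
#' @return An object of class `fold_result`: `pairs` (data frame of
#'   paired top-strand arm positions), `ehbs` (data frame: `arm`, `pos`
#'   within the arm, `offset` from the core-proximal stem end, `base_top`
#'   and bottom-strand `base`), `stem_score` (paired count minus gap
#'   count) and the aligned strings.
#' @export
fold_arms <- function(arm_left, arm_right, wobble = FALSE) {
  x <- strsplit(toupper(arm_left), "", fixed = TRUE)[[1]]
  yr <- rev(strsplit(toupper(arm_right), "", fixed = TRUE)[[1]])
  n <- length(x)
  m <- length(yr)
  if (n < 1L || m < 1L) stop("arms must be non-empty")

  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- -(0L:n)
  S[1L, ] <- -(0L:m)
  for (i in seq_len(n)) {
    w <- as.integer(.wc_pair(x[i], yr, wobble))
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + w[j], S[i, j + 1L] - 1L,
                               S[i + 1L, j] - 1L)
    }
  }

  # traceback from the loop-distal corner; preferring the diagonal defers
  # gaps toward the start of the alignment, i.e. the core-proximal end
  i <- n; j <- m
  pairs <- list(); ehb <- list()
  len_r <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + as.integer(.wc_pair(x[i], yr[j], wobble))) {
      if (.wc_pair(x[i], yr[j], wobble)) {
        pairs[[length(pairs) + 1L]] <-
          c(left_pos = i, right_pos = len_r - j + 1L)
      }
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 1L) {
      ehb[[length(ehb) + 1L]] <- list(arm = "left", pos = i)
      i <- i - 1L
    } else {
      ehb[[length(ehb) + 1L]] <- list(arm = "right", pos = len_r - j + 1L)
      j <- j - 1L
    }
  }

  pairs_df <- if (length(pairs)) {
    df <- as.data.frame(do.call(rbind, pairs))
    df[order(df$left_pos), , drop = FALSE]
  } else {
    data.frame(left_pos = integer(), right_pos = integer())
  }
  rownames(pairs_df) <- NULL

  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ehb_df <- if (length(ehb)) {
    arm <- vapply(ehb, `[[`, character(1), "arm")
    pos <- vapply(ehb, `[[`, integer(1), "pos")
    base_top <- ifelse(arm == "left", x[pos], rev(yr)[pos])
    offset <- ifelse(arm == "left", pos, len_r - pos + 1L)
    df <- data.frame(arm = arm, pos = pos, offset = as.integer(offset),
                     base_top = base_top,
                     base = unname(comp[base_top]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$arm, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(arm = character(), pos = integer(), offset = integer(),
               base_top = character(), base = character(),
               stringsAsFactors = FALSE)
  }

  structure(
    list(pairs = pairs_df, ehbs = ehb_df,
         stem_score = S[n + 1L, m + 1L],
         n_paired = nrow(pairs_df), n_ehb = nrow(ehb_df),
         arm_left = paste(x, collapse = ""),
         arm_right = arm_right),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("attC arm fold: %d paired, %d EHB(s), stem score %d\n",
              x$n_paired, x$n_ehb, x$stem_score))
  if (x$n_ehb) {
    cat("  EHBs (bottom strand):",
        paste(sprintf("%s@%d(%s arm)", x$ehbs$base, x$ehbs$offset,
                      x$ehbs$arm), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fold the bottom strand of an attC candidate
#'
#' @param candidate One-row candidate data frame from [find_core_pairs()]
#'   (or any list with `arm_left` and `arm_right`).
#' @param wobble Passed to [fold_arms()].
#' @return A `fold_result` (see [fold_arms()]).
#' @export
fold_bottom_strand <- function(candidate, wobble = FALSE) {
  if (is.data.frame(candidate)) {
    candidate <- as.list(candidate[1, , drop = FALSE])
  }
  if (is.null(candidate$arm_left) || is.null(candidate$arm_right)) {
    stop("candidate must carry `arm_left` and `arm_right`")
  }
  if (nchar(candidate$arm_left) < 7L || nchar(candidate$arm_right) < 7L) {
    stop("arms shorter than the 7-mer cores cannot be folded")
  }
  fold_arms(candidate$arm_left, candidate$arm_right, wobble = wobble)
}

#' Render a folded candidate as a dot-bracket string
#'
#' @param candidate One-row candidate from [find_core_pairs()].
#' @param fold Matching `fold_result`.
#' @return Dot-bracket string spanning the candidate (paired left-arm
#'   positions `(`, paired right-arm positions `)`, everything else `.`).
#' @export
fold_dotbracket <- function(candidate, fold) {
  candidate <- as.list(candidate[1, , drop = FALSE])
  total <- candidate$total_length
  db <- rep(".", total)
  la_off <- 0L # left arm starts at candidate start
  ra_start <- total - nchar(candidate$arm_right) + 1L
  db[fold$pairs$left_pos + la_off] <- "("
  db[ra_start + fold$pairs$right_pos - 1L] <- ")"
  paste(db, collapse = "")
}

#' Canonical extrahelical-base specification
#'
#' Default identities and core-proximal stem offsets of the two EHBs
#' required for canonical single-stranded attC recognition. These defaults
#' are literature-derived configuration values (not measured by this
#' package) and should be adjusted to the fold conventions of the sites
#' under study.
#'
#' @param ehbs List of `list(base =, offset =)` entries.
#' @return The specification list, classed `canonical_ehb_spec`.
#' @export
canonical_ehb_spec <- function(ehbs = list(
                                 list(base = "G", offset = 9L),
                                 list(base = "T", offset = 13L)
                               )) {
  structure(ehbs, class = "canonical_ehb_spec")
}

#' Check a fold for the canonical EHBs
#'
#' @param fold A `fold_result` from [fold_bottom_strand()].
#' @param spec A [canonical_ehb_spec()].
#' @param tolerance Positional tolerance on the stem offset (default 1).
#' @return List with `ok` (TRUE iff every configured EHB is present) and
#'   `missing` (character report naming absent EHBs).
#' @export
check_canonical_ehbs <- function(fold, spec = canonical_ehb_spec(),
                                 tolerance = 1L) {
  if (is.null(spec) || !length(spec)) {
    stop("no canonical EHB specification configured: supply one via ",
         "`canonical_ehb_spec()`")
  }
  missing <- character()
  for (e in spec) {
    found <- nrow(fold$ehbs) > 0L &&
      any(fold$ehbs$base == e$base &
            abs(fold$ehbs$offset - e$offset) <= tolerance)
    if (!found) {
      missing <- c(missing,
                   sprintf("%s at stem offset %d (+/-%d)",
                           e$base, e$offset, tolerance))
    }
  }
  list(ok = length(missing) == 0L, missing = missing)
}
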