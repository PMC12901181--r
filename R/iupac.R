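#' IUPAC nucleotide code table
#'
#' The 15 degenerate nucleotide codes and the base sets they denote
#' (R = purine \{A,G\}, Y = pyrimidine \{C,T\}, ..., N = any base).
#'
#' @return Named list mapping each IUPAC code to its character vector of
#'   unambiguous bases.
#' @export
iupac_codes <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"),
    S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

#' Expand a single IUPAC code to its base set
#'
#' @param code A single IUPAC nucleotide character (case-insensitive).
#' @return Character vector of the unambiguous bases the code denotes.
#' @examples
#' expand_iupac("R") # purine: A, G
#' expand_iupac("N")
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("`code` must be a single character")
  }
  up <- toupper(code)
  tab <- iupac_codes()
  if (!up %in% names(tab)) {
    stop("invalid IUPAC nucleotide code: '", code, "'")
  }
  tab[[up]]
}

# Bit-mask encoding: A=1, C=2, G=4, T=8; bit 16 marks the literal letter N so
# that an N in the subject matches pattern N and nothing else (the sites the
# pipeline targets are exact-sequence curated, so subject Ns are treated as
# unknowns, not wildcards).
.iupac_bits <- function() {
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  tab <- iupac_codes()
  bits <- vapply(tab, function(b) sum(base_bits[b]), integer(1))
  bits["N"] <- bits[["N"]] + 16L
  bits
}

.encode_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bits <- .iupac_bits()
  bad <- setdiff(unique(chars), names(bits))
  if (length(bad)) {
    stop("invalid IUPAC nucleotide code: '", bad[1], "'")
  }
  unname(bits[chars])
}

.encode_subject <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  sub_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
  bad <- setdiff(unique(chars), names(sub_bits))
  if (length(bad)) {
    stop("invalid character in sequence: '", bad[1],
         "' (subject sequences must be over A, C, G, T, N)")
  }
  unname(sub_bits[chars])
}

#' Define a degenerate IUPAC motif
#'
#' @param name Short label for the motif.
#' @param pattern Non-empty string over the IUPAC nucleotide alphabet.
#' @return An object of class `iupac_motif`.
#' @examples
#' core_site <- iupac_motif("core_site", "GTTRRRY")
#' @export
iupac_motif <- function(name, pattern) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("`pattern` must be a non-empty string")
  }
  .encode_pattern(pattern) # validates
  structure(
    list(name = name, pattern = toupper(pattern)),
    class = "iupac_motif"
  )
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat("IUPAC motif", x$name, ":", x$pattern,
      sprintf("(%d nt)\n", nchar(x$pattern)))
  invisible(x)
}

.as_motif <- function(motif) {
  if (inherits(motif, "iupac_motif")) return(motif)
  if (is.character(motif) && length(motif) == 1L) {
    return(iupac_motif(motif, motif))
  }
  stop("`motif` must be an `iupac_motif` or a pattern string")
}

#' Reverse-complement a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' degenerate codes are complemented correctly (R <-> Y etc.).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.empty_hits <- function() {
  data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), motif_name = character(), matched = character(),
    mismatches = integer(), stringsAsFactors = FALSE
  )
}

.scan_one_strand <- function(subj_code, pat_code, max_mismatch) {
  L <- length(subj_code)
  m <- length(pat_code)
  n_pos <- L - m + 1L
  if (n_pos < 1L) return(integer(0))
  mism <- integer(n_pos)
  for (j in seq_len(m)) {
    ok <- bitwAnd(subj_code[j:(n_pos + j - 1L)], pat_code[j]) != 0L
    mism <- mism + as.integer(!ok)
  }
  which(mism <= max_mismatch)
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every position (overlaps included) where each pattern column's
#' base set contains the sequence base, on the requested strand(s). An `N`
#' in the subject sequence matches only an `N` pattern column. Coordinates
#' are 1-based inclusive on the forward strand; for minus-strand hits
#' `matched` is the subsequence as read 5'->3' on the minus strand.
#'
#' @param sequence Nucleotide string over A, C, G, T, N (case-insensitive).
#' @param motif An [iupac_motif()] or a pattern string.
#' @param strand One of `"both"`, `"forward"`, `"reverse"`.
#' @param max_mismatch Maximum number of mismatching columns tolerated
#'   (default 0, i.e. exact degenerate matching).
#' @param seq_id Identifier recorded in the hit table.
#' @return A data frame of hits (`seq_id`, `start`, `end`, `strand`,
#'   `motif_name`, `matched`, `mismatches`) sorted by `start`, then strand
#'   (`+` before `-`).
#' @examples
#' scan_motif("AAACAAAGTTAGAC", iupac_motif("dattI1", "AAACAAAGTTRRRY"))
#' @export
scan_motif <- function(sequence, motif,
                       strand = c("both", "forward", "reverse"),
                       max_mismatch = 0L, seq_id = "seq") {
  strand <- match.arg(strand)
  motif <- .as_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(.empty_hits())
  subj <- .encode_subject(sequence)
  pat <- .encode_pattern(motif$pattern)
  m <- length(pat)
  L <- length(subj)
  seq_up <- toupper(sequence)
  out <- list()
  if (strand %in% c("both", "forward")) {
    st <- .scan_one_strand(subj, pat, max_mismatch)
    if (length(st)) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, start = st, end = st + m - 1L, strand = "+",
        motif_name = motif$name,
        matched = substring(seq_up, st, st + m - 1L),
        mismatches = 0L, stringsAsFactors = FALSE
      )
    }
  }
  if (strand %in% c("both", "reverse")) {
    rc <- revcomp(seq_up)
    subj_rc <- .encode_subject(rc)
    st_rc <- .scan_one_strand(subj_rc, pat, max_mismatch)
    if (length(st_rc)) {
      end_rc <- st_rc + m - 1L
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id,
        start = L - end_rc + 1L, end = L - st_rc + 1L, strand = "-",
        motif_name = motif$name,
        matched = substring(rc, st_rc, end_rc),
        mismatches = 0L, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  if (max_mismatch > 0L) {
    hits$mismatches <- .count_mismatches(hits, pat)
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.count_mismatches <- function(hits, pat_code) {
  vapply(hits$matched, function(s) {
    sc <- .encode_subject(s)
    sum(bitwAnd(sc, pat_code) == 0L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Scan several sequences for several motifs
#'
#' @param sequences Named character vector of sequences (names become
#'   `seq_id`s) or a [Biostrings::DNAStringSet].
#' @param motifs A single motif or list of [iupac_motif()] objects.
#' @inheritParams scan_motif
#' @return Combined hit data frame.
#' @export
scan_motifs <- function(sequences, motifs, strand = "both",
                        max_mismatch = 0L) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (inherits(motifs, "iupac_motif") || is.character(motifs)) {
    motifs <- list(motifs)
  }
  res <- list()
  for (id in names(sequences)) {
    for (mo in motifs) {
      res[[length(res) + 1L]] <- scan_motif(
        sequences[[id]], mo, strand = strand,
        max_mismatch = max_mismatch, seq_id = id
      )
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .empty_hits()
  rownames(out) <- NULL
  out
}

#' Bundled integron motif set
#'
#' The field's consensus motifs used throughout the pipeline: the minimal
#' truncated-attI consensus for class 1 (`dattI1`, 14 nt, AAACAAAGTTRRRY)
#' and class 2 (`dattI2`, 15 nt, AATAAAATGTTRRRY), the attC core site
#' R' (`core_site`, GTTRRRY), the inverse core site R'' (`inverse_core`,
#' RYYYAAC) and the attI1 L box (`l_box`, CCCTAAA).
#'
#' @return Named list of [iupac_motif()] objects.
#' @export
integron_motifs <- function() {
  path <- system.file("extdata", "motifs.yaml", package = "integronArrays")
  motifs_from_config(path)
}

#' Load motif definitions from a YAML config
#'
#' The file maps motif names to IUPAC pattern strings.
#'
#' @param path Path to a YAML file (`name: PATTERN` entries).
#' @return Named list of [iupac_motif()] objects.
#' @export
motifs_from_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) iupac_motif(nm, raw[[nm]]))
  stats::setNames(out, names(raw))
}
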