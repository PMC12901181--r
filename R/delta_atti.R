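# Detection and crossover-relative classification of truncated attI
# (Delta-attI) sites. A Delta-attI site is the minimal consensus motif
# (AAACAAAGTTRRRY for class 1, AATAAAATGTTRRRY for class 2) plus however
# many additional reference-identical bases extend upstream of it. Sites
# are labelled by the upstream extent relative to the crossover G
# (position -X), and the retained fragment length obeys
# retained_length == |position_label| + 6 (the G is the innermost counted
# upstream position; the 6 nt TTRRRY downstream complete the core).

#' Format a Delta-attI site label
#'
#' @param class_label 1 or 2.
#' @param position_label Negative integer.
#' @return Label string such as `"dattI1-11"` (read: Delta-attI1 at
#'   crossover-relative position -11).
#' @export
delta_label <- function(class_label, position_label) {
  sprintf("dattI%d%d", class_label, position_label)
}

#' Classify a minimal-consensus hit as a Delta-attI site
#'
#' Walks upstream from the consensus match, comparing the context sequence
#' base-by-base against the 3' end of the reference attI until the first
#' mismatch or reference exhaustion. The matched upstream run sets the
#' crossover-relative position label and the retained fragment length.
#'
#' @param hit One-row hit data frame from [scan_motif()] for the minimal
#'   Delta-attI consensus (`motif_name` `"dattI1"` or `"dattI2"`).
#' @param context_sequence Forward-strand sequence the hit was found in.
#' @param reference Matching [reference_atti()] object.
#' @param max_mismatch_ext Mismatches tolerated during upstream extension
#'   (default 0: the extension requires exact identity to the reference).
#' @return An object of class `delta_atti_site`: a list with
#'   `class_label`, `position_label`, `retained_length`,
#'   `upstream_extension`, `core_matched`, fragment coordinates
#'   (`start`, `end`, `strand`, `crossover_g`) and a `truncated` flag set
#'   when a contig edge cut the upstream walk short.
#' @export
classify_delta_atti <- function(hit, context_sequence, reference,
                                max_mismatch_ext = 0L) {
  stopifnot(inherits(reference, "reference_atti"))
  hit <- as.list(hit[1, , drop = FALSE])
  hit_class <- if (identical(hit$motif_name, "dattI1")) 1L
               else if (identical(hit$motif_name, "dattI2")) 2L
               else stop("hit motif_name must be 'dattI1' or 'dattI2', got '",
                         hit$motif_name, "'")
  if (hit_class != reference$class_label) {
    stop("hit class (", hit_class, ") does not match reference class (",
         reference$class_label, ")")
  }
  context_sequence <- toupper(context_sequence)
  L <- nchar(context_sequence)
  m <- hit$end - hit$start + 1L
  u_min <- m - 6L # upstream consensus bases up to and including the G

  # work in the hit strand's orientation
  if (identical(hit$strand, "-")) {
    oriented <- revcomp(context_sequence)
    o_start <- L - hit$end + 1L
  } else {
    oriented <- context_sequence
    o_start <- hit$start
  }

  g <- reference$crossover_g_index
  ref_chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  ctx_chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
  ext <- 0L
  mism <- 0L
  truncated <- FALSE
  repeat {
    ref_pos <- g - u_min - ext
    ctx_pos <- o_start - 1L - ext
    if (ref_pos < 1L) break # reference exhausted
    if (ctx_pos < 1L) {
      truncated <- TRUE
      break
    }
    if (ctx_chars[ctx_pos] != ref_chars[ref_pos]) {
      mism <- mism + 1L
      if (mism > max_mismatch_ext) break
    }
    ext <- ext + 1L
  }

  o_frag_start <- o_start - ext
  o_frag_end <- o_start + m - 1L
  if (identical(hit$strand, "-")) {
    f_start <- L - o_frag_end + 1L
    f_end <- L - o_frag_start + 1L
    crossover_g <- f_start + 6L
  } else {
    f_start <- o_frag_start
    f_end <- o_frag_end
    crossover_g <- f_end - 6L
  }

  position_label <- -(u_min + ext)
  structure(
    list(
      seq_id = hit$seq_id,
      class_label = hit_class,
      position_label = position_label,
      retained_length = u_min + ext + 6L,
      upstream_extension = ext,
      core_matched = substring(hit$matched, m - 6L, m),
      label = delta_label(hit_class, position_label),
      start = f_start, end = f_end, strand = hit$strand,
      crossover_g = crossover_g,
      truncated = truncated
    ),
    class = "delta_atti_site"
  )
}

#' @export
print.delta_atti_site <- function(x, ...) {
  cat(sprintf(
    "Delta-attI%d site at position %d (%d nt retained)%s\n",
    x$class_label, x$position_label, x$retained_length,
    if (x$truncated) " [truncated by contig edge]" else ""
  ))
  cat(sprintf("  %s:%d-%d (%s), core %s\n",
              x$seq_id, x$start, x$end, x$strand, x$core_matched))
  invisible(x)
}

#' @export
as.data.frame.delta_atti_site <- function(x, ...) {
  data.frame(
    seq_id = x$seq_id, orf_id = if (is.null(x$orf_id)) NA_character_
                                else x$orf_id,
    class_label = x$class_label, label = x$label,
    position_label = x$position_label,
    retained_length = x$retained_length,
    upstream_extension = x$upstream_extension,
    core_matched = x$core_matched,
    start = x$start, end = x$end, strand = x$strand,
    crossover_g = x$crossover_g, truncated = x$truncated,
    stringsAsFactors = FALSE
  )
}

.empty_delta_sites <- function() {
  data.frame(
    seq_id = character(), orf_id = character(), class_label = integer(),
    label = character(), position_label = integer(),
    retained_length = integer(), upstream_extension = integer(),
    core_matched = character(), start = integer(), end = integer(),
    strand = character(), crossover_g = integer(), truncated = logical(),
    stringsAsFactors = FALSE
  )
}

#' Find Delta-attI cassette sites in an annotated sequence
#'
#' Scans both strands for the minimal class-1 and class-2 Delta-attI
#' consensus motifs, classifies each hit against the matching reference,
#' and keeps only sites whose retained fragment begins within `window` nt
#' downstream of an ORF stop codon in the ORF's orientation (the
#' attI-derived region starts just after the cassette ORF even when the
#' consensus itself sits hundreds of bases further, as in deeply extended
#' sites). Sites overlapping ORFs are excluded. This ORF-context filter
#' stands in for the manual curation step a human screener would perform.
#'
#' @param sequence Forward-strand nucleotide string.
#' @param orfs Data frame of ORF features with columns `orf_id`, `start`,
#'   `end`, `strand`.
#' @param references List with the class-1 and class-2
#'   [reference_atti()] objects (default: bundled references).
#' @param window Context window downstream of the stop codon, in nt
#'   (default 150).
#' @param seq_id Identifier recorded for the sites.
#' @param require_context If `FALSE`, classify every consensus hit without
#'   ORF-context filtering (then `orfs` may be `NULL`).
#' @return Data frame of classified sites (one row per site, array order),
#'   each linked to its upstream ORF via `orf_id`.
#' @export
find_delta_atti_cassette_sites <- function(sequence, orfs,
                                           references = list(
                                             atti_reference(1),
                                             atti_reference(2)
                                           ),
                                           window = 150L, seq_id = "seq",
                                           require_context = TRUE) {
  refs <- stats::setNames(references,
                          vapply(references, function(r)
                            as.character(r$class_label), character(1)))
  if (require_context && (is.null(orfs) || nrow(orfs) == 0L)) {
    stop("no ORF annotations available: supply `orfs` (GenBank CDS ",
         "features or synthetic truth) or set require_context = FALSE ",
         "to classify every consensus hit")
  }
  motifs <- integron_motifs()
  hits <- rbind(
    scan_motif(sequence, motifs$dattI1, strand = "both", seq_id = seq_id),
    scan_motif(sequence, motifs$dattI2, strand = "both", seq_id = seq_id)
  )
  if (!nrow(hits)) return(.empty_delta_sites())

  rows <- list()
  for (i in seq_len(nrow(hits))) {
    cls <- if (hits$motif_name[i] == "dattI1") "1" else "2"
    site <- classify_delta_atti(hits[i, ], sequence, refs[[cls]])
    df <- as.data.frame(site)
    df$orf_id <- NA_character_
    if (require_context) {
      # exclude sites overlapping any ORF, then require the retained
      # fragment to start within the window past a same-strand stop codon
      if (any(df$start <= orfs$end & df$end >= orfs$start)) next
      if (df$strand == "+") {
        cand <- orfs[orfs$strand == "+" &
                       df$start > orfs$end &
                       df$start <= orfs$end + window, , drop = FALSE]
        if (!nrow(cand)) next
        df$orf_id <- cand$orf_id[which.max(cand$end)]
      } else {
        cand <- orfs[orfs$strand == "-" &
                       df$end < orfs$start &
                       df$end >= orfs$start - window, , drop = FALSE]
        if (!nrow(cand)) next
        df$orf_id <- cand$orf_id[which.min(cand$start)]
      }
    }
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) return(.empty_delta_sites())
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive the minimal IUPAC consensus of aligned instances
#'
#' Per column, returns the minimal IUPAC code whose base set equals the
#' union of observed bases.
#'
#' @param instances Character vector of equal-length aligned nucleotide
#'   strings (IUPAC codes allowed; their base sets enter the union).
#' @return Consensus string over the IUPAC alphabet.
#' @examples
#' derive_consensus(c("AAACAAAGTTAGAC", "AAACAAAGTTGGGT"))
#' @export
derive_consensus <- function(instances) {
  if (!length(instances)) stop("need at least one instance")
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L) {
    stop("instances must all have equal length")
  }
  codes <- lapply(instances, .encode_pattern)
  bits <- Reduce(bitwOr, codes)
  bits <- bitwAnd(bits, 15L) # strip the literal-N marker for the union
  tab <- .iupac_bits()
  lut <- stats::setNames(names(tab), as.character(bitwAnd(unname(tab), 15L)))
  paste(lut[as.character(bits)], collapse = "")
}
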