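# Bundled attI reference sites.
#
# The package ships synthetic stand-in references (see
# inst/extdata/atti_references_synthetic.*): constructed sequences that
# satisfy the published structural constraints of the canonical sites --
# attI1 is 65 bp with direct repeats DR1/DR2, the L box CCCTAAA, an R box
# realizing GTTRRRY and the crossover G at the -1 position of a -56 upstream
# extent; the attI2 region is 311 bp ending AATAAAATG + TTRRRY. Users working
# with the real GenBank-derived sites can construct their own references
# with reference_atti().

#' Construct a reference attI site
#'
#' @param class_label Integron class, 1 or 2.
#' @param sequence Full attI nucleotide sequence.
#' @param crossover_g_index 1-based position of the crossover G within
#'   `sequence` (the recombination breakpoint lies between this G and the
#'   following T of the GTTRRRY core).
#' @param boxes Optional named list of `c(start, end)` subregions (L_box,
#'   R_box, DR1, DR2); may be empty for class 2, where structural elements
#'   are undefined.
#' @param source Free-text provenance string.
#' @return An object of class `reference_atti`.
#' @export
reference_atti <- function(class_label, sequence, crossover_g_index,
                           boxes = list(), source = "user") {
  stopifnot(class_label %in% c(1L, 2L))
  sequence <- toupper(sequence)
  .encode_subject(sequence)
  g <- as.integer(crossover_g_index)
  if (g < 1L || g > nchar(sequence)) {
    stop("crossover_g_index outside the reference sequence")
  }
  if (substring(sequence, g, g) != "G") {
    stop("base at crossover_g_index must be G, found '",
         substring(sequence, g, g), "'")
  }
  structure(
    list(class_label = as.integer(class_label), sequence = sequence,
         crossover_g_index = g, boxes = boxes, source = source),
    class = "reference_atti"
  )
}

#' @export
print.reference_atti <- function(x, ...) {
  cat(sprintf("Reference attI%d (%d bp), crossover G at %d\n",
              x$class_label, nchar(x$sequence), x$crossover_g_index))
  cat("  source:", x$source, "\n")
  if (length(x$boxes)) {
    cat("  boxes:", paste(names(x$boxes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a bundled attI reference
#'
#' @param class_label 1 (attI1, 65 bp) or 2 (attI2 region, 311 bp).
#' @return A [reference_atti()] object.
#' @export
atti_reference <- function(class_label) {
  stopifnot(class_label %in% c(1L, 2L))
  fa <- system.file("extdata", "atti_references_synthetic.fa",
                    package = "integronArrays")
  meta_path <- system.file("extdata", "atti_references_synthetic.yaml",
                           package = "integronArrays")
  seqs <- read_fasta(fa)
  meta <- yaml::read_yaml(meta_path)
  key <- paste0("attI", class_label)
  m <- meta[[key]]
  reference_atti(
    class_label = class_label,
    sequence = seqs[[m$id]],
    crossover_g_index = m$crossover_g_index,
    boxes = lapply(m$boxes, function(b) c(start = b[[1]], end = b[[2]])),
    source = m$source
  )
}

#' Extract a truncated attI (Delta-attI) fragment from a reference
#'
#' Returns the fragment a site labelled `position_label` retains: the
#' `|position_label|` reference bases ending at the crossover G plus the
#' 6 nt TTRRRY core remainder downstream of it, i.e.
#' `|position_label| + 6` nt in total.
#'
#' @param reference A [reference_atti()] object.
#' @param position_label Negative integer: crossover-relative upstream
#'   extent of the site (e.g. -11).
#' @return Nucleotide string of the retained fragment.
#' @examples
#' nchar(delta_fragment(atti_reference(1), -11)) # 17
#' @export
delta_fragment <- function(reference, position_label) {
  stopifnot(inherits(reference, "reference_atti"))
  p <- as.integer(position_label)
  if (p >= 0L) stop("position_label must be negative (e.g. -11)")
  g <- reference$crossover_g_index
  if (g + p < 0L) {
    stop("position_label extends beyond the 5' end of the reference")
  }
  if (g + 6L > nchar(reference$sequence)) {
    stop("reference lacks the 6 nt core remainder downstream of the G")
  }
  substring(reference$sequence, g + p + 1L, g + 6L)
}
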