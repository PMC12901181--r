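#' Read a (multi-)FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; sequences are uppercased and
#' record ids are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (wrapped lines and lower case allowed).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write a hit or site table as TSV
#'
#' @param x Data frame (e.g. from [scan_motif()] or the classifiers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert motif hits to a GRanges object
#'
#' @param hits Hit data frame from [scan_motif()].
#' @param feature_type GFF3 feature type to record (column `type`).
#' @return A [GenomicRanges::GRanges] with hit metadata columns.
#' @export
hits_to_granges <- function(hits, feature_type = "nucleotide_motif") {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand
  )
  S4Vectors::mcols(gr)$type <- feature_type
  S4Vectors::mcols(gr)$Name <- hits$motif_name
  S4Vectors::mcols(gr)$matched <- hits$matched
  gr
}

#' Write motif hits as GFF3
#'
#' @inheritParams hits_to_granges
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_gff3 <- function(hits, path, feature_type = "nucleotide_motif") {
  rtracklayer::export(hits_to_granges(hits, feature_type), path,
                      format = "gff3")
  invisible(path)
}

# ---- Minimal GenBank flat-file reader -------------------------------------
# Parses only what the pipeline consumes: LOCUS name, CDS feature locations
# (a..b and complement(a..b); join() records are skipped with a warning) with
# gene/locus_tag/product qualifiers, and the ORIGIN sequence block. This is a
# purposely small reader for IntegronFinder-style annotation files.

#' Read a GenBank flat file (sequence + CDS features)
#'
#' @param path Path to a GenBank flat file.
#' @return List with `id`, `sequence` (character) and `features`
#'   (data frame: `type`, `start`, `end`, `strand`, `gene`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (missing LOCUS line): ", path)
  }
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[1])), "\\s+")[[1]][1]
  feat_from <- which(grepl("^FEATURES", lines))[1]
  orig_from <- which(grepl("^ORIGIN", lines))[1]
  if (is.na(orig_from)) stop("GenBank record has no ORIGIN block: ", path)
  seq_lines <- lines[(orig_from + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank ORIGIN block is empty: ", path)

  feats <- data.frame(type = character(), start = integer(), end = integer(),
                      strand = character(), gene = character(),
                      stringsAsFactors = FALSE)
  if (!is.na(feat_from) && feat_from + 1L < orig_from) {
    block <- lines[(feat_from + 1L):(orig_from - 1L)]
    key_idx <- which(grepl("^ {5}\\S", block))
    for (k in seq_along(key_idx)) {
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      header <- trimws(block[from])
      parts <- strsplit(header, "\\s+")[[1]]
      type <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      if (grepl("join|order", loc)) {
        warning("skipping compound location in ", path, ": ", loc)
        next
      }
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2L) next
      qual_lines <- block[seq(from + 1L, length.out = max(0L, to - from))]
      gene <- NA_character_
      for (qn in c("gene", "locus_tag", "product")) {
        m <- grep(sprintf('^\\s+/%s="?', qn), qual_lines, value = TRUE)
        if (length(m)) {
          gene <- gsub('"', "", sub(sprintf('^\\s+/%s=', qn), "", m[1]))
          break
        }
      }
      feats <- rbind(feats, data.frame(
        type = type, start = min(nums[1:2]), end = max(nums[1:2]),
        strand = strand, gene = gene, stringsAsFactors = FALSE
      ))
    }
  }
  list(id = id, sequence = sequence, features = feats)
}
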