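# Corpus-level orchestration: load many integron records, run site
# detection, classification and array building on each, and aggregate the
# variant counts, ranked unusual-array table, cross-class events and
# tandem statistics. Integron class is always taken from record metadata
# or configuration, never inferred from the integrase sequence.

#' Default pipeline configuration
#'
#' @param ... Named overrides of the defaults: `window` (Delta-attI
#'   ORF-context window, nt), `min_len`/`max_len` (attC span envelope),
#'   `loop_len` (attC central loop), `min_stem_fraction` (attC fold
#'   filter), `tandem_identity`, `tandem_key`, `canonical_ehbs`.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window = 150L, min_len = 57L, max_len = 141L, loop_len = 10L,
    min_stem_fraction = 0.8, tandem_identity = 1.0,
    tandem_key = "full_cassette", canonical_ehbs = canonical_ehb_spec()
  )
  utils::modifyList(cfg, list(...))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return Configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.split_fasta_records <- function(lines) {
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no FASTA records found")
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) lines[starts[i]:ends[i]])
}

.corpus_record <- function(id, class_label, sequence, orfs, source) {
  if (is.null(orfs)) {
    orfs <- data.frame(orf_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  }
  list(id = id, class_label = class_label, sequence = sequence,
       orfs = orfs, source = source)
}

#' Load a corpus of integron records
#'
#' Reads FASTA (sequence only) and GenBank (sequence + CDS features as
#' ORFs) files into a uniform record list. Malformed records are skipped
#' with a logged reason. A `synthetic_corpus` from [generate_corpus()]
#' can be passed directly to [summarize_survey()] instead.
#'
#' @param paths Character vector of FASTA / GenBank file paths.
#' @param class_labels Integron class per record: a single value
#'   recycled to all records, or a named vector keyed by record id
#'   (classes are survey metadata, never inferred from sequence).
#' @return List of records (class `integron_corpus`), each with `id`,
#'   `class_label`, `sequence`, `orfs`, `source`.
#' @export
load_corpus <- function(paths, class_labels = 1) {
  records <- list()
  for (path in paths) {
    if (grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE)) {
      rec <- tryCatch(read_genbank(path), error = function(e) {
        message("skipping malformed GenBank record ", path, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(rec)) next
      cds <- rec$features[rec$features$type == "CDS", , drop = FALSE]
      orfs <- if (nrow(cds)) {
        data.frame(
          orf_id = ifelse(is.na(cds$gene),
                          paste0("cds", seq_len(nrow(cds))), cds$gene),
          start = cds$start, end = cds$end, strand = cds$strand,
          stringsAsFactors = FALSE
        )
      } else NULL
      records[[rec$id]] <- .corpus_record(rec$id, NA, rec$sequence, orfs,
                                          path)
    } else {
      lines <- readLines(path, warn = FALSE)
      for (chunk in .split_fasta_records(lines)) {
        id <- sub("\\s.*$", "", sub("^>", "", chunk[1]))
        seq <- toupper(paste(chunk[-1L], collapse = ""))
        ok <- tryCatch({
          if (!nzchar(seq)) stop("empty sequence")
          .encode_subject(seq)
          TRUE
        }, error = function(e) {
          message("skipping malformed record '", id, "' in ", path, ": ",
                  conditionMessage(e))
          FALSE
        })
        if (ok) records[[id]] <- .corpus_record(id, NA, seq, NULL, path)
      }
    }
  }
  if (!length(records)) stop("no readable records in the given paths")
  ids <- names(records)
  cls <- if (!is.null(names(class_labels))) {
    unname(class_labels[ids])
  } else {
    rep_len(class_labels, length(records))
  }
  for (i in seq_along(records)) records[[i]]$class_label <- cls[i]
  structure(records, class = "integron_corpus")
}

#' Run full site detection and array building on one record
#'
#' Scans for Delta-attI consensus hits (ORF-context filtered when ORF
#' annotations are available), attC core pairs (filtered by fold
#' quality), and exact full-attI matches; Delta-attI calls contained in a
#' full attI span are suppressed (the site is complete, not truncated);
#' then assembles the cassette array.
#'
#' @param record A corpus record (from [load_corpus()] or a
#'   `synthetic_integron`).
#' @param config A [pipeline_config()].
#' @return List with `delta_sites`, `attc_sites`, `atti_sites`, `sites`
#'   (unified table) and `array` (a `cassette_array`).
#' @export
run_detection <- function(record, config = pipeline_config()) {
  id <- if (!is.null(record$id)) record$id else record$integron_id
  seq <- record$sequence
  orfs <- record$orfs
  has_orfs <- !is.null(orfs) && nrow(orfs) > 0L
  if (!has_orfs) {
    warning("record ", id, " has no ORF annotations; ",
            "Delta-attI context filtering disabled")
  }
  delta <- find_delta_atti_cassette_sites(
    seq, orfs, window = config$window, seq_id = id,
    require_context = has_orfs
  )
  attc <- filter_attc_candidates(
    find_core_pairs(seq, min_len = config$min_len,
                    max_len = config$max_len,
                    loop_len = config$loop_len, seq_id = id),
    min_stem_fraction = config$min_stem_fraction
  )
  atti <- rbind(find_full_atti(seq, atti_reference(1), seq_id = id),
                find_full_atti(seq, atti_reference(2), seq_id = id))
  if (nrow(delta) && nrow(atti)) {
    contained <- vapply(seq_len(nrow(delta)), function(i) {
      any(delta$start[i] >= atti$start & delta$end[i] <= atti$end)
    }, logical(1))
    delta <- delta[!contained, , drop = FALSE]
  }
  sites <- sites_table(delta_sites = delta, attc_sites = attc,
                       atti_sites = atti)
  arr <- build_array(sites, orfs, seq, integron_id = id,
                     class_label = record$class_label)
  list(record_id = id, delta_sites = delta, attc_sites = attc,
       atti_sites = atti, sites = sites, array = arr)
}

#' Summarize detection over a whole corpus
#'
#' @param corpus An `integron_corpus` from [load_corpus()] or a
#'   `synthetic_corpus` from [generate_corpus()].
#' @param config A [pipeline_config()].
#' @return Object of class `survey_result`: per-integron detections,
#'   Delta-attI variant `counts` per class, ranked
#'   `array_type_frequencies` of unusual cassettes, `cross_class_events`
#'   (site class differing from the host integron class) and
#'   `tandem_summary`.
#' @export
summarize_survey <- function(corpus, config = pipeline_config()) {
  records <- if (inherits(corpus, "synthetic_corpus")) corpus$records
             else corpus
  detections <- lapply(records, run_detection, config = config)
  names(detections) <- vapply(detections, `[[`, character(1), "record_id")
  host_class <- vapply(records, function(r) as.character(r$class_label),
                       character(1))

  all_delta <- do.call(rbind, lapply(detections, function(d) {
    if (!nrow(d$delta_sites)) return(NULL)
    cbind(integron_id = d$record_id,
          host_class = host_class[[match(d$record_id, names(detections))]],
          d$delta_sites, stringsAsFactors = FALSE)
  }))
  if (is.null(all_delta)) {
    all_delta <- cbind(integron_id = character(), host_class = character(),
                       .empty_delta_sites())
  }

  counts <- if (nrow(all_delta)) {
    agg <- stats::aggregate(list(n = all_delta$label),
                            by = list(label = all_delta$label,
                                      class_label = all_delta$class_label),
                            FUN = length)
    agg[order(-agg$n, agg$label), , drop = FALSE]
  } else {
    data.frame(label = character(), class_label = integer(),
               n = integer())
  }
  rownames(counts) <- NULL

  # ranked unusual-cassette array types (ORF label + its Delta-attI site)
  unusual <- do.call(rbind, lapply(detections, function(d) {
    cs <- d$array$cassettes
    cs <- cs[!is.na(cs$downstream_label) &
               startsWith(cs$downstream_label, "dattI"), , drop = FALSE]
    if (!nrow(cs)) return(NULL)
    data.frame(integron_id = d$record_id,
               array_type = paste(cs$orf_id, cs$downstream_label,
                                  sep = "-"),
               stringsAsFactors = FALSE)
  }))
  array_type_frequencies <- if (!is.null(unusual)) {
    tab <- sort(table(unusual$array_type), decreasing = TRUE)
    data.frame(array_type = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(array_type = character(), n = integer())
  }

  cross <- all_delta[all_delta$host_class %in% c("1", "2") &
                       as.character(all_delta$class_label) !=
                         all_delta$host_class, , drop = FALSE]
  rownames(cross) <- NULL

  tandem <- do.call(rbind, lapply(detections, function(d) {
    runs <- detect_tandem(d$array,
                          identity_threshold = config$tandem_identity,
                          key = config$tandem_key)
    data.frame(integron_id = d$record_id, n_runs = nrow(runs),
               max_run_length = if (nrow(runs)) max(runs$run_length)
                                else 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(tandem) <- NULL

  structure(
    list(detections = detections, delta_sites = all_delta,
         counts = counts,
         array_type_frequencies = array_type_frequencies,
         cross_class_events = cross, tandem_summary = tandem),
    class = "survey_result"
  )
}

#' @export
print.survey_result <- function(x, ...) {
  cat("Integron survey:", length(x$detections), "record(s),",
      nrow(x$delta_sites), "Delta-attI site(s) in",
      nrow(x$counts), "variant bin(s)\n")
  if (nrow(x$counts)) {
    cat("  variants:",
        paste(sprintf("%s (n=%d)", x$counts$label, x$counts$n),
              collapse = ", "), "\n")
  }
  n_tandem <- sum(x$tandem_summary$n_runs > 0)
  cat("  cross-class events:", nrow(x$cross_class_events),
      "| integrons with tandem runs:", n_tandem, "\n")
  invisible(x)
}

#' Write the per-site review table
#'
#' One row per Delta-attI site with its flanking sequence, for optional
#' human inspection (the in-silico analogue of eyeballing the gene
#' cassette context in a sequence viewer).
#'
#' @param survey A `survey_result`.
#' @param corpus The corpus the survey was computed from.
#' @param path Output TSV path.
#' @param flank Flanking length, nt (default 30).
#' @return Invisibly, `path`.
#' @export
write_review_tsv <- function(survey, corpus, path, flank = 30L) {
  records <- if (inherits(corpus, "synthetic_corpus")) corpus$records
             else corpus
  seqs <- vapply(records, `[[`, character(1), "sequence")
  ids <- vapply(records, function(r)
    if (!is.null(r$id)) r$id else r$integron_id, character(1))
  names(seqs) <- ids
  d <- survey$delta_sites
  if (nrow(d)) {
    d$flanking <- vapply(seq_len(nrow(d)), function(i) {
      s <- seqs[[d$integron_id[i]]]
      substring(s, max(1L, d$start[i] - flank),
                min(nchar(s), d$end[i] + flank))
    }, character(1))
  }
  write_tsv(d, path)
}
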