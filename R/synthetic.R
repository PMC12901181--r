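# Ground-truth synthetic integron generator. Builds annotated variable
# regions with planted sites, arrays, tandem duplications and point
# mutations, plus binomial colony-count data, so every pipeline stage can
# be exercised round-trip against a known truth table without downloads.
#
# Layout of a generated record (all features on the forward strand):
#   [pad 30] leading_site { [spacer 10] ORF [spacer 8] downstream_site }...
# The 8 nt stop-to-site spacer keeps every planted Delta-attI well inside
# the default 150 nt ORF-context window. Inter-site filler is uniform
# random nucleotides at GC 0.5. Mutations are substitutions only (no
# indels, so truth coordinates stay stable) and never touch a 7-mer core.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_orf <- function(orf_length) {
  stopifnot(orf_length >= 30L, orf_length %% 3L == 0L)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_int <- orf_length %/% 3L - 2L
  paste0("ATG", paste(sample(codons, n_int, replace = TRUE), collapse = ""),
         "TAA")
}

#' Build a synthetic attC site
#'
#' R'' is the aadB-style GCCTAAC; the arm is a random inverted repeat so
#' that R' is its reverse complement GTTAGGC (a GTTRRRY realization). An
#' optional extrahelical base is inserted into the right arm at a given
#' core-proximal stem offset (`ehb = list(base =, offset =)`, base given
#' as its bottom-strand identity; offset must clear the 7-mer core,
#' i.e. be at least 8).
#'
#' @param arm_ext Non-core arm length in nt (default 20).
#' @param loop_len Central loop length in nt (default 10).
#' @param ehb Optional `list(base =, offset =)`.
#' @return Nucleotide string (57-141 nt for default-compatible choices).
#' @export
make_attc <- function(arm_ext = 20L, loop_len = 10L, ehb = NULL) {
  r2 <- "GCCTAAC"
  arm <- .random_dna(arm_ext)
  loop <- .random_dna(loop_len)
  right <- revcomp(arm)
  if (!is.null(ehb)) {
    stopifnot(is.list(ehb), !is.null(ehb$base), !is.null(ehb$offset))
    if (ehb$offset < 8L || ehb$offset > arm_ext + 7L) {
      stop("EHB offset must lie in the non-core arm (8..arm_ext+7)")
    }
    right_full <- paste0(right, revcomp(r2)) # the detected right arm
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ins_top <- unname(comp[toupper(ehb$base)])
    len_r <- nchar(right_full) + 1L
    pos <- len_r - ehb$offset + 1L # arm position after insertion
    right_full <- paste0(substring(right_full, 1L, pos - 1L), ins_top,
                         substring(right_full, pos, nchar(right_full)))
    return(paste0(r2, arm, loop, right_full))
  }
  paste0(r2, arm, loop, right, revcomp(r2))
}

#' Describe one cassette of a synthetic integron plan
#'
#' @param orf_length ORF length in nt including start and stop codons
#'   (at least 30, multiple of 3).
#' @param downstream_site One of `"attC"`, `"dattI1-<X>"` /
#'   `"dattI2-<X>"` (e.g. `"dattI1-11"` for the site extending to
#'   crossover-relative position -11), `"attI1_full"`, `"attI2_full"`.
#' @param orf_id Gene label (defaults to `orf<i>` at generation time).
#' @param duplicate_of Index of an earlier cassette to copy verbatim
#'   (creates tandem-identical cassettes), or `NA`.
#' @param ehb Optional EHB insertion for attC sites (see [make_attc()]).
#' @return A `cassette_plan` list.
#' @export
cassette_plan <- function(orf_length = 300L, downstream_site = "attC",
                          orf_id = NULL, duplicate_of = NA_integer_,
                          ehb = NULL) {
  if (orf_length < 30L) stop("orf_length must be at least 30 nt")
  if (orf_length %% 3L != 0L) stop("orf_length must be a multiple of 3")
  structure(
    list(orf_length = as.integer(orf_length),
         downstream_site = downstream_site, orf_id = orf_id,
         duplicate_of = as.integer(duplicate_of), ehb = ehb),
    class = "cassette_plan"
  )
}

#' Specify a synthetic integron
#'
#' @param integron_id Record identifier.
#' @param integron_class `1`, `2` or `"SCI"` (recorded as metadata).
#' @param leading_site `"attI1"`, `"attI2"` or `"attC"`.
#' @param cassettes List of [cassette_plan()] entries.
#' @param mutation_rate Per-base substitution probability in `[0, 1)`,
#'   applied outside the 7-mer site cores.
#' @param seed RNG seed for this record.
#' @return A `synthetic_integron_spec`.
#' @export
synthetic_integron_spec <- function(integron_id, integron_class = 1,
                                    leading_site = "attI1",
                                    cassettes = list(cassette_plan()),
                                    mutation_rate = 0, seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate < 1)
  stopifnot(leading_site %in% c("attI1", "attI2", "attC"))
  cassettes <- lapply(cassettes, function(p) {
    if (inherits(p, "cassette_plan")) p else do.call(cassette_plan, p)
  })
  for (p in cassettes) {
    if (!is.na(p$duplicate_of) &&
        (p$duplicate_of < 1L || p$duplicate_of > length(cassettes))) {
      stop("duplicate_of must reference an existing cassette index")
    }
  }
  structure(
    list(integron_id = integron_id, integron_class = integron_class,
         leading_site = leading_site, cassettes = cassettes,
         mutation_rate = mutation_rate, seed = as.integer(seed)),
    class = "synthetic_integron_spec"
  )
}

.parse_site_type <- function(type) {
  if (type == "attC") return(list(kind = "attC"))
  if (type %in% c("attI1_full", "attI2_full")) {
    return(list(kind = "atti_full",
                class_label = as.integer(substring(type, 5L, 5L))))
  }
  m <- regmatches(type, regexec("^dattI([12])(-[0-9]+)$", type))[[1]]
  if (length(m) == 3L) {
    return(list(kind = "delta", class_label = as.integer(m[2]),
                position_label = as.integer(m[3])))
  }
  stop("unknown downstream_site type: ", type)
}

.build_site <- function(type, plan = NULL, refs) {
  info <- .parse_site_type(type)
  if (info$kind == "attC") {
    seq <- make_attc(ehb = plan$ehb)
    list(seq = seq, type = "attC", label = "attC",
         crossover_offset = nchar(seq) - 6L)
  } else if (info$kind == "atti_full") {
    ref <- refs[[info$class_label]]
    list(seq = ref$sequence, type = paste0("attI", info$class_label),
         label = paste0("attI", info$class_label),
         crossover_offset = ref$crossover_g_index)
  } else {
    ref <- refs[[info$class_label]]
    frag <- delta_fragment(ref, info$position_label)
    list(seq = frag, type = paste0("dattI", info$class_label),
         label = delta_label(info$class_label, info$position_label),
         position_label = info$position_label,
         crossover_offset = -info$position_label)
  }
}

#' Generate a synthetic integron with ground truth
#'
#' Deterministic for a fixed spec seed: the same spec generates the same
#' bytes. Sites are built from the bundled references (Delta-attI
#' fragments cut at the requested position; attC arms as inverted repeats
#' with optional EHB insertions); ORFs have proper start/stop codons and
#' no internal in-frame stops; mutations never touch the 7-mer cores.
#'
#' @param spec A [synthetic_integron_spec()].
#' @param pad Leading filler length (default 30 nt).
#' @param spacer_site_orf Filler between a site and the next ORF start
#'   (default 10 nt).
#' @param spacer_orf_site Filler between an ORF stop and its downstream
#'   site (default 8 nt; well inside the 150 nt context window).
#' @return List (class `synthetic_integron`) with `integron_id`,
#'   `class_label`, `sequence`, `orfs` (feature data frame) and `truth`
#'   (`sites`, `tandem_runs`, `array_string`).
#' @export
generate_integron <- function(spec, pad = 30L, spacer_site_orf = 10L,
                              spacer_orf_site = 8L) {
  stopifnot(inherits(spec, "synthetic_integron_spec"))
  refs <- list(atti_reference(1), atti_reference(2))
  .with_seed(spec$seed, {
    # leading block
    lead_type <- if (spec$leading_site == "attC") "attC"
                 else paste0(spec$leading_site, "_full")
    lead <- .build_site(lead_type, refs = refs)
    pieces <- c(.random_dna(pad), lead$seq)
    site_rows <- list()
    orf_rows <- list()
    pos <- pad + 1L
    site_rows[[1L]] <- data.frame(
      cassette_index = 0L, type = lead$type, label = lead$label,
      start = pos, end = pos + nchar(lead$seq) - 1L, strand = "+",
      crossover_g = pos + lead$crossover_offset - 1L,
      stringsAsFactors = FALSE
    )
    pos <- pos + nchar(lead$seq)

    blocks <- list()
    for (i in seq_along(spec$cassettes)) {
      p <- spec$cassettes[[i]]
      if (!is.na(p$duplicate_of)) {
        blocks[[i]] <- blocks[[p$duplicate_of]]
      } else {
        site <- .build_site(p$downstream_site, plan = p, refs = refs)
        sp2 <- .random_dna(spacer_orf_site)
        if (startsWith(site$type, "dattI")) {
          # the planted upstream extent is only truthful if reference
          # identity stops exactly at the fragment junction: force the
          # base before the fragment to differ from the reference base
          ref <- refs[[as.integer(substring(site$type, 6L, 6L))]]
          rp <- ref$crossover_g_index + site$position_label
          if (rp >= 1L && nchar(sp2) > 0L) {
            fb <- substring(ref$sequence, rp, rp)
            if (substring(sp2, nchar(sp2), nchar(sp2)) == fb) {
              repl <- setdiff(c("A", "C", "G", "T"), fb)[1]
              sp2 <- paste0(substring(sp2, 1L, nchar(sp2) - 1L), repl)
            }
          }
        }
        blocks[[i]] <- list(
          sp1 = .random_dna(spacer_site_orf),
          orf = .random_orf(p$orf_length),
          sp2 = sp2,
          site = site,
          orf_id = if (is.null(p$orf_id)) sprintf("orf%02d", i)
                   else p$orf_id
        )
      }
      b <- blocks[[i]]
      orf_start <- pos + nchar(b$sp1)
      orf_end <- orf_start + nchar(b$orf) - 1L
      site_start <- orf_end + nchar(b$sp2) + 1L
      orf_rows[[i]] <- data.frame(
        orf_id = b$orf_id, start = orf_start, end = orf_end, strand = "+",
        cassette_index = i, stringsAsFactors = FALSE
      )
      site_rows[[i + 1L]] <- data.frame(
        cassette_index = i, type = b$site$type, label = b$site$label,
        start = site_start, end = site_start + nchar(b$site$seq) - 1L,
        strand = "+",
        crossover_g = site_start + b$site$crossover_offset - 1L,
        stringsAsFactors = FALSE
      )
      pieces <- c(pieces, b$sp1, b$orf, b$sp2, b$site$seq)
      pos <- site_start + nchar(b$site$seq)
    }
    pieces <- c(pieces, .random_dna(pad))
    sequence <- paste(pieces, collapse = "")
    sites <- do.call(rbind, site_rows)
    orfs <- do.call(rbind, orf_rows)

    # tandem truth: maximal runs of consecutive verbatim-identical blocks
    sig <- vapply(blocks, function(b)
      paste(b$orf, b$sp2, b$site$seq, sep = "|"), character(1))
    runs <- list()
    i <- 1L
    while (i <= length(sig)) {
      j <- i
      while (j < length(sig) && sig[j + 1L] == sig[i]) j <- j + 1L
      if (j > i) {
        runs[[length(runs) + 1L]] <- data.frame(
          start_index = i, run_length = j - i + 1L
        )
      }
      i <- j + 1L
    }
    tandem_runs <- if (length(runs)) do.call(rbind, runs) else
      data.frame(start_index = integer(), run_length = integer())

    # mutation pass: one uniform draw and one replacement draw per base, so
    # the mutated set is nested across increasing rates under a fixed seed
    if (spec$mutation_rate > 0) {
      chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
      L <- length(chars)
      u <- stats::runif(L)
      shift <- sample(1:3, L, replace = TRUE)
      protected <- logical(L)
      for (r in seq_len(nrow(sites))) {
        if (sites$type[r] == "attC") {
          protected[sites$start[r]:(sites$start[r] + 6L)] <- TRUE
          protected[(sites$end[r] - 6L):sites$end[r]] <- TRUE
        } else if (startsWith(sites$type[r], "dattI")) {
          protected[(sites$end[r] - 6L):sites$end[r]] <- TRUE
        } else {
          g <- sites$crossover_g[r]
          protected[g:(g + 6L)] <- TRUE
        }
      }
      mutate <- u < spec$mutation_rate & !protected
      bases <- c("A", "C", "G", "T")
      idx <- match(chars[mutate], bases)
      chars[mutate] <- bases[((idx - 1L + shift[mutate]) %% 4L) + 1L]
      sequence <- paste(chars, collapse = "")
    }

    arr <- c(lead$label,
             as.vector(rbind(orfs$orf_id, sites$label[-1L])))
    structure(
      list(integron_id = spec$integron_id,
           class_label = spec$integron_class,
           sequence = sequence, orfs = orfs,
           truth = list(sites = sites, tandem_runs = tandem_runs,
                        array_string = paste(arr, collapse = "|"))),
      class = "synthetic_integron"
    )
  })
}

#' Generate a corpus of synthetic integrons
#'
#' Per-record seeds are derived deterministically from the master seed
#' (each spec's own seed is overridden), so a different master seed
#' changes every sequence but not the planted composition.
#'
#' @param specs List of [synthetic_integron_spec()].
#' @param seed Master seed (integer).
#' @return List (class `synthetic_corpus`) with `records` and a merged
#'   truth site table `truth_sites`.
#' @export
generate_corpus <- function(specs, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  seed <- as.integer(seed)
  records <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- as.integer((as.numeric(seed) * 7919 + 104729 * i) %%
                            2147483629)
    records[[i]] <- generate_integron(sp)
  }
  names(records) <- vapply(records, `[[`, character(1), "integron_id")
  truth_sites <- do.call(rbind, lapply(records, function(r) {
    cbind(integron_id = r$integron_id, class_label = r$class_label,
          r$truth$sites, stringsAsFactors = FALSE)
  }))
  rownames(truth_sites) <- NULL
  structure(list(records = records, truth_sites = truth_sites),
            class = "synthetic_corpus")
}

#' Simulate colony-PCR assay replicates
#'
#' Each replicate's positive-colony count is drawn binomially
#' (`n_colonies`, `true_p`), emulating picking colonies at random and
#' scoring the event-specific PCR band.
#'
#' @param true_p True per-colony event probability.
#' @param n_replicates Number of biological replicates (default 3).
#' @param n_colonies Colonies screened per replicate (default 30).
#' @param seed RNG seed.
#' @param construct_id,event_type Labels carried into the replicate table.
#' @return Data frame of [assay_replicates()] rows.
#' @export
generate_assay_counts <- function(true_p, n_replicates = 3L,
                                  n_colonies = 30L, seed = 1L,
                                  construct_id = "construct",
                                  event_type = "excision") {
  stopifnot(true_p >= 0, true_p <= 1)
  .with_seed(seed, {
    k <- stats::rbinom(n_replicates, n_colonies, true_p)
    assay_replicates(construct_id, event_type,
                     k_positive = k, n_colonies = n_colonies)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits a multi-FASTA of the sequences, a feature TSV (ORFs) and the
#' truth site TSV.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(corpus$records, `[[`, character(1), "sequence")
  write_fasta(seqs, file.path(dir, "corpus.fa"))
  orfs <- do.call(rbind, lapply(corpus$records, function(r) {
    cbind(integron_id = r$integron_id, r$orfs, stringsAsFactors = FALSE)
  }))
  write_tsv(orfs, file.path(dir, "orfs.tsv"))
  write_tsv(corpus$truth_sites, file.path(dir, "truth_sites.tsv"))
  invisible(dir)
}
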