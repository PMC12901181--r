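# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Brute-force IUPAC matcher: position-by-position set membership using
# expand_iupac(), plain loops, no bit masks. Subject N matches only
# pattern N.
brute_scan_forward <- function(sequence, pattern) {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  n <- length(s)
  m <- length(p)
  hits <- integer()
  if (n < m) return(hits)
  for (start in 1:(n - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      sb <- s[start + j - 1]
      if (sb == "N") {
        if (p[j] != "N") { ok <- FALSE; break }
      } else if (!(sb %in% expand_iupac(p[j]))) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

rc_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]),
                                 collapse = ""))
}

random_dna_chr <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_iupac_pattern <- function(n) {
  paste(sample(names(iupac_codes()), n, replace = TRUE,
               prob = c(rep(4, 4), rep(1, 11))), collapse = "")
}

# Closed-form Welch oracle (textbook formulas, no stats::t.test).
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exhaustive fold oracle: plain recursion over all monotone alignments of
# the left arm against the reversed right arm (match +1 when
# Watson-Crick complementary, aligned mismatch 0, unaligned base -1).
# Exponential; use only for arms <= 7 nt.
fold_score_oracle <- function(arm_left, arm_right) {
  x <- strsplit(toupper(arm_left), "")[[1]]
  y <- rev(strsplit(toupper(arm_right), "")[[1]])
  comp <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
  }
  rec <- function(i, j) {
    if (i > length(x)) return(-(length(y) - j + 1))
    if (j > length(y)) return(-(length(x) - i + 1))
    max(rec(i + 1, j) - 1,
        rec(i, j + 1) - 1,
        rec(i + 1, j + 1) + as.integer(comp(x[i], y[j])))
  }
  rec(1, 1)
}

# Alignment-based fold oracle via Biostrings (established independent
# implementation): global alignment of the left arm against the
# reverse-complemented right arm, match +1, mismatch 0, gap -1 per base.
fold_score_biostrings <- function(arm_left, arm_right) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(arm_left),
    Biostrings::reverseComplement(Biostrings::DNAString(arm_right)),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  as.integer(Biostrings::score(al))
}

# Survey emulation corpus: the published composition, planted exactly.
# 96 Delta-attI1-type cassettes (90 x -11 of which 65 are the
# blaOXA10-dattI1-11 array type, 2 x -12, 2 x -10, 2 x -8) and
# 14 Delta-attI2-type (8 x -11 of which 2 sit in class-1 hosts as
# cross-class events, 2 x -10, 2 x -9, 2 x -238), plus 28 integrons with
# a tandem run (27 of length 2, one of length 4).
survey_emulation_specs <- function() {
  specs <- list()
  add <- function(id, class, lead, plans) {
    specs[[length(specs) + 1]] <<- synthetic_integron_spec(
      id, class, lead, plans
    )
  }
  for (i in 1:65) {
    add(sprintf("c1_oxa_%02d", i), 1, "attI1", list(
      cassette_plan(300, "dattI1-11", orf_id = "blaOXA10"),
      cassette_plan(300, "attC", orf_id = "aadA2")
    ))
  }
  for (i in 1:25) {
    add(sprintf("c1_aadB_%02d", i), 1, "attI1", list(
      cassette_plan(300, "dattI1-11", orf_id = "aadB")
    ))
  }
  k <- 0
  for (v in c("dattI1-12", "dattI1-10", "dattI1-8")) {
    for (i in 1:2) {
      k <- k + 1
      add(sprintf("c1_var_%02d", k), 1, "attI1", list(
        cassette_plan(300, v, orf_id = sprintf("gene%02d", k))
      ))
    }
  }
  for (i in 1:6) {
    add(sprintf("c2_ybeA_%02d", i), 2, "attC", list(
      cassette_plan(300, "dattI2-11", orf_id = "ybeA")
    ))
  }
  k <- 0
  for (v in c("dattI2-10", "dattI2-9", "dattI2-238")) {
    for (i in 1:2) {
      k <- k + 1
      add(sprintf("c2_var_%02d", k), 2, "attC", list(
        cassette_plan(300, v, orf_id = sprintf("orf2_%02d", k))
      ))
    }
  }
  for (i in 1:2) { # cross-class: Delta-attI2 cassette inside a class-1 host
    add(sprintf("c1_cross_%02d", i), 1, "attI1", list(
      cassette_plan(300, "dattI2-11", orf_id = "ybeA")
    ))
  }
  for (i in 1:27) {
    add(sprintf("c1_tand2_%02d", i), 1, "attI1", list(
      cassette_plan(150, "attC", orf_id = "aadB"),
      cassette_plan(150, "attC", orf_id = "aadB", duplicate_of = 1)
    ))
  }
  add("c1_tand4_01", 1, "attI1", list(
    cassette_plan(150, "attC", orf_id = "blaGES24"),
    cassette_plan(150, "attC", orf_id = "blaGES24", duplicate_of = 1),
    cassette_plan(150, "attC", orf_id = "blaGES24", duplicate_of = 1),
    cassette_plan(150, "attC", orf_id = "blaGES24", duplicate_of = 1)
  ))
  specs
}
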