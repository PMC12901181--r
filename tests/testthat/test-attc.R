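# attC candidates, arm-alignment folding and EHB calling.

test_that("find_core_pairs keeps only in-envelope (R'', R') pairs", {
  set.seed(3)
  # aadB-style R'' with a matching R' 60 nt downstream (outer span 64)
  arm <- random_dna_chr(20)
  site <- paste0("GCCTAAC", arm, random_dna_chr(10), rc_chr(arm),
                 "GTTAGGC")
  # neutral poly-T flanks: no accidental cores outside the construct
  seqn <- paste0(strrep("T", 25), site, strrep("T", 25))
  cand <- find_core_pairs(seqn)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$total_length, 64L)
  expect_equal(cand$crossover_g, cand$r1_start)
  expect_equal(cand$r2_matched, "GCCTAAC")

  # the R''-inactivating point modification (GCCTAAC -> GCCTAGG)
  site_dead <- sub("GCCTAAC", "GCCTAGG", site)
  expect_equal(nrow(find_core_pairs(paste0(strrep("T", 25), site_dead,
                                           strrep("T", 25)))), 0L)

  # cores separated beyond the 141 bound
  far <- paste0("GCCTAAC", strrep("T", 186), "GTTAGGC")
  expect_equal(nrow(find_core_pairs(far)), 0L)
  # and below the 57 bound
  near <- paste0("GCCTAAC", strrep("T", 20), "GTTAGGC")
  expect_equal(nrow(find_core_pairs(near)), 0L)
})

test_that("perfect inverted-repeat arms fold fully with no EHBs", {
  set.seed(11)
  for (k in c(7, 10, 20)) {
    arm <- random_dna_chr(k)
    f <- fold_arms(arm, rc_chr(arm))
    expect_equal(f$stem_score, k)
    expect_equal(f$n_paired, k)
    expect_equal(f$n_ehb, 0L)
    # every reported pair is Watson-Crick complementary
    la <- strsplit(arm, "")[[1]]
    ra <- strsplit(rc_chr(arm), "")[[1]]
    pair_ok <- chartr("ACGT", "TGCA", la[f$pairs$left_pos]) ==
      ra[f$pairs$right_pos]
    expect_true(all(pair_ok))
  }
})

test_that("inserted bases surface as exactly that many EHBs", {
  set.seed(21)
  arm <- random_dna_chr(10)
  right <- rc_chr(arm)
  # one insertion
  r1 <- paste0(substring(right, 1, 4), "A", substring(right, 5))
  f1 <- fold_arms(arm, r1)
  expect_equal(f1$n_ehb, 1L)
  expect_equal(f1$stem_score, 10L - 1L)
  expect_equal(f1$n_paired, 10L)
  # two independent insertions: two EHBs, two gap penalties
  r2 <- paste0(substring(r1, 1, 8), "C", substring(r1, 9))
  f2 <- fold_arms(arm, r2)
  expect_equal(f2$n_ehb, 2L)
  expect_equal(f2$stem_score, 10L - 2L)
  # EHB positions are disjoint from paired positions on the same arm
  right_ehbs <- f2$ehbs$pos[f2$ehbs$arm == "right"]
  expect_length(intersect(right_ehbs, f2$pairs$right_pos), 0L)
})

test_that("fold score matches the exhaustive recursion oracle (short arms)", {
  set.seed(31)
  for (rep in 1:12) {
    a <- random_dna_chr(sample(4:7, 1))
    b <- random_dna_chr(sample(4:7, 1))
    expect_equal(fold_arms(a, b)$stem_score, fold_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("fold score matches an independent global aligner (arms <= 12)", {
  set.seed(37)
  for (rep in 1:25) {
    a <- random_dna_chr(sample(7:12, 1))
    b <- random_dna_chr(sample(7:12, 1))
    expect_equal(fold_arms(a, b)$stem_score, fold_score_biostrings(a, b),
                 info = paste(a, b))
  }
  # also on near-palindromic arms with planted bulges
  for (rep in 1:10) {
    arm <- random_dna_chr(sample(8:11, 1))
    right <- rc_chr(arm)
    at <- sample(nchar(right) - 1, 1)
    right <- paste0(substring(right, 1, at), sample(c("A", "C", "G", "T"), 1),
                    substring(right, at + 1))
    expect_equal(fold_arms(arm, right)$stem_score,
                 fold_score_biostrings(arm, right))
  }
})

test_that("fold symmetry: swapping reverse-complemented arms mirrors pairs", {
  set.seed(41)
  for (rep in 1:8) {
    arm <- random_dna_chr(9)
    right <- rc_chr(arm)
    at <- sample(8, 1)
    right <- paste0(substring(right, 1, at), "G", substring(right, at + 1))
    f <- fold_arms(arm, right)
    g <- fold_arms(rc_chr(right), rc_chr(arm))
    expect_equal(g$stem_score, f$stem_score)
    # mirrored pairing: (i, j) <-> (len_right - j + 1, len_left - i + 1)
    mirrored <- data.frame(
      left_pos = nchar(right) - f$pairs$right_pos + 1L,
      right_pos = nchar(arm) - f$pairs$left_pos + 1L
    )
    mirrored <- mirrored[order(mirrored$left_pos), ]
    rownames(mirrored) <- NULL
    expect_equal(g$pairs, mirrored)
  }
})

test_that("adding an EHB never increases the stem score", {
  set.seed(47)
  for (rep in 1:10) {
    arm <- random_dna_chr(10)
    right <- rc_chr(arm)
    base_score <- fold_arms(arm, right)$stem_score
    at <- sample(9, 1)
    right_ins <- paste0(substring(right, 1, at),
                        sample(c("A", "C", "G", "T"), 1),
                        substring(right, at + 1))
    expect_lte(fold_arms(arm, right_ins)$stem_score, base_score)
  }
})

test_that("wobble option counts G.T pairs as paired", {
  expect_equal(fold_arms("GGGG", "TTTT")$stem_score, 0L)
  expect_equal(fold_arms("GGGG", "TTTT", wobble = TRUE)$stem_score, 4L)
})

test_that("canonical EHB check reports presence and names the missing", {
  set.seed(53)
  cfg <- canonical_ehb_spec(list(list(base = "G", offset = 9L),
                                 list(base = "T", offset = 13L)))
  # build a site carrying the G EHB only
  s1 <- make_attc(ehb = list(base = "G", offset = 9L))
  f1 <- fold_bottom_strand(find_core_pairs(s1)[1, ])
  chk1 <- check_canonical_ehbs(f1, cfg)
  expect_false(chk1$ok)
  expect_length(chk1$missing, 1L)
  expect_match(chk1$missing, "^T at")
  # a perfect palindrome misses both
  arm <- random_dna_chr(12)
  f0 <- fold_arms(arm, rc_chr(arm))
  chk0 <- check_canonical_ehbs(f0, cfg)
  expect_false(chk0$ok)
  expect_length(chk0$missing, 2L)
  # both planted EHBs present -> TRUE (build the right arm by direct
  # insertion: right-arm offsets count from the arm's 3' core end, so a
  # 14 nt arm holds offset 13 at position 2 and offset 9 at position 6;
  # bottom-strand G/T correspond to top-strand C/A insertions)
  ins <- function(s, at, b) paste0(substring(s, 1, at), b,
                                   substring(s, at + 1))
  right2 <- ins(ins(rc_chr(arm), 1, "A"), 5, "C")
  f2 <- fold_arms(arm, right2)
  chk2 <- check_canonical_ehbs(f2, cfg)
  expect_true(chk2$ok)
  expect_error(check_canonical_ehbs(f1, list()), "canonical EHB")
})

test_that("dot-bracket rendering spans the candidate and balances", {
  set.seed(61)
  s <- make_attc()
  cand <- find_core_pairs(s)[1, ]
  f <- fold_bottom_strand(cand)
  db <- fold_dotbracket(cand, f)
  expect_equal(nchar(db), cand$total_length)
  expect_equal(sum(strsplit(db, "")[[1]] == "("),
               sum(strsplit(db, "")[[1]] == ")"))
  expect_error(fold_bottom_strand(list(arm_left = "ACGT",
                                       arm_right = "ACGTACG")),
               "shorter than")
})
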