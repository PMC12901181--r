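make_context <- function(fragment, left = "TTGCTT", right = "GATCGA") {
  paste0(left, fragment, right)
}

classify_fragment <- function(reference, position_label,
                              left = "TTGCTT") {
  frag <- delta_fragment(reference, position_label)
  # the flank must not extend the reference-identity run past the junction
  rp <- reference$crossover_g_index + position_label
  if (rp >= 1) {
    fb <- substring(reference$sequence, rp, rp)
    if (substring(left, nchar(left), nchar(left)) == fb) {
      left <- paste0(substring(left, 1, nchar(left) - 1),
                     setdiff(c("A", "C", "G", "T"), fb)[1])
    }
  }
  ctx <- make_context(frag, left = left)
  motif <- integron_motifs()[[paste0("dattI", reference$class_label)]]
  hits <- scan_motif(ctx, motif, strand = "forward")
  expect_equal(nrow(hits), 1L)
  classify_delta_atti(hits, ctx, reference)
}

test_that("bundled references satisfy their structural invariants", {
  r1 <- atti_reference(1)
  expect_equal(nchar(r1$sequence), 65L)
  expect_equal(substring(r1$sequence, r1$crossover_g_index,
                         r1$crossover_g_index), "G")
  lb <- r1$boxes$L_box
  expect_equal(substring(r1$sequence, lb["start"], lb["end"]), "CCCTAAA")
  r2 <- atti_reference(2)
  expect_equal(substring(r2$sequence, r2$crossover_g_index,
                         r2$crossover_g_index), "G")
  expect_gte(r2$crossover_g_index, 238L) # supports the deepest site
  expect_error(reference_atti(1, "AAAA", 2), "must be G")
})

test_that("classifier reproduces every printed (position, length) pair", {
  r1 <- atti_reference(1)
  r2 <- atti_reference(2)
  cases1 <- list(c(-12, 18), c(-11, 17), c(-10, 16), c(-8, 14))
  cases2 <- list(c(-11, 17), c(-10, 16), c(-9, 15), c(-238, 244))
  for (cs in cases1) {
    site <- classify_fragment(r1, cs[1])
    expect_equal(site$position_label, cs[1])
    expect_equal(site$retained_length, cs[2])
  }
  for (cs in cases2) {
    site <- classify_fragment(r2, cs[1])
    expect_equal(site$position_label, cs[1])
    expect_equal(site$retained_length, cs[2])
  }
})

test_that("retained length always equals |position| + 6", {
  r1 <- atti_reference(1)
  for (p in seq(-8L, -40L)) {
    site <- classify_fragment(r1, p)
    expect_equal(site$retained_length, -site$position_label + 6L)
    expect_equal(site$retained_length, nchar(delta_fragment(r1, p)))
  }
})

test_that("truncating the fragment by one base shifts the label by one", {
  r2 <- atti_reference(2)
  for (p in c(-20L, -100L, -238L)) {
    deep <- classify_fragment(r2, p)
    shallow <- classify_fragment(r2, p + 1L)
    expect_equal(deep$retained_length - shallow$retained_length, 1L)
    expect_equal(deep$position_label, shallow$position_label - 1L)
  }
})

test_that("classification is deterministic and strand-aware", {
  r1 <- atti_reference(1)
  frag <- delta_fragment(r1, -11)
  ctx <- make_context(frag)
  motif <- integron_motifs()$dattI1
  h <- scan_motif(ctx, motif, strand = "forward")
  s1 <- classify_delta_atti(h, ctx, r1)
  s2 <- classify_delta_atti(h, ctx, r1)
  expect_identical(s1, s2)
  # same fragment planted on the minus strand
  ctx_rc <- rc_chr(ctx)
  h_rc <- scan_motif(ctx_rc, motif, strand = "both")
  expect_equal(h_rc$strand, "-")
  s3 <- classify_delta_atti(h_rc, ctx_rc, r1)
  expect_equal(s3$position_label, -11L)
  expect_equal(s3$retained_length, 17L)
  # fragment coordinates map back to the forward strand
  expect_equal(substring(ctx_rc, s3$start, s3$end), rc_chr(frag))
})

test_that("a contig edge inside the upstream walk sets the truncation flag", {
  r2 <- atti_reference(2)
  frag <- delta_fragment(r2, -30) # 36 nt
  ctx <- substring(frag, 11) # cut 10 upstream bases away
  h <- scan_motif(ctx, integron_motifs()$dattI2, strand = "forward")
  site <- classify_delta_atti(h, ctx, r2)
  expect_true(site$truncated)
  expect_equal(site$position_label, -20L)
  # class mismatch is rejected
  expect_error(classify_delta_atti(h, ctx, atti_reference(1)),
               "does not match")
})

test_that("ORF-context filtering keeps cassette sites and drops the rest", {
  spec <- synthetic_integron_spec("ctx1", 1, "attI1", list(
    cassette_plan(300, "dattI1-11", orf_id = "aadB")
  ), seed = 5)
  g <- generate_integron(spec)
  sites <- find_delta_atti_cassette_sites(g$sequence, g$orfs,
                                          seq_id = "ctx1")
  truth <- g$truth$sites[g$truth$sites$type == "dattI1", ]
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$orf_id, "aadB")
  expect_equal(sites$label, "dattI1-11")
  expect_equal(sites$start, truth$start)
  expect_equal(sites$end, truth$end)

  # the same 14-nt consensus embedded mid-ORF is excluded
  frag <- delta_fragment(atti_reference(1), -8)
  orf_with_motif <- paste0("ATG", frag, "A", strrep("GCA", 20), "TAA")
  seqn <- paste0("TTTTTT", orf_with_motif, "TTTTTT")
  orfs <- data.frame(orf_id = "orfX", start = 7L,
                     end = 6L + nchar(orf_with_motif), strand = "+")
  expect_equal(
    nrow(find_delta_atti_cassette_sites(seqn, orfs, seq_id = "s")), 0L
  )

  # two cassettes each followed by the same variant: two sites in order
  spec2 <- synthetic_integron_spec("ctx2", 2, "attC", list(
    cassette_plan(300, "dattI2-11", orf_id = "ybeA"),
    cassette_plan(300, "dattI2-11", orf_id = "orfB")
  ), seed = 6)
  g2 <- generate_integron(spec2)
  sites2 <- find_delta_atti_cassette_sites(g2$sequence, g2$orfs,
                                           seq_id = "ctx2")
  expect_equal(sites2$orf_id, c("ybeA", "orfB"))
  expect_equal(sites2$label, c("dattI2-11", "dattI2-11"))
  expect_false(is.unsorted(sites2$start))

  # missing annotations are rejected with guidance
  expect_error(find_delta_atti_cassette_sites(g$sequence, NULL),
               "ORF annotations")
})

test_that("derive_consensus takes minimal IUPAC codes over column unions", {
  # every RRRY column must see both a purine pair and be covered: a
  # column observing only {G} stays G (minimal code), so the two
  # realizations are chosen to cover {A,G} at each R column
  expect_equal(derive_consensus(c("AAACAAAGTTAGAC", "AAACAAAGTTGAGT")),
               "AAACAAAGTTRRRY")
  expect_equal(derive_consensus(c("AAACAAAGTTAGAC", "AAACAAAGTTGGGT")),
               "AAACAAAGTTRGRY")
  expect_equal(derive_consensus("ACGT"), "ACGT")
  expect_equal(derive_consensus(c("AAAA", "CCCC", "GGGG", "TTTT")),
               "NNNN")
  expect_equal(derive_consensus(c("AC", "GT")), "RY")
  expect_error(derive_consensus(character(0)), "at least one")
  expect_error(derive_consensus(c("AC", "ACG")), "equal length")
})

test_that("planted consensus instances re-derive the printed consensus", {
  # realize the degenerate RRRY tail in several ways and re-derive
  tails <- c("AGAC", "GAGT", "AAAC", "GGGT")
  inst1 <- paste0("AAACAAAGTT", tails)
  expect_equal(derive_consensus(inst1), "AAACAAAGTTRRRY")
  inst2 <- paste0("AATAAAATGTT", tails)
  expect_equal(derive_consensus(inst2), "AATAAAATGTTRRRY")
})
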