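# Corpus loading and survey aggregation.

write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

test_that("load_corpus reads multi-FASTA and assigns class metadata", {
  fa <- write_lines(c(
    ">intA class 1 record", "ACGTACGTACGT", "ACGT",
    ">intB", "ttttgggg"
  ), tempfile(fileext = ".fa"))
  corpus <- load_corpus(fa, class_labels = c(intA = 1, intB = 2))
  expect_length(corpus, 2L)
  expect_equal(corpus$intA$sequence, "ACGTACGTACGTACGT")
  expect_equal(corpus$intB$sequence, "TTTTGGGG") # case-folded
  expect_equal(corpus$intB$class_label, 2)
})

test_that("load_corpus exposes GenBank CDS features as ORFs", {
  gb <- write_lines(c(
    "LOCUS       testrec       60 bp    DNA     linear   BCT",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..22",
    '                     /gene="aadB"',
    "     CDS             complement(30..47)",
    '                     /locus_tag="orfX"',
    "     CDS             50..58",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac",
    "       51 acgtacgtac",
    "//"
  ), tempfile(fileext = ".gb"))
  corpus <- load_corpus(gb, class_labels = 1)
  rec <- corpus[[1]]
  expect_equal(rec$id, "testrec")
  expect_equal(nchar(rec$sequence), 60L)
  expect_equal(nrow(rec$orfs), 3L)
  expect_equal(rec$orfs$orf_id[1:2], c("aadB", "orfX"))
  expect_equal(rec$orfs$strand, c("+", "-", "+"))
})

test_that("malformed records are skipped with a logged reason", {
  fa <- write_lines(c(
    ">ok1", "ACGTACGT",
    ">bad", "ACGT??GT",
    ">ok2", "GGGGCCCC",
    ">empty", "",
    ">ok3", "ATATATAT"
  ), tempfile(fileext = ".fa"))
  expect_message(corpus <- load_corpus(fa), "skipping malformed")
  expect_length(corpus, 3L)
  expect_setequal(names(corpus), c("ok1", "ok2", "ok3"))
  expect_error(suppressMessages(
    load_corpus(write_lines(c(">x", "??"), tempfile(fileext = ".fa")))
  ), "no readable records")
})

test_that("summarize recovers a small planted composition exactly", {
  specs <- list(
    synthetic_integron_spec("i1", 1, "attI1",
                            list(cassette_plan(300, "dattI1-11",
                                               orf_id = "aadB"))),
    synthetic_integron_spec("i2", 1, "attI1",
                            list(cassette_plan(300, "dattI1-11",
                                               orf_id = "aadB"))),
    synthetic_integron_spec("i3", 1, "attI1",
                            list(cassette_plan(300, "dattI1-11",
                                               orf_id = "blaOXA10"))),
    synthetic_integron_spec("i4", 2, "attC",
                            list(cassette_plan(300, "dattI2-11",
                                               orf_id = "ybeA")))
  )
  corpus <- generate_corpus(specs, seed = 77)
  sv <- summarize_survey(corpus)
  expect_equal(sv$counts$n[sv$counts$label == "dattI1-11"], 3L)
  expect_equal(sv$counts$n[sv$counts$label == "dattI2-11"], 1L)
  # every counted site is in exactly one bin and sums match detections
  expect_equal(sum(sv$counts$n), nrow(sv$delta_sites))
  # array-type table counts each unusual cassette once
  expect_equal(sum(sv$array_type_frequencies$n), 4L)
  expect_equal(sv$array_type_frequencies$n[
    sv$array_type_frequencies$array_type == "aadB-dattI1-11"], 2L)
  expect_equal(nrow(sv$cross_class_events), 0L)
})

test_that("an empty corpus summarizes to all-zero results", {
  specs <- list(
    synthetic_integron_spec("plain", 1, "attI1",
                            list(cassette_plan(300, "attC",
                                               orf_id = "aadB")))
  )
  sv <- summarize_survey(generate_corpus(specs, seed = 5))
  expect_equal(nrow(sv$counts), 0L)
  expect_equal(sum(sv$array_type_frequencies$n), 0L)
  expect_equal(nrow(sv$cross_class_events), 0L)
})

test_that("cross-class sites are flagged against the host class", {
  specs <- list(
    synthetic_integron_spec("host1", 1, "attI1",
                            list(cassette_plan(300, "dattI2-11",
                                               orf_id = "ybeA"))),
    synthetic_integron_spec("host2", 2, "attC",
                            list(cassette_plan(300, "dattI2-11",
                                               orf_id = "ybeA")))
  )
  sv <- summarize_survey(generate_corpus(specs, seed = 21))
  expect_equal(nrow(sv$cross_class_events), 1L)
  expect_equal(sv$cross_class_events$integron_id, "host1")
  expect_equal(sv$cross_class_events$label, "dattI2-11")
})

test_that("survey results are invariant to record order", {
  specs <- list(
    synthetic_integron_spec("r1", 1, "attI1",
                            list(cassette_plan(300, "dattI1-11",
                                               orf_id = "aadB"))),
    synthetic_integron_spec("r2", 1, "attI1",
                            list(cassette_plan(300, "dattI1-8",
                                               orf_id = "catB"))),
    synthetic_integron_spec("r3", 2, "attC",
                            list(cassette_plan(300, "dattI2-238",
                                               orf_id = "aadB")))
  )
  corpus <- generate_corpus(specs, seed = 33)
  rev_corpus <- corpus
  rev_corpus$records <- rev(corpus$records)
  sv1 <- summarize_survey(corpus)
  sv2 <- summarize_survey(rev_corpus)
  norm <- function(d) {
    d <- d[order(d$label, d$class_label), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(norm(sv1$counts), norm(sv2$counts))
  expect_equal(sv1$array_type_frequencies[
    order(sv1$array_type_frequencies$array_type), "n"],
    sv2$array_type_frequencies[
      order(sv2$array_type_frequencies$array_type), "n"])
})

test_that("the review table carries flanking sequence for each site", {
  corpus <- generate_corpus(list(
    synthetic_integron_spec("rv1", 1, "attI1",
                            list(cassette_plan(300, "dattI1-11",
                                               orf_id = "aadB")))
  ), seed = 41)
  sv <- summarize_survey(corpus)
  path <- tempfile(fileext = ".tsv")
  write_review_tsv(sv, corpus, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 1L)
  expect_true(nchar(tab$flanking) > tab$end - tab$start + 1L)
  expect_true(grepl(substring(corpus$records$rv1$sequence,
                              tab$start, tab$end),
                    tab$flanking, fixed = TRUE))
})
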