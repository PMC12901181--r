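---
title: "Detecting unusual recombination sites in integron cassette arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unusual recombination sites in integron cassette arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integronArrays)
```

## The problem

Integrons are bacterial genetic platforms in which an integrase (IntI)
shuffles mobile gene cassettes in and out of a variable region by
site-specific recombination. A canonical cassette is one ORF followed by an
*attC* recombination site; the platform itself carries the primary *attI*
site next to the integrase gene. Besides these canonical sites, variable
regions of clinical class 1 and class 2 integrons harbour *unusual*
cassettes in which the expected *attC* has been replaced by a truncated
fragment of an *attI* site — a ΔattI site — producing
attI–ORF–ΔattI or attC–ORF–ΔattI architectures. This package provides a
tested, reusable pipeline for the in-silico side of that biology:

* degenerate (IUPAC) motif scanning — the primitive under all site
  detection;
* detection and crossover-relative classification of ΔattI1/ΔattI2 sites;
* *attC* site modelling by bottom-strand arm alignment with
  extrahelical-base (EHB) calling;
* cassette-array assembly, architecture typing and tandem-duplicate
  detection;
* corpus-level survey summaries;
* replicate frequency statistics for in vivo recombination assays
  (mean ± SD over colony-PCR replicates, pairwise Welch's *t*-tests,
  significance letter groups);
* a ground-truth synthetic integron generator that makes every stage
  testable round-trip without downloads.

## Site anatomy and the coordinate convention

An *attC* site is delimited by the inverse core site R″ (consensus
`RYYYAAC`) and the core site R′ (consensus `GTTRRRY`), 57–141 bp apart.
The recombination crossover lies between the first (G) and second
nucleotides of R′. The class 1 *attI1* site is 65 bp, with the L box
`CCCTAAA`, an R box realizing `GTTRRRY`, two direct repeats upstream, and
the crossover G closing a −56 upstream extent.

A ΔattI site is the minimal conserved consensus —
`AAACAAAGTTRRRY` (14 nt) for ΔattI1, `AATAAAATGTTRRRY` (15 nt) for
ΔattI2 — plus however many additional bases upstream of it are identical
to the reference *attI* 3′ end. Sites are labelled by the
crossover-relative position −X at which that identity run ends, and the
package enforces the single convention consistent with all printed
(position, length) pairs:

```
retained_length = |position_label| + 6
```

The crossover G is the innermost counted upstream position, and the 6 nt
`TTRRRY` downstream complete the core. So a site whose fragment spans
17 nt is ΔattI1~−11~; the bare 14-nt consensus is the class floor
ΔattI1~−8~ (15 nt and −9 for class 2). The deepest class 2 variant,
ΔattI2~−238~, retains 244 nt.

```{r convention}
r1 <- atti_reference(1)
nchar(delta_fragment(r1, -11)) # 17
nchar(delta_fragment(r1, -8))  # 14 = length of the minimal consensus
```

Note that the *full* attI1 site does not follow the Δ rule: 65 bp with a
−56 extent implies a 9 nt downstream tail (56 + 9 = 65), which is why the
bundled references store an explicit `crossover_g_index` instead of
deriving it.

### Bundled references are synthetic stand-ins

The package was developed without network access, so the bundled attI1
and attI2 references (`inst/extdata/atti_references_synthetic.*`) are
*constructed* sequences, labelled synthetic in filename and metadata.
They satisfy every structural constraint the classifier relies on
(lengths 65 and 311 bp; boxes; crossover G; the consensus-compatible
3′ ends) and were screened so that no unintended core or consensus motif
occurs in them. All classifier arithmetic — the only thing the
acceptance checks quantify — depends on the position↔length convention,
not on the literal reference bases. Users analysing real records should
construct references from the GenBank-derived sites with
`reference_atti()`.

## The scanner

`scan_motif()` is a bit-mask matcher over the 15 IUPAC codes, reporting
all (overlapping) hits on either strand in 1-based inclusive forward
coordinates. Two deliberate choices:

* **Subject `N` matches only pattern `N`.** The sites this pipeline
  targets are exact-sequence curated; treating sequencing `N`s as
  wildcards would manufacture matches. (This is why the scanner is not a
  thin wrapper over `Biostrings::matchPattern(fixed = FALSE)`, whose
  subject-ambiguity semantics are wildcard-like.)
* **Mismatch budget defaults to 0.** The original screening tolerated
  deviations through *human* curation, not algorithmically; a
  `max_mismatch` knob exists for exploratory scans.

The scanner is verified in the test suite against a brute-force
position-by-position oracle on random sequences, plus strand-mirror and
degeneracy-monotonicity property checks.

## ΔattI classification

`classify_delta_atti()` anchors a consensus hit to the reference: it
walks upstream base-by-base, requiring exact identity (the surveyed
sites are reported at 100% identity; a mismatch-tolerant mode exists but
is off by default), until the first mismatch, the reference's 5′ end, or
a contig edge (which sets a `truncated` flag). The matched run fixes
`position_label` and `retained_length`.

`find_delta_atti_cassette_sites()` adds the ORF-context filter that
replaces manual curation: a site is only reported if its retained
fragment *starts* within a window (default 150 nt) downstream of an ORF
stop codon, in the ORF's orientation, and does not overlap an ORF. The
filter keys on the fragment start, not the consensus match, because in
deeply extended sites (ΔattI2~−238~) the consensus sits hundreds of
bases past the stop codon while the attI-derived region still begins
immediately after it. For optional human review,
`write_review_tsv()` emits every call with flanking sequence.

Whether the original screening scanned both strands is not stated; the
package scans both and relies on orientation normalisation in the array
builder, which is the conservative choice (minus-strand hits are
context-filtered against minus-strand ORFs).

## attC folding and EHBs

`find_core_pairs()` enumerates every ordered (R″, R′) pair whose outer
span lies in [57, 141] bp. Arms are the cores plus the adjacent interior
bases after reserving a central loop (default 10 nt); when the interior
is odd the right arm takes the extra base, so a single-base bulge is
recovered intact.

`fold_bottom_strand()` models the hairpin as a **global alignment** of
the left arm against the reverse-complemented right arm: +1 for a
Watson–Crick pair, 0 for an aligned non-complementary pair, −1 per
unaligned (gapped) base. Gapped bases are the EHBs, reported with their
bottom-strand identity and core-proximal stem offset. This is a
pairing-topology model, not a thermodynamic fold: the structural claims
the pipeline makes concern which bases are extruded from the stem, not
free energies (thermodynamic folding in the source analyses was
display-only). Design details:

* **Tie-break:** among equal-score alignments the traceback prefers the
  diagonal from the loop-distal corner, which places gaps closest to the
  core-proximal end; deterministic.
* **G·T wobble pairs** count as unpaired by default (`wobble = TRUE` to
  change), since EHB definitions in the literature are Watson–Crick
  based.
* `stem_score` = paired count − gap count; a perfect inverted repeat of
  length *k* scores exactly *k*. The fold is verified against an
  exhaustive enumeration oracle on short arms and against an
  independent global aligner on arms up to 12 nt.

`check_canonical_ehbs()` tests for the two EHBs required for canonical
single-stranded recognition. Their identities and offsets ship as a
configurable default (`canonical_ehb_spec()`: G at stem offset 9, T at
13, ±1) — these are literature-derived configuration values chosen to be
consistent with the generator's fold geometry, **not** quantities this
package measures; anyone holding reference folds for specific sites
should calibrate the spec against them.

Spurious core pairings in random sequence are common enough to matter
(≈1 chance in 10³ per position for each 7-mer), so the pipeline filters
candidates by fold quality: `filter_attc_candidates()` keeps a candidate
when `stem_score ≥ 0.8 × max(arm length)`. True inverted-repeat arms
score ≈1.0 (≈0.93 with one EHB); unrelated arms align far below 0.8.

## Arrays and tandem runs

`build_array()` forms one cassette per ORF flanked by its nearest
upstream and downstream sites; boundaries are crossover G positions, so
consecutive cassettes tile the variable region. ORFs with no upstream
flank are orphans; a missing downstream flank (contig edge) yields a
`-truncated` architecture. Records whose leading attI lies on the minus
strand are flipped (and the flip logged) so arrays read 5′→3′ from the
attI end. ΔattI calls contained in a full attI span are suppressed
upstream in `run_detection()` — the site is complete, not truncated.

`detect_tandem()` reports maximal runs of ≥2 consecutive cassettes whose
keyed sequences are pairwise identical at or above a threshold. The key
defaults to the full cassette (ORF + downstream site) at threshold 1.0 —
the strict reading of "identical" — with an ORF-only key and relaxed
thresholds available because repeat-identity screens of sedentary
chromosomal integrons key on the repeat, not the cargo. Identity is
length-normalised global identity (`pairwiseAlignment` matches divided
by the longer sequence).

## Assay statistics

The analysis unit is the per-replicate proportion k/n (30 colonies per
replicate, ≥3 biological replicates), exactly as a mean ± SD over
replicates implies — never pooled counts. `estimate_frequency()` uses
the n−1 sample SD. `welch_t_test()` wraps `stats::t.test(var.equal =
FALSE)` and defines the degenerate zero-variance cases explicitly
(100% vs 100% comparisons arise naturally in these assays): equal means
→ t = 0, p = 1; unequal constant samples → flagged degenerate with a
warning. p-values are two-sided. No multiplicity correction is applied
by default — the source analyses report plain pairwise tests — with a
Holm option exposed (`pairwise_welch(adjust = "holm")`).

`group_letters()` assigns significance letters as the maximal cliques of
the non-significance graph (constructs share a letter iff no pair within
the lettered set is significant), ordered deterministically by smallest
member index; a construct straddling two groups gets both letters
("ab"). The test suite also measures the empirical type-I error of the
Welch test on equal-p binomial groups (n = 3 replicates of 30 colonies,
10,000 simulations): with such small samples the realised level sits
below nominal (the observed rate is accepted in a documented 0.01–0.09
band), which is stated here rather than hidden.

## The synthetic generator

`generate_integron()` builds a variable region as
`[pad] leading_site {spacer ORF spacer site}...` with all features on
the forward strand and a truth table of every planted feature. Choices
that matter:

* Inter-site filler is uniform random nucleotides at GC 0.5; ORFs have
  proper start/stop codons and no internal in-frame stops.
* attC sites default to 7-mer cores plus 20 nt inverted-repeat arms and
  a 10 nt loop (64 bp total, inside the 57–141 envelope); EHB insertions
  are opt-in per site and placed in the right arm, where a real
  bottom-strand EHB sits without disrupting the top-strand cores.
* ΔattI fragments are cut from the bundled references at the requested
  position; the base immediately upstream of the fragment is forced to
  differ from the corresponding reference base, otherwise the planted
  truth label would be off by the chance length of the extended match.
* Mutations are substitutions only (truth coordinates stay stable),
  never touch the 7-mer cores, and are drawn as one uniform variate and
  one replacement per base — so the mutated set is *nested* across
  increasing rates under a fixed seed, which makes the
  recall-vs-mutation-rate monotonicity property deterministic rather
  than statistical.
* `generate_corpus()` derives per-record seeds from one master seed;
  changing the master seed changes every byte but not the planted
  composition.

What the generator does *not* emulate: real attC sequence heterogeneity
(arms are exact inverted repeats up to planted EHBs), insertion
sequences and introns interrupting sites, sequencing error, and any
mechanistic model of recombination itself. Round-trip tests on generator
output therefore demonstrate the correctness of the detection and
bookkeeping machinery — recall = precision = 1 at mutation rate 0,
graceful degradation with mutations — not detection performance on real,
messier records.

## Problem sizes and runtime

The test suite exercises: oracle equivalence on dozens of random
sequences ≤200 nt and patterns ≤15 nt; exhaustive fold enumeration on
arms ≤7 nt (the enumeration is exponential) plus an independent-aligner
check on arms ≤12 nt; a published-scale survey emulation of 138 synthetic
integrons planted with the exact composition of the reported corpus (96
ΔattI1-type and 14 ΔattI2-type cassettes, 90 and 8 of them at −11, the
blaOXA-10-type array in 65 of 96, two cross-class events, 28
tandem-carrying integrons including one run of four); and 10,000-
simulation calibration of the Welch test. The whole suite runs in a few
minutes on one CPU.

## Known limitations

* The GenBank reader is deliberately minimal (single-interval CDS
  locations; `join()` records are skipped with a warning).
* attC detection is forward-strand; analyse both orientations by
  scanning the reverse complement or relying on array-builder
  normalisation.
* The canonical-EHB defaults are configuration, not measurement, and
  should be validated against reference folds before being interpreted
  for real sites.
* Published corpus tallies are snapshots of mutable external databases;
  the package validates the machinery against planted compositions and
  makes no claim of reproducing snapshot-dependent counts.
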