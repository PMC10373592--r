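---
title: "Methods: amplicon-based quantification of multi-allelic editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon-based quantification of multi-allelic editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispamp)
```

# The setting and the model

`crispamp` analyses CRISPR/Cas9 editing outcomes at a single multi-copy
amplicon locus in a polyploid genome. The locus model is deliberately simple
and explicit:

- a **reference amplicon** (the bundled demonstration locus is 586 bp) with
  two Cas9 targets whose blunt cut sites lie 100 bp apart. The cut is placed
  3 nt 5' of the PAM (between protospacer positions −4 and −3, −1 adjacent to
  the PAM), the standard SpCas9 geometry; the source assays never state it,
  so it is fixed here rather than configurable.
- **haplotypes** (gene copies/alleles) defined as substitution-only SNP
  profiles over a declared list of variable positions (36 in the demo locus,
  5 of them inside the target seed/PAM regions). Substitution-only profiles
  keep coordinates stable across haplotypes; native *indel* variants of the
  target region are represented separately in the variant catalog, which is
  also where a real locus's indel-bearing alleles belong analytically (they
  are target-window observations, not genome-wide coordinate systems).
- a haplotype is **uneditable** at a target when its protospacer+PAM window
  differs from the canonical target string; the flag is derived, never set by
  hand. The demo locus ships one allele (`copy6`) uneditable at both targets
  (the rare HDR donor), and one uneditable allele per single target
  (`copy3`, `copy15`).

All coordinates are 0-based, half-open, on the + strand of the amplicon;
PAM-relative labels (−1…−20, P1–P3) are display-only.

# Indel calling

Reads are admitted to a target's analysis only when both 10-mer **indicator
anchors** flanking the target window occur exactly (in either orientation;
reads are reverse-complemented into reference frame). This certifies full
window coverage without scoring heuristics. Calling then proceeds in two
tiers:

1. **Wild type** iff the read contains the exact reference sequence over
   cut ± *r* (default *r* = 5). The source material does not define the
   wild-type marker's semantics; exact match over the window mirrors the
   behaviour of the published amplicon-analysis tool the parameters come
   from, and is cheap and directly testable. A consequence we accept: an
   indel *outside* the window but inside the comparison range on an
   otherwise-perfect read is called WT. Under the NHEJ spectrum this
   concerns a negligible read fraction.
2. Otherwise the indicator-delimited segment is **globally aligned**
   (match +2, mismatch −4, gap open −6, gap extend −1) to the corresponding
   reference segment via `Biostrings::pairwiseAlignment`; indel events are
   extracted and **left-aligned** (deletions shifted while the flanking base
   repeats; insertion strings rotated), so every homopolymer-equivalent
   placement reports one canonical event. Events are reported when they
   intersect cut ± *R* (default *R* = 30). Substitution-only reads are
   `edited` with `net_indel = 0` and are *not* counted in indel frequency —
   the reported statistic is an indel frequency, not a mismatch frequency.
   This also keeps native seed-SNP alleles out of the indel counts.

Net indel is the sum of signed indel sizes within ± *R*; a read is a
frameshift read when the net is not a multiple of 3. Summaries report
percentages at the printed-table precision: one decimal below 10%, integer at
or above 10% (half-away-from-zero).

Dropout (cut-to-cut) deletions remove the inner indicator anchors, so dropout
reads are invisible to per-target summaries — as they are in the emulated
assays, where they surface as a shorter PCR band instead. They are quantified
separately by `detect_large_deletion()`, which anchors on the outermost
indicators and asks whether a single deletion event spans both cut sites
under *some* homopolymer-equivalent placement (the stored event is
left-aligned, so naive interval containment would be wrong).

# Variant tracking

Native target-region variants are defined by their full expected
protospacer+PAM window string. After orientation normalization, assignment is
by exact substring occurrence, longest expected string first, then catalog
order; remaining reads are `canonical` (exact canonical window) or `other`
(including de-novo edits and reads carrying a cataloged variant plus an extra
edit — the source material never says how such reads were counted; exact
full-window matching is this package's documented choice, and it keeps
`canonical + Σvariants + other = reads_used` an exact partition). Variants
seen only in short-read data can carry a "possibly sequencing error" flag;
nothing is filtered automatically.

# Allele resolution and HDR

Clone (Sanger-like) reads are assigned to haplotypes by Hamming distance over
the variable positions *outside* the target windows (cut ± *R*), so edits
never influence the flank profile. Indel-bearing reads are profiled on
aligned columns. Defaults: `max_mismatch = 1` for real Sanger error rates, 0
in the error-free test fixtures; ties and reads covering < 80% of informative
positions are unassigned.

HDR evidence comes in two forms, deliberately separated:

- `hdr_components()` counts the **estimator classes** by target genotype
  alone: reads carrying the donor's window genotype at every donor-variant
  target, split into donor-identical (native donor molecules or full-length
  conversions — indistinguishable, which is exactly why the estimate
  subtracts a background) and recombinant (donor windows on a different SNP
  background). The corrected estimate is
  `sum(components) − native donor background`, clamped at zero, reported at
  one decimal. Counting by genotype rather than by resolved flank keeps the
  estimator unbiased when a long conversion tract swallows most informative
  flank SNPs.
- `detect_hdr()` resolves the **per-read evidence**: the recipient haplotype
  is the one whose profile explains the read outside a single contiguous
  tract containing the target windows (scored by parsimony — the fewest
  positions the tract must absorb; ambiguity means no candidate). Tract
  bounds follow from informative SNPs (positions where donor and recipient
  differ): the minimal tract spans the farthest donor-matching SNPs plus the
  windows; the maximal tract reaches the nearest recipient-matching SNPs, or
  is flagged unbounded. The true tract always lies between the two.

The estimator reports the conservative, donor-genotype-only figure; NHEJ-type
mutations shared across distinct flank profiles are additional (not
estimated) evidence, matching the source analysis's own description of its
figure as conservative. PCR/cloning chimeras can mimic recombinant reads;
the simulator models only true conversion, so this caveat is documented, not
resolved.

# CE analysis

Peak tables (sample, dye, size, height) are the input; raw trace parsing is
out of scope. Peaks below 1% of the tallest peak are noise; a peak is WT
within 0.5 bp of the expected product size (the assays state sizes only as
"~"; both thresholds are arguments). Mutation frequency is
`100 · mutant / (mutant + WT)` peak heights. Subsamples of a line are uniform
when pairwise frequencies agree within 5 points (a choice, surfaced as
`freq_tol`) and, by default, their mutant net-indel sets are identical.

# Reporting and statistics

Efficiency/rate operations are exact rational arithmetic rounded
half-away-from-zero at printed precision (base R's banker's rounding would
disagree with printed tables on .5 boundaries). The one-way ANOVA is the
balanced textbook decomposition; Tukey's HSD uses
`qtukey(1 − α, k, df_within) · sqrt(MSE/n)` and the compact letter display
assigns letters to maximal windows of the mean-sorted groups with spread ≤
HSD, which makes shared letters transitive by construction. Unequal group
sizes are an error directing to an unbalanced alternative, not silently
approximated. The acceptance check validates that the HSD threshold
reproduces `TukeyHSD()`'s pairwise decisions rather than any particular
published threshold value, whose underlying MSE is not available.

# The synthetic-data generator

The generator states the world the validation assumes:

- **Lineages**: a pool of cell lineages (Dirichlet fractions) over a copy
  dosage; dosage weights generalize integer copy numbers so a rare,
  under-amplified donor allele can hold e.g. 0.7% of template share.
- **Repair**: per editable copy — donor conversion with probability
  `hdr_prob` (one tract whose endpoints fall uniformly among the inter-SNP
  intervals flanking the donor-variant windows, so flank informativeness
  varies); otherwise the cut-to-cut dropout deletion with probability
  `large_del_prob`; otherwise per-target NHEJ with probability `cut_prob`
  and the size spectrum `{+1: 0.4, −1: 0.3, −2: 0.1, −3: 0.05, +2: 0.05,
  other small: 0.1}`, concentrated on ±1 bp at the cut as observed in the
  emulated data. Uneditable copies never receive events.
- **Reads**: full-amplicon (amplicon sequencing, not shotgun), uniform
  per-base substitution error (default 0 for clones, configurable for short
  reads), optional truncation and reverse-complement emission, constant
  placeholder qualities ("I") — the pipeline never uses quality. Read counts
  are multinomial over lineage × dosage; `exact_counts = TRUE` allocates by
  largest remainder for calibration scenarios whose published frequencies
  are exact (e.g. 73% of 10,000 reads, 28 of 80 clones).
- **Not emulated**: instrument-specific error/length profiles, paired-end
  structure, PCR chimeras, cloning bias. A green round-trip test therefore
  establishes that the pipeline recovers what the generator put in — not
  that it is robust to artifacts the generator does not produce.

Determinism: one master seed; independent draws (lineages, reads, clones)
use seeds derived from it, so identical configs give byte-identical FASTQ,
FASTA and truth outputs.

# Numerical and design choices

- Enzyme recognition strings are configuration, not constants; the demo
  builder ships a canonical profile and an `as_printed` profile because the
  two differ in one published motif and the package takes no position on
  which is correct.
- Primer matching is exact; the emulated assays used validated conserved
  primers, and mismatch-tolerant PCR is a non-goal.
- Alignment tie-breaks are resolved by event-level left-alignment after the
  fact, not by trusting the aligner's internal gap placement.
- The WT-marker monotonicity property is implemented in the only
  self-consistent direction: a larger exact-match window is stricter, so the
  WT set at `r = 5` is contained in the WT set at `r = 2`.
- A deliberately small 80 bp single-target locus backs the alignment oracle
  tests: every single-indel call is checked against brute-force enumeration
  of all single-indel edits that transform reference into read.

# Known limitations

- Exact indicator matching excludes reads with an error inside an anchor
  (~10% at 0.5% base error with two 10-mers); exclusion is unbiased with
  respect to edit status, so frequencies are unaffected, but yields drop.
- Haplotype profiles are substitution-only; an allele defined by a flanking
  indel would need representation through the variant catalog.
- `detect_hdr` requires an unambiguous recipient; conversions that erase
  nearly all informative flank SNPs are counted by the estimator but not
  listed as per-read candidates.
- The CE module trusts the upstream peak caller; co-migrating fragments and
  pull-up peaks are invisible to it.
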