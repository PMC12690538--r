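---
title: "Phenotyping piRNA-pathway mutants from small-RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping piRNA-pathway mutants from small-RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
library(dplyr)
```

## The biology being measured

In the *Drosophila* germline, PIWI-clade Argonautes loaded with 23–29 nt
piRNAs silence transposons. Two biogenesis routes leave distinct, countable
footprints in a small-RNA sequencing library:

* **Ping-pong amplification.** Aubergine, guided by an antisense piRNA,
  slices a transposon transcript; AGO3 is loaded with the resulting sense
  piRNA and reciprocates. Because each Argonaute cuts 10 nt from its guide's
  5′ end, sense/antisense piRNA pairs overlap by **exactly 10 nt at their 5′
  ends**, antisense guides begin with U (1U) and sense partners carry A at
  position 10 (forced by complementarity).
* **Phasing.** Zucchini-dependent fragmentation produces head-to-tail piRNA
  trails; its footprint is a **uridine enrichment at the genomic position
  immediately downstream (+1) of piRNA 3′ ends**.

A hypomorphic mutant can collapse ping-pong while leaving phasing intact —
distinguishing the two footprints, and quantifying transposon piRNA loss
relative to a denominator the pathway does not touch, is exactly what this
package automates.

## Pipeline stages and their parameters

The analysis chain mirrors the standard small-RNA workflow; every stage is an
exported function and `run_pipeline()` executes them in order, writing every
intermediate so each step is independently auditable.

1. **Preprocessing** (`preprocess_reads()`). The 3′ adapter is located as the
   leftmost full match, or a terminal adapter prefix of at least
   `min_overlap = 5` nt, tolerating `floor(0.1 × overlap)` mismatches. Reads
   without a detectable adapter are **discarded**: the library architecture
   places 4 randomized nucleotides (UMIs) on *both* sides of the insert, and
   only an adapter hit guarantees the 3′ UMI was sequenced, making UMI
   stripping well defined. UMIs are retained in the output (for optional
   deduplication) but no deduplication is applied. Inserts are then
   size-selected to 18–40 nt, the analysis window for these libraries.
2. **Hierarchical classification** (`classify_reads()`). Reads matching any
   infrastructural RNA (rRNA, tRNA, snRNA, snoRNA, miRNA; either strand,
   full-length, ≤ 1 mismatch) are removed *first*. Of the remainder, 20–22 nt
   reads matching an hpRNA locus are endogenous siRNAs; their count `S` is
   the normalisation denominator. hpRNA matching reuses the ≤ 1-mismatch
   full-length rule for symmetry. Classification is exclusive — a read
   matching both an hpRNA and a transposon counts as siRNA only — so no read
   appears in both numerator and denominator. Finally, remaining reads longer
   than 22 nt are piRNA candidates.
3. **Transposon alignment** (`align_reads()`). Exhaustive ungapped
   full-length comparison against every consensus, both strands, reporting
   *all* placements in the best (minimal-mismatch) stratum within
   `max_mm = 3` — the all/best/strata multi-mapper convention. Indels are out
   of scope; non-ACGT read symbols count as mismatches. Each best-stratum
   alignment contributes one count to its (transposon, strand) cell; an
   optional fractional mode (1/n per hit) is available but off by default.
   The implementation is a small vectorised C++ scanner whose output contract
   is the brute-force scan itself; the test suite holds it equal to an
   independently written naive scanner on 1,000 random planted instances per
   run, and `read_sam()` accepts externally produced alignments as an
   alternative front door.
4. **Quantification** (`count_pirnas()`, `normalize_abundance()`,
   `fold_changes()`). Abundance is `A = 10⁶ · c / S` per (transposon,
   strand). `S = 0` is a hard, explicit failure — never a silent NaN
   (`run_pipeline()` degrades to `NA` abundances with a warning so an empty
   library still yields a clean run). Fold changes between libraries use a
   pseudo-count `ε = 1` normalised unit, recorded in the output; replicates
   are averaged on the normalised scale first.
5. **Ping-pong linkage** (`overlap_spectrum()`, `linkage_z()`). For 0-based
   half-open alignments, a sense 5′ end is `s5 = start` and an antisense 5′
   end is `a5 = end − 1`; a pair overlaps by `d = a5 − s5 + 1` shared bases,
   so the planted geometry `s5 = a5 − 9` gives d = 10 (pinned by a coordinate
   unit test). Counts `o(d)` for d = 1..20 use products of alignment weights.
   The linkage score is
   `z10 = (f(10) − mean f(d≠10)) / sd f(d≠10)` with `f = o / Σo` and the
   sample standard deviation over the 19 background distances. The score is
   *undefined* — reported as missing, never 0 — when `Σo < min_pairs = 100`
   or the background is degenerate. The background window (1–20) follows the
   established linkage formulation; both the window and `min_pairs` are
   arguments.
6. **3′-end signature** (`collect_windows()`, `end_signature()`). For each
   antisense piRNA alignment the 11-nt window covering the last 10 read
   positions plus 1 genomic position downstream of the 3′ end is extracted in
   read orientation (windows crossing the reference edge are skipped and
   counted). The 10-inside/1-outside split is a configurable default
   (`window_up`, `window_down`); the +1 anchor is the point of the statistic.
   Per base, `z_b = (F[+1][b] − mean_p F[p][b]) / sd_p F[p][b]` with the
   **population** standard deviation over the 11 positions. This convention
   is pinned by a closed-form oracle: if the +1 frequency is the single
   outlier among 11 otherwise equal positions, `z = √10 ≈ 3.162` regardless
   of effect size — the statistic saturates there, so "z > 3" is close to its
   ceiling and should be read as a detection call, not an effect size.
   Signatures need `min_windows = 100` windows, else they are undefined.

## What the simulator emulates, and how

`simulate_library()` produces raw FASTQ with the sequenced architecture
`UMI₄ + insert + UMI₄ + adapter + read-through`, padded with G (two-colour
dark cycles) to 150 nt, plus a truth table. Sequencing errors are off by
default (`error_rate = 0`): the downstream statistics tolerate ≤ 3
mismatches, and the error-free case is what makes exact conservation checks
meaningful; a uniform per-base error rate is available.

Per transposon `t` (weight `w_t` proportional to consensus length), emission
is Poisson with ping-pong fraction `f` and genotype fold multipliers:

* pair events: `n₀ · w_t · f · antisense_fold_t` (one antisense + one sense
  read, 5′ ends overlapping by exactly 10 nt at uniformly chosen loci),
* antisense singles: `n₀ · w_t · (1 − f) · p_anti · antisense_fold_t`,
* sense singles: `n₀ · w_t · (1 − f) · (1 − p_anti) · sense_fold_t`,

with `n₀ = n_pirna / (1 + f)` so wild-type totals match the requested size.
This makes the expected antisense count per transposon *exactly linear* in
`antisense_fold` (a tested invariant) and makes `f = 1` produce only pair
members. `p_anti = 0.75` reflects the antisense dominance of germline
transposon piRNAs; the 1U bias of pair-member antisense guides is 0.9 —
field-typical strong bias, configurable.

Nucleotide biases are planted by **conditioned placement**, not by editing
bases: a read end is sampled among consensus positions whose genomic base
realises the desired outcome (an A at the antisense 5′ position makes the
read start with U; an A just upstream of the antisense alignment start makes
the +1 downstream base U). The consensus sequences are therefore immutable,
every read is an exact substring of the shared reference FASTA, and any
number of libraries simulated from one reference set are mutually consistent
— which is what lets the full pipeline recover truth exactly at error rate 0.
`phasing_u_bias` is the exact marginal probability that +1 is U, so 0.25 is
the uniform null.

Genotype presets encode the three study conditions: `genotype_wildtype()`
(folds 1, `f = 0.5`, phasing bias 0.8); `genotype_zf_like()` (folds 0.4/0.8
— within the less-than-10-fold band, `f = 0.05` — ping-pong collapsed but not
abolished, phasing untouched); `genotype_null_like()` (folds 1/30 — inside
the reported 10–100-fold reduction band, no ping-pong, no phasing bias).

What the simulator does **not** emulate: realistic base composition or
repeat structure of transposon consensus sequences (references are uniform
random, so multi-mapping is far rarer than in real data), quality-score
realism, PCR duplication, ligation biases, and genome-scale piRNA clusters
outside consensus space. Passing tests therefore validate the *statistics
and bookkeeping* of the pipeline, not its behaviour under heavy
multi-mapping or degraded input.

## Numerical and degenerate-input choices

* Flat overlap spectra (zero background variance with no excess at 10) give
  an undefined z10; a zero-variance background with an excess at 10 yields
  +Inf rather than masking a perfect signal.
* Zero siRNAs: `normalize_abundance()` aborts with an explicit message;
  the orchestrator converts this to `NA` abundances plus a warning so empty
  inputs run clean end to end.
* Empty inputs at every stage return empty, correctly typed tables.
* Transposons shorter than twice the longest read are skipped by the
  simulator with a warning.
* All randomness is local: generators take explicit seeds and restore the
  caller's RNG state, so identical specifications are byte-identical on
  disk.

## Scale of the verification runs

The test suite and the acceptance script size their simulations to make each
property measurable while staying desk-scale: 1,000 random instances for the
aligner-vs-oracle check; one 50,000-read library for classification
conservation; 20 seeds × 5 transposons for the ping-pong and phasing null
calibrations; 50,000 planted piRNAs for signal detection; and three
full-pipeline libraries (20 transposons of 1 kb, 50,000 piRNAs, 10,000
siRNAs each) for the wild-type / Zinc-Finger-like / null-like genotype
contrast. At these sizes the Poisson sampling noise is a few percent —
comfortably inside the 10–100-fold and <10-fold bands being verified.

## Known limitations

* Ungapped alignment only; reads spanning indel polymorphisms against the
  consensus are lost or down-weighted.
* The linkage background window (1–20) and the 10 + 1 signature split follow
  the conventions above; alternative windows are exposed as arguments but
  not validated against external datasets here.
* The t-test comparing per-transposon linkage between genotypes treats
  transposons as independent units, as is conventional; shared piRNA-pathway
  machinery makes them correlated in reality, so its p-values are an
  ordering device rather than a calibrated error rate.
* Heterotypic vs homotypic ping-pong decomposition and per-Argonaute
  attribution require IP data and are out of scope.
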