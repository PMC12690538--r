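# pirnakit

Small-RNA sequencing is how piRNA-pathway mutants are phenotyped in the
*Drosophila* germline: transposon-silencing defects show up as lost antisense
piRNAs, collapsed ping-pong amplification, or a broken phasing signature —
three different footprints that separate a null allele from a hypomorph.
`pirnakit` implements that analysis as a tested, reusable R pipeline, plus a
seeded synthetic-library generator so every stage can be verified against
ground truth at desk scale.

The pipeline, from raw FASTQ to statistics:

1. **Preprocess** — 3′ adapter trimming, removal of the 4 randomized
   nucleotides (UMIs) flanking the insert, 18–40 nt size selection.
2. **Classify** — hierarchical filtering: infrastructural RNAs
   (rRNA/tRNA/snRNA/snoRNA/miRNA, ≤ 1 mismatch) out first; 20–22 nt reads
   matching hpRNA loci become the endogenous-siRNA set whose count *S*
   normalises everything; remaining reads > 22 nt are piRNA candidates.
3. **Align** — exhaustive ungapped mapping to transposon consensus sequences,
   ≤ 3 mismatches, reporting **all** hits in the best mismatch stratum, both
   strands (all/best/strata multi-mapper semantics).
4. **Quantify** — per (transposon, strand) abundance
   *A* = 10⁶ · *c* / *S* ("per one million endogenous siRNAs"), fold changes
   (A_mut + ε)/(A_wt + ε) between genotypes.
5. **Ping-pong linkage** — the 5′–5′ overlap spectrum *o(d)*, d = 1..20,
   between opposite-strand piRNAs, and the linkage score
   *z10* = (f(10) − mean f(d≠10)) / sd f(d≠10), the z-score of the 10-nt
   overlap frequency against the other distances.
6. **Phasing signature** — base frequencies in the 11-nt window around
   antisense piRNA 3′ ends (10 read-terminal positions + 1 downstream) and
   the +1 z-score z_b = (F[+1][b] − mean F[p][b]) / sd F[p][b]; uridine
   enrichment at +1 is the phasing readout.

`simulate_library()` generates the ground-truth libraries: planted 10-nt
5′-overlap pairs with 1U/10A biases, a +1U phasing bias, piRNA (23–29 nt) and
siRNA (20–22 nt) size classes, infrastructural background, and genotype
effect-size presets (`genotype_wildtype()`, `genotype_zf_like()`,
`genotype_null_like()`).

## Worked example

```r
library(pirnakit)
library(dplyr)

refs <- make_references(n_te = 3, n_infra = 3, n_hp = 2, seed = 42)
lib  <- simulate_library(refs, library_spec(genotype_wildtype(),
          n_pirna = 20000, n_sirna = 10000, n_infrastructural = 5000,
          seed = 7), dir = "demo")

pp  <- preprocess_reads(lib$files$fastq)
cls <- classify_reads(pp$reads, lib$refs)
cls$report
#>   class               n
#> 1 infrastructural  5000
#> 2 pirna_candidate 20390
#> 3 sirna           10000

aln <- align_reads(filter(cls$reads, class == "pirna_candidate"), lib$refs)
normalize_abundance(count_pirnas(aln), cls$sirna_count, "wildtype")
#>   library  transposon strand    count sirna_count abundance
#> 1 wildtype TE01       sense      2904       10000    290400
#> 2 wildtype TE01       antisense  3947       10000    394700
#> 3 wildtype TE02       sense      2812       10000    281200
#> ...

linkage_z(overlap_spectrum(aln))
#>   transposon n_pairs   z10
#> 1 TE01        130631  32.4
#> 2 TE02        125156  18.2
#> 3 TE03        136609  17.2

end_signature(collect_windows(aln, lib$refs)$windows)
#> 3'-end nucleotide signature over 11785 windows
#>   z at +1: U/T 3.16, A -3.14, C -3.14, G -3.13
```

Reading the numbers: every planted read is recovered and classified exactly
(error rate is 0 by default); antisense piRNA abundance is ~390,000 per
million siRNAs per transposon; z10 far above 3 on every transposon reflects
the planted ping-pong fraction of 0.5; and the +1 U/T z-score sits at its
√10 ≈ 3.16 ceiling because 80% of antisense 3′ ends are followed by uridine.
A `genotype_null_like()` library run through the same code shows 10–100-fold
antisense loss and undefined/near-zero z10; a `genotype_zf_like()` library
shows <10-fold abundance changes, collapsed z10, and an intact +1U signature.

`run_pipeline(pipeline_config(...))` executes the whole chain for a table of
libraries, writes every intermediate TSV plus a hashed manifest, averages
replicates per genotype, and emits fold-change tables and a wild-type vs
mutant linkage comparison. Result objects have `tidy()`/`glance()` methods
and plots (`plot_overlap_spectrum()`, `plot_abundance_scatter()`,
`autoplot()`).

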