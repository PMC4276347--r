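# regmodes

Integrative multi-omics analysis of promoter chromatin state and gene
regulation across two cellular states, built for the pre-pro-B → pro-B
transition of early B-lymphocyte development but applicable to any
two-state design with the same data types.

The package is for computational biologists who have, per gene and per
state: H3K4me3 and H3ac ChIP-seq tag libraries, GRO-seq nascent
transcription (tags or counts), RNA-seq FPKM, and iTRAQ peptide-level
protein log2 ratios — and who want to know **where regulation acts**:
at the chromatin/transcription level, post-transcriptionally, or not at
all.

## The method

1. **Promoter activity (cRPKM).** Each promoter (TSS ± 200 bp) is scored
   per mark by `RPKM = count / (width_kb × library_millions)`; the two
   marks' RPKMs (each normalised by its own library) are summed into the
   cumulative score `cRPKM`. A promoter is *active* when `cRPKM > 8`
   (strict; single-mark scores with an identical-position amplicon stack
   are set inactive). The cutoff can be estimated from data as the
   antimode of the bimodal score distribution. Crossing the two states'
   calls yields four promoter classes.
2. **Expression and stability.** Gene-level GRO-seq RPKM (whole gene
   span, strand-matched), RNA-seq FPKM, and the inferred stability index
   `FPKM / RPKM` per state with its between-state differential
   `log10((FPKM_pro/RPKM_pro)/(FPKM_pre/RPKM_pre))`.
3. **Regulatory modes.** Per-gene states on three axes (transcription,
   mRNA, protein) at ≥2-, ≥2- and ≥1.5-fold give 27 combinations,
   collapsed into four broad groups — *transcriptional* (concordant on
   all axes), *post-transcriptional* (protein change over unchanged
   transcription; sub-split into `rna_level` vs `downstream`),
   *undetermined/ambiguous*, and *no protein change*.
4. **Statistics.** Wilcoxon–Mann–Whitney class comparisons (exact or
   tie-corrected), quartile strata, binned frequency distributions, and
   interval enrichment of score-selected regions at TSSs (Jaccard,
   projection/binomial and Monte-Carlo relative-distance tests).

A fully parameterised synthetic-data generator emulates the whole stack
(bimodal promoter scores with the antimode near 8, transcription
populations 2–3 orders of magnitude apart, state-specific unstable
transcripts, regulatory modes with concordant fold effects, library
depth asymmetry, amplicon artifacts) with ground truth, so the pipeline
is testable end to end without downloads.

## Worked example

```r
library(regmodes)

params  <- generator_params(n_genes = 1000, seed = 42)
dataset <- simulate_dataset(generate_truth(params))
report  <- run_pipeline(dataset, run_config(do_enrichment = FALSE))
print(report)
#> regmodes pipeline report
#>   genes: 1000
#>     active_in_both           436
#>     exclusively_pre_pro_B    22
#>     exclusively_pro_B        82
#>     inactive_in_both         460
#>   antimode estimate: 17.3
#>   DE proteins: 249
```

The class counts are the four-way promoter classification at the
`cRPKM > 8` cutoff (the two exclusive classes are small, with the pro-B
one larger — partly a real signal, partly the shallower pre-pro-B
libraries under-calling that state). The antimode (17.3) is the
estimated valley of the bimodal score distribution and lies between the
generating populations (≈0.9 and ≈80); 249 proteins clear the 1.5-fold
differential cutoff. Because the data are synthetic, the calls can be
scored against truth:

```r
score_against_truth(report, dataset$truth)
#> # A tibble: 1 × 5
#>   promoter_class_accuracy axis_state_accuracy broad_group_accuracy ...
#> 1                   0.975               0.912                0.974
```

97.5% of promoter classes and 97.4% of broad regulatory groups are
recovered, and the designated gene with a 24-fold protein decrease on
flat transcription/mRNA is called post-transcriptional/downstream.
`tidy(report)` returns the per-gene master table, `glance(report)` a
one-row summary, `autoplot(report)` the group-by-class percentage
matrix; `summarize_table1(report$master)` gives that matrix as a tidy
tibble.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/regmodes-cli.R simulate --n-genes 1000 --seed 42 --out fixture/
Rscript inst/scripts/regmodes-cli.R run --fixture fixture/ --out report/
```

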