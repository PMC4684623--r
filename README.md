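# apobecsig

Integrative analysis of APOBEC-family cytidine-deaminase activity in breast
cancer: linking `APOBEC3B`/`APOBEC3C` mRNA levels to somatic C-to-T
mutagenesis, stratified by estrogen-receptor (ER) status and by the germline
`APOBEC3B` deletion polymorphism (copy-number states CN0/CN1/CN2).

The package is aimed at cancer-genomics analysts who have per-sample somatic
SNV tables, gene-level expression, clinical metadata and (optionally)
bisulfite CpG calls, and who want the classical APOBEC-mutagenesis readouts
without a full signature-deconvolution framework. A synthetic-cohort
generator with known ground truth makes every stage testable without any
external data.

## What it computes

* **Strand-collapsed mutation spectra.** Every SNV is mapped to one of six
  pyrimidine-reference classes (C>A/G>T, C>G/G>C, C>T/G>A, T>A/A>T,
  T>C/A>G, T>G/A>C); per-sample counts, relative frequencies, and burden
  summaries (total SNVs and C>T/G>A per exome).
* **Trinucleotide motif excess rates.** For each C-centered class the 16
  motifs' observed counts are compared with the background-normalized
  expectation `E(m) = N · f_bg(m)`; the excess rate is
  `(observed − expected) / expected`. The T*C*W motif (W = A or T, mutated
  C in TCA/TCT) is the APOBEC deamination context; TCW vs non-TCW counts
  between two groups are tested with Fisher's exact test.
* **Expression quantification.**
  `RPKM = reads · 10⁹ / (length_bp · total mapped reads)`, group contrasts
  by two-sided Wilcoxon rank-sum, and a printed-table style cohort summary
  (counts, half-up rounded percentages, deletion carriers = CN0 + CN1).
* **Stratified burden–expression association.** Spearman's ρ between a
  gene's expression and the per-exome burden within each ER stratum or CN
  group, with a tricube local-linear smooth and a least-squares line for
  plotting; clinical contrasts (vital status, ordinal stage trend).
* **Promoter methylation profiles.** CpG sites (depth ≥ 4) averaged in 100
  non-overlapping 100-bp bins across TSS ± 5 kb, promoter-aligned for
  minus-strand genes; proximal (±0.5 kb) contrasts between cell types by
  Wilcoxon signed-rank.
* **Statistical core.** Spearman, rank-sum, signed-rank and Fisher tests
  switch to exhaustive-enumeration exact p-values at small sample sizes
  (n ≤ 10 pairs, ≤ 12 pooled observations, ≤ 12 nonzero differences) and
  use tie-corrected approximations above; all tie handling is mid-rank.

## Worked example

```r
library(apobecsig)

cfg    <- sim_config(n_tumor = 400, n_normal = 40, seed = 42)
cohort <- simulate_cohort(cfg)

summarize_cohort(cohort$metadata)
#>   category    level tumor_count tumor_pct normal_count normal_pct
#>  er_status positive         289      72.3           33       82.5
#>  er_status negative          81      20.3            6       15.0
#>  ...
#> Germline-deletion carriers among tumors (CN0 + CN1): 81

exomes <- cohort$metadata[cohort$metadata$has_exome, ]
spec   <- count_spectrum(cohort$variants, exomes, group_by = "cn_state")
spec
#> Mutation spectrum: 324 samples, 18455 SNVs
#>   statistic pooled_count     mean       sd
#>  total_snvs        18455 56.95988 52.08063
#>       ct_ga         7179 22.15741 22.81538

associate_burden_expression(spec, cohort$expression, "APOBEC3B", exomes,
                            stratify_by = "er_status")
#> Burden (C>T/G>A) vs APOBEC3B expression, stratified by er_status
#>   stratum   n       rho            p
#>  negative  69 0.1241967 3.092717e-01
#>  positive 230 0.3408647 1.152277e-07
```

The per-exome burden is negative-binomial with mean ≈ 57 and SD ≈ 52, and
the C>T/G>A burden correlates with `APOBEC3B` expression in the ER+ stratum
only (generator targets: ρ = 0.32 in ER+, 0 in ER−) — the ER-dependent
coupling pattern the analysis is designed to detect.

```r
ann <- annotate_variants(cohort$variants)
grp <- exomes$cn_state[match(ann$sample, exomes$sample_id)]
tcw_enrichment_test(ann[grp == "0", ], ann[grp == "2", ],
                    labels = c("CN0", "CN2"))
#>      TCW non-TCW
#> CN0   34     161
#> CN2 5190    2592
#> odds ratio = 0.1055, two-sided p = 2.47e-44
```

Under the default generator the APOBEC signature intensity follows
`APOBEC3B` expression, so homozygous-deletion (CN0) samples — pinned at the
expression floor — are TCW-depleted relative to CN2; the test resolves this
easily. Set `signature_slopes` / `signature_baseline` to emulate other
scenarios (e.g. expression-independent TCW pressure in deletion carriers).

A full run — simulate → spectrum → motif → associate → methylation → report
— is one call:

```r
report <- run_pipeline(pipeline_config(sim = cfg, outdir = "out", seed = 42))
```

or from a shell via the bundled wrapper
(`inst/scripts/apobecsig-cli.R simulate|report`).

## Layout

* `R/` — simulator, spectrum/motif analysis, statistics, methylation, IO,
  pipeline driver
* `tests/testthat/` — unit, property and acceptance tests with
  enumeration oracles
* `vignettes/apobec-mutagenesis.Rmd` — methods vignette (model,
  parameters, design decisions, limitations)
* `inst/extdata/` — tiny synthetic FASTA/BED/TSV fixtures
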