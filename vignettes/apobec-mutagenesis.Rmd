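---
title: "APOBEC mutagenesis analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APOBEC mutagenesis analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecsig)
```

# Scope and data model

`apobecsig` analyses the relationship between APOBEC-family cytidine
deaminase expression (chiefly `APOBEC3B` and `APOBEC3C`) and somatic
C-to-T mutagenesis in breast tumors, stratified by estrogen-receptor (ER)
status and by the germline `APOBEC3B` deletion (copy-number states CN0,
CN1, CN2). Five data types flow through the pipeline:

* somatic SNVs (sample, chromosome, 1-based position, ref, alt, optional
  +strand trinucleotide context);
* a gene × sample RPKM matrix (or counts plus feature lengths);
* sample metadata (ER status, tissue, CN state, vital status, TNM stage,
  exome availability);
* a background trinucleotide composition (supplied as a table or computed
  from a reference FASTA and a BED territory);
* CpG methylation calls (position, methylated reads, total reads) plus a
  stranded TSS annotation.

Alignment, mutation calling, CNV genotyping and peak calling are out of
scope: the package consumes their outputs.

# Mutation spectrum and strand collapse

Each substitution is recorded by its pyrimidine-reference form: a purine
reference is complemented together with its alternate allele, and the
trinucleotide context is reverse-complemented, so `G>A` in `TGA` becomes
`C>T` in `TCA`. Six classes cover the 12 ordered base pairs, and all motifs
are 3-mers with a C or T center, read 5'→3'. The APOBEC deamination context
is T*C*W (motifs TCA and TCT with a mutated C). Variants whose context
window contains an ambiguous base keep their class (class needs no context)
but are excluded from motif analyses.

Per-sample class counts, relative frequencies and burden summaries (total
SNVs and C>T/G>A per exome, mean ± SD) are produced by `count_spectrum()`;
samples present in the metadata but free of variants count as zero-burden,
so cohort-level means are not inflated by dropping empty samples. Note that
a pooled total divided by the sample count and a mean of per-sample counts
answer subtly different questions when a cohort subset is analysed; the
package reports both so either convention can be matched.

# Background-normalized motif excess

For a substitution class with pooled count $N$ and a background motif
frequency $f(m)$ over the 16 C-centered motifs, the expected ("mean")
occurrence is the analytic expectation $E(m) = N f(m)$, so expectations sum
exactly to $N$ within each class. The excess rate is

$$\mathrm{excess}(m) = \frac{O(m) - E(m)}{E(m)},$$

bounded below by −1 and exactly 0 in expectation when mutations are drawn
from the background. An optional permutation expectation (seeded
multinomial draws) is available as a cross-check of the analytic form; the
two agree by construction and the analytic version is deterministic, which
is why it is the default.

The background composition is an explicit input. When computed from a
FASTA plus BED territory, every overlapping 3-mer whose center lies in the
territory is tallied, with G/A-centered 3-mers reverse-complemented into
the C/T tallies. Whether the right territory is a capture region, the
covered exome, or a whole genome depends on how the variants were called;
the package does not guess.

TCW enrichment between two groups uses the 2×2 table (rows = groups,
columns = TCW / non-TCW C-centered mutations) and the two-sided Fisher
exact test. By default all three C-centered classes are pooled;
`classes = c("C>G", "C>T")` restricts to the APOBEC-preferred outcomes, and
the pipeline reports both variants.

# Statistical core

The rank-based tests are implemented with exhaustive enumeration below a
crossover and classical approximations above it:

| test | exact regime | approximation |
|---|---|---|
| Spearman | n ≤ 10 (full permutation null, cached per rank multiset) | t with n − 2 df |
| rank-sum | pooled n ≤ 12, no ties (all $\binom{N}{n_a}$ splits) | normal, tie-corrected, 0.5 continuity correction |
| signed-rank | ≤ 12 nonzero differences (all $2^n$ sign patterns) | normal, tie-corrected, continuity correction |
| Fisher 2×2 | always exact (hypergeometric summation, p ≤ p_obs·(1+10⁻⁷)) | — |

Ties receive mid-ranks everywhere; two-sided exact p-values are
$P(|T - E T| \ge |T_{obs} - E T|)$ under the permutation null, which
coincides with the usual two-tail sum for these symmetric nulls. The
crossovers keep enumeration instantaneous; they were checked numerically
against the approximations, whose largest absolute deviation over the full
null support at the crossover sizes is below 0.02. Zero differences are
removed before the signed-rank test; a constant input makes Spearman's rho
undefined and is flagged rather than coerced.

`loess_smooth()` is a first-degree tricube-weighted local linear smoother
(window = nearest `floor(span·n)` points, default span 0.75, no robustness
iterations): deterministic, exactly reproducing globally linear signals,
used only for plotting alongside an ordinary least-squares line. No
p-value in the package is ever corrected for multiple testing; reports
carry the number of tests run so users can apply their own correction.

Burden–expression association is Spearman's rho per stratum, computed on
the RPKM scale; being rank-based it is invariant to the log2 display
transform (`log2(RPKM + 1)`, pseudocount 1), which therefore never feeds a
test. The stage trend treats TNM stage as ordinal (I = 1 … IV = 4) with
Spearman's rho, consistent with the rank-based toolkit; `unknown` levels
are always excluded from contrasts.

# Methylation profiles

CpG sites need at least 4 supporting reads (inclusive). Profiles are built
from 100 contiguous half-open 100-bp tiles spanning TSS − 5 kb to
TSS + 5 kb — "100-bp windows" here means non-overlapping tiles, matching a
per-100-bp-bin heatmap; a sliding window with step < width is deliberately
not provided. A bin's value is the unweighted mean of its site-level
ratios (ratios are computed per site first, so deep sites do not dominate
a bin), and empty bins are NA, never 0. The TSS itself falls in the first
downstream bin; minus-strand genes have their bin order reversed so bin 1
is always the 5' end of the gene. The proximal promoter is TSS ± 0.5 kb
(10 bins). Promoter comparisons pair the proximal bins covered in both
profiles and use the signed-rank test; pairing bins (not sites) is the
default because site coverage rarely matches across libraries, and a
site-level pairing can be built from the raw tables if needed.

# The synthetic cohort generator

`sim_config()` defaults describe the cohort the analysis is designed for:
915 tumors and 85 adjacent normals; tumor ER fractions 664 : 196 : 55
(positive : negative : unknown), CN fractions 28 : 162 : 597 : 128
(CN0 : CN1 : CN2 : unknown), exome data for 750/915 of tumors; per-exome
burden negative-binomial with mean 57.9 and SD 50.9 (size by method of
moments, `mean²/(sd² − mean)`); normals carry their own ER/CN fractions.

Expression is log2-normal per gene and ER stratum. Defaults place
`APOBEC3B` and `APOBEC3C` higher in ER− than ER+ tumors (means 3.5 vs 2.0
and 4.0 vs 3.0 on the log2 RPKM scale, SDs 1.0/0.8), with a lower
`APOBEC3B` level in normal tissue and small clinical effects (stage slope
±0.15 per stage, vital-status shift ±0.3) so clinical contrasts have a
recoverable direction. `APOBEC3B` expected expression is multiplied by
copy/2; CN0 samples sit exactly at a configurable floor (default 0.05
RPKM, nonzero so log-scale plots stay finite; CN unknown is treated as two
copies).

Mutations are drawn per sample: burden $N_i$ from the negative binomial,
then each mutation is an APOBEC-signature event (C>T with probability 2/3
or C>G, in TCA/TCT) with per-sample probability

$$p_i = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(p_0) + \beta_s z_i\big),$$

where $z_i$ is the within-stratum standardized log2 `APOBEC3B` expression,
$p_0$ is the baseline (default 0.2; 0 disables the signature), and
$\beta_s$ is the stratum's link slope. Non-signature mutations draw a
class from the background six-class mix and a motif from the background
trinucleotide frequencies for the matching center base. Half of all
records are emitted on the purine strand so downstream strand collapse is
always exercised. The background class mix (C>A 0.11, C>G 0.09, C>T 0.25,
T>A 0.09, T>C 0.30, T>G 0.16) represents non-APOBEC processes; the pooled
simulated spectrum is still C>T-dominant once the signature is added, and
the gap between the background and signature C>T shares is what gives the
link its dynamic range (with the cohort's strong burden overdispersion, a
background C>T share as high as 0.40 would cap the attainable
expression–burden correlation near 0.24, below the 0.32 study target).

**Link calibration.** Users specify per-stratum *target* Spearman
correlations between expression and C>T/G>A burden (defaults: ER+ 0.32,
ER− 0, unknown 0.32 — ER-unknown tumors behave like ER+). The slope
$\beta_s$ realizing a target is found by `uniroot` on a Monte-Carlo
estimate of the correlation (4000 internal samples drawn with a fixed
internal seed and common random numbers across slope evaluations, so the
estimate is a smooth deterministic function of the configuration).
Calibration is independent of the run seed, cached on a configuration
hash, and raises an error for unattainable targets instead of silently
saturating. Explicit `signature_slopes` bypass it.

The negative `APOBEC3C` association in ER− tumors is modelled as a
descriptive target, not a mechanism: after variants are drawn, ER−
`APOBEC3C` values are re-drawn from a Gaussian copula against the C>T/G>A
burden ranks with latent correlation $2\sin(\pi\rho_S/6)$ (default target
−0.26). Whether that association is causal or compositional is not a
question the generator answers.

Methylation tracks place a CpG every 50 bp across TSS ± 5 kb per cell
type; depth is Poisson (mean 30), the methylation ratio is beta-drawn —
promoter shapes within ±0.5 kb (defaults Beta(1,9)/Beta(2,8) for
normal/tumor-like tracks, mean 0.1–0.2), flank shapes Beta(7,3) (mean
0.7) — and the methylated count is binomial. A zero first (second) beta
shape forces ratio 0 (1) exactly, for degenerate-case tests.

**Reproducibility.** One root seed spawns deterministic child streams in a
documented order — (1) metadata, (2) expression, (3) variants,
(4) methylation, (5) `APOBEC3C` coupling — so identical configurations and
seeds give byte-identical cohorts and written files, and omitting a
component (`include=`) does not shift the others' streams.

What the generator emulates is the *statistical* structure: stratum
fractions, overdispersed burdens, an expression-coupled TCW-concentrated
signature, promoter-vs-flank methylation contrast. What it does not
emulate: genomic position structure (variants are uniform over a synthetic
chromosome), kataegis clustering, replication-timing or expression-level
covariates of mutation rate, sample contamination or subclonality, batch
effects, or CN0 tumors acquiring TCW mutations from APOBEC3B-independent
sources. Passing tests therefore demonstrate correctness of the analysis
machinery under the stated model, not robustness to every artefact of real
tumor data.

```{r example}
cfg <- sim_config(n_tumor = 120, n_normal = 10, seed = 7)
cohort <- simulate_cohort(cfg)
exomes <- cohort$metadata[cohort$metadata$has_exome, ]
spec <- count_spectrum(cohort$variants, exomes)
spec$burden_summary
associate_burden_expression(spec, cohort$expression, "APOBEC3B",
                            exomes)$summary
```

# Verification strategy and problem sizes

The test suite pairs every statistic with an independent oracle:
recursive-enumeration permutation nulls for Spearman, bitmask subset and
sign-pattern scans for the rank tests, direct hypergeometric summation for
Fisher, an `lm()`-based tricube fit for the smoother, and naive tallies
for spectra and motif tables; base R's `cor.test`, `wilcox.test` and
`fisher.test` serve as additional cross-checks where their conventions
coincide. Monte-Carlo checks run at sizes chosen to keep the full suite
around half a minute: 500 background-only cohorts of 15 exomes for the
excess-rate null (mean within 3 SEs of 0), 200 signature-vs-background
pairs of 25 exomes for enrichment power, 1000 equal-size null pairs for
Fisher calibration, 20 cohorts of 600 tumors for correlation-target
recovery (median within ±0.10), 2000 null pairs for rank-sum type-I error,
and a single 5000-exome cohort for burden moments (within 5%). Coverage
claims estimated from k replicates include binomial sampling slack in
their thresholds; fixed-seed determinism makes every run identical.

# Known limitations

* Expected motif counts condition on the realized class total; sampling
  error in the background composition itself is not propagated.
* The excess rate is undefined (NA) for motifs with zero background
  frequency; such motifs are reported, not dropped silently.
* `loess_smooth` evaluates only at observed x values and does not
  extrapolate; curves from strata with < 5 samples are skipped along with
  the stratum.
* RPKM is the only normalization offered (no TPM/TMM, no batch
  correction), matching the expression unit the analysis is defined in.
* The simulator's clinical variables shift expression means but are not
  linked to burden or survival time; survival-time modelling is explicitly
  out of scope.
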