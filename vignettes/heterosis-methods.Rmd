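---
title: "Methods: mid-parent heterosis, non-additive expression and allele-specific bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mid-parent heterosis, non-additive expression and allele-specific bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterosim)
```

# Scope

`heterosim` analyses replicated F1-hybrid versus parent experiments of the
kind used to study heterosis in self-pollinating crops. It covers four
linked questions:

1. **Field performance.** Does the F1 out-yield the mid-parent value, and
   does the F2 show inbreeding depression? (`heterosis_report`,
   `fit_location_model`, `trial_contrast`, `pooled_contrast`)
2. **Transcriptome-level additivity.** Which genes is the F1 expressing
   outside the interval spanned by its parents?
   (`differential_calls`, `classify_gene_categories`)
3. **Allelic balance.** At parent-distinguishing SNPs, does the F1
   transcribe both parental alleles equally?
   (`call_parent_specific_snps`, `bias_calls`)
4. **Functional signal.** Are the non-additive or biased gene sets
   enriched for annotation terms? (`sea`, `enrichment_report`)

Every stage has a truth-parameterized generator (`trial_truth` /
`simulate_trial` and friends), so the full pipeline can be exercised and
calibrated without field or sequencing data.

# Field-trial model

## The linear model

Each location is analysed separately as a randomized complete block
design (RCBD) with optional polynomial spatial trend:

$$ y_{ijk} = \mu + g_i + b_j + \sum_{d=1}^{4} \rho_d r_{ijk}^d
           + \sum_{d=1}^{4} \gamma_d c_{ijk}^d + \varepsilon_{ijk} $$

where $g_i$ is the genotype effect, $b_j$ the block effect, and $r$, $c$
are the centred and scaled plot row and column coordinates. The error is
assumed i.i.d. normal within a location; locations are allowed different
error variances and are combined only at the contrast level.

## Outlier screening

Before fitting, externally studentized residuals are computed per
location under the full model (`studentized_residuals`; these equal the
leave-one-out deletion residuals scaled by the deleted-fit standard
error, and the unit tests verify this against a brute-force refit
oracle). Observations with |residual| > 3 are dropped in a single pass
(`flag_outliers`). A single pass is deliberate: iterating the rule on
small trials can cascade and hollow out a genotype.

## Trend covariate selection

The row/column polynomial terms (degree 1–4 per axis) are pruned by
backward elimination on sequential (type-1) F tests at
`alpha_covariate = 0.05` (`select_trend_covariates`). Two rules shape
the search:

* **Hierarchy** — a lower-order term is never dropped while a
  higher-order term of the same axis remains, so only axis-maximal terms
  are candidates at each step.
* **Worst-first** — among candidates failing the test, the largest
  p-value is removed and the model refitted.

Aliased terms (possible when the layout confounds an axis with blocks)
are treated as removable with p-value ∞.

## Contrasts and pooling

Heterosis is measured by single-degree-of-freedom contrasts on the
adjusted genotype means:

* F1 vs mid-parent: $L = \mu_{F1} - (\mu_{P1} + \mu_{P2})/2$
* F2 vs mid-parent: $L = \mu_{F2} - (\mu_{P1} + \mu_{P2})/2$

`trial_contrast` computes $L$, its standard error from the coefficient
covariance, and a t test on the residual degrees of freedom. Tests are
one-sided (gain over mid-parent) for yield and harvestable protein,
two-sided otherwise, matching the directional hypotheses usual for
heterosis traits. Across locations, `pooled_contrast` combines estimates
by inverse-variance weighting with Satterthwaite degrees of freedom
$\nu = (\sum w_i)^{-2} \big/ \sum w_i^2/\nu_i$ evaluated on the
per-location variances. This is a fixed-effect combination; with only
two locations a location-random-effect variance is not estimable, so we
do not attempt one.

Harvestable protein, if absent from the plot table, is derived per plot
as `yield * protein / 100` (protein is in g/100 g).

# Expression classification

Expression values are compared between genotypes with a Welch two-sample
t test on `log2(x + pseudocount)` (default pseudocount 1), gated by a
fold-change requirement: a gene is differential only if
`|log2FC| >= log2(min_fold)` with `min_fold = 2` — the ≥2-fold gate is
**inclusive**, so an exact 2-fold change passes. The fold change itself
is computed on floored means,

```
log2FC = log2(max(mean1, pseudocount) / max(mean2, pseudocount))
```

so that zero-expression groups give finite, sign-correct values rather
than ±Inf; the floor and the test's pseudocount are the same parameter.

A gene's category comes from its two calls (F1 vs P1, F1 vs P2):
up/up → `above_both`, down/down → `below_both` (the two non-additive
classes), one direction and one null → a single-parent class, opposite
directions → `crossover`, both null → `not_de`. `category_counts`
tabulates these, and `cross_location_concordance` reports the $R^2$ of
log2 fold changes over genes significant at both locations plus the
direction-agreement fraction.

With zero within-group variance the Welch statistic is undefined; the
package defines p = 1 when the group means are equal and p = 0
otherwise, which is the correct limit and makes noise-free simulations
classifiable.

# Allele-specific bias

## Site filtering

Starting from per-sample allele depths (`read_allele_depth` accepts a
simple VCF with `AD` fields or a long TSV):

1. **Splice-proximity masking** (`mask_splice_proximal`): sites within
   2 bp of an exon–intron boundary are removed, because alignment around
   splice junctions misassigns alleles. Boundaries come from intron
   intervals in BED convention via `junctions_from_bed`.
2. **Parent-specific SNP calling** (`call_parent_specific_snps`): a site
   is usable only if, in *every* parental replicate at *both* locations,
   one parent is effectively homozygous for the alternative allele and
   the other for the reference (minor-allele fraction ≤ 0.05) with depth
   ≥ 8. Any missing or shallow parental replicate rejects the site —
   silently passing a half-genotyped site would be worse than losing it.

The 5% residual tolerance reflects sequencing error plus residual
heterozygosity: one parent in the motivating design is an F4-derived
line, expected ~12.5% heterozygous ($1/2^{t-1}$ at generation $F_t$).

## Bias calling

For each surviving SNP and location, F1 replicate fractions of the
origin-parent allele are pooled by summing counts (weighting replicates
by depth). A SNP is *biased* iff

* the pooled majority fraction strictly exceeds the threshold
  (`max(p, 1-p) > 0.73`; exactly 0.73 is never biased), **and**
* all evaluable replicates fall on the same side of 0.5.

The fixed 0.73 default corresponds to two standard deviations of the
pooled-fraction distribution above one half in the motivating
experiment; `empirical_threshold` recomputes `0.5 + 2*sd(fractions)`
(floored at 0.5) from the data at hand and needs at least 30 fractions.
`substitution_class_test` provides a Fisher exact test for
over-representation of C→T/G→A substitutions among biased SNPs, the
signature expected if bisulfite-detectable methylation differences drove
the bias. `summarize_gene_bias` lifts SNP calls to genes and
`cross_location_bias_concordance` compares the two locations.

# Enrichment

`sea` is a singular enrichment analysis: for each term with at least
`min_term_size = 5` annotated background genes, the upper-tail
hypergeometric probability
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)` of seeing ≥ k annotated
genes in a study list of n, with Benjamini–Hochberg FDR across terms.
The background should be the *expressed* gene set, not the genome —
using the genome inflates enrichment of anything transcription-related.
`enrichment_report` emits a single `NONE` row when nothing passes, so
downstream tables always have a row per comparison.

# Synthetic data: realism and limits

The generators are designed for *calibration*, not biological mimicry:

* **Trials** (`simulate_trial`): genotype mean + normal block effect +
  optional row/column polynomial + normal error, laid out in one column
  band per block. Defaults (5 blocks, replicate counts 1/3/6/6 for
  F1/F2/parents, two locations) copy the motivating design, where F1
  seed is scarce. The F1 mean is always derived as
  mid-parent + `heterosis_shift`, so the planted effect is the exact
  estimand of the F1 contrast.
* **Expression** (`simulate_expression`): per-gene baselines are
  log-uniform over ~3 decades; replicate noise is log-normal with a
  coefficient of variation (`replicate_cv`, default 0.2 — typical
  between-replicate variation for RNA-seq FPKM at moderate expression),
  mean-corrected by $e^{-\sigma^2/2}$ so the planted mean is the true
  mean. Category truth (`above_both`, `parent_dominant`, …) is planted
  per gene with a fixed fold.
* **Allele counts** (`simulate_allele_counts`): Poisson total depth,
  binomial (or beta-binomial, `overdispersion`) allelic split at 0.5 or
  `bias_level`; residual heterozygosity makes a parental replicate
  heterozygous with probability `residual_het_rate`, which is what makes
  the parent-specific filter's rejection path exercisable.

Known limits: no spatial correlation beyond the polynomial trend, no
genotype × location interaction in the generator (locations differ only
through separate noise draws), expression counts are continuous FPKM-like
values rather than integer counts, and reads are independent across
sites (no haplotype linkage).

# Numerical and design decisions

* Adjusted genotype means and their covariance are computed by applying
  an L-matrix (genotype at equal block weights and mean covariate
  values) to the `lm` coefficient vector and `vcov`; contrasts then
  reduce to $L\beta$ algebra and are verified in the tests against a
  direct normal-equations solve.
* All simulation is plain base-R RNG seeded via `set.seed`; a run is a
  pure function of its config, and the pipeline derives distinct
  per-stage substreams (`stage_seed`) so enabling or disabling one stage
  does not shift another stage's draws.
* The pipeline (`run_pipeline`) writes only delimited text plus a JSON
  manifest; the manifest is the only file with a timestamp, so analytic
  outputs are byte-identical across reruns.
* Typical problem sizes are small: tens of plots per location, $10^3$ to
  $3\times10^4$ genes, $10^2$ to $10^4$ SNP sites. Everything is
  vectorized per gene/site group; a full default pipeline run takes a
  few seconds on one core.

# A worked micro-example

```{r example}
plots <- simulate_trial(trial_truth(seed = 42, heterosis_shift = 200))
rep <- heterosis_report(plots, traits = "yield")
rep[rep$contrast == "F1_vs_midparent", ]
```

The pooled row estimates the planted 200 kg/ha shift with its standard
error and one-sided p-value.
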