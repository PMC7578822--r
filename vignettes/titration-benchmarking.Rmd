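---
title: "Benchmarking RNA-seq pipelines with titration mixture designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking RNA-seq pipelines with titration mixture designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrabench)
```

## The mixture design and its two laws

The benchmark rests on a titration design: reference RNA samples A and B
are mixed by mass into C (3 parts A, 1 part B) and D (1 part A, 3 parts B).
Mass fractions do not translate directly into expression fractions because
the two references differ in mRNA concentration; with
$z = \mathrm{[mRNA]}_A / \mathrm{[mRNA]}_B = 1.43$, a mass fraction $p$ of A
contributes $pz$ parts of mRNA against $(1-p)$ parts from B, so the
per-mRNA expected expression of the mixtures is

$$C = \frac{3zA + B}{3z + 1}, \qquad D = \frac{zA + 3B}{z + 3}.$$

This is the unique mixing law consistent with both the 3:1/1:3 mass design
and the expected mixing ratio

$$\mathrm{EMR}_{C,D} = \frac{3zR + 1}{zR + 3}\cdot\frac{z+3}{3z+1},
\qquad R = A/B,$$

which `emr_expected()` implements and `mixture_expression()` reproduces as
$C/D$ for every $(A, B, z)$ — a property the test suite checks on 1,000
random triples. Two consequences follow for every gene, and they are the
entire basis of the reference-set filters:

* **Titration order (TO)**: $A \ge C \ge D \ge B$ or the reverse, because
  $C$ and $D$ are convex combinations of $A$ and $B$ with ordered weights.
* **EMR**: the observed $C/D$ ratio must match $\mathrm{EMR}_{C,D}$.

Single-replicate qPCR measurements carry roughly 15% relative noise, so
both filters compare margin-widened quantities with $a = 1.15$ and
$b = 0.85$ (± one standard deviation around each measurement). The TO
chains compare $a\bar q$ against $b\bar q$ link by link; the EMR criterion
accepts a gene when the intervals $[bR, aR]$ and
$[b\,\mathrm{EMR}, a\,\mathrm{EMR}]$ overlap, equivalently
$\mathrm{EMR}\cdot b/a \le R \le \mathrm{EMR}\cdot a/b$. With replicated
qPCR ($N > 1$) the margins default back to $a = b = 1$, the strict
multi-replicate ordering. Equality always satisfies the inequalities, and a
gene with $\bar q_D = 0$ is excluded from the EMR set with provenance
"undefined ratio" rather than guessed.

`build_reference_set()` chains detectability (non-zero everywhere and
Ct ≤ 35 when cycle thresholds are available), TO, EMR and — when count
matrices are supplied — non-zero counts in every replicate of every sample,
site and pipeline. The low-expressing subset is the round-half-up 20% of
reference genes with the smallest unweighted mean qPCR expression over
A–D; round-half-up reproduces the canonical 10,222 → 2,044 arithmetic.

## Normalization

All six normalizations are library rescalings $y = x \cdot s_{s,n}$ whose
factor statistics are computed **only on present genes** — per site, a gene
is present when its replicate-mean counts satisfy
$(\bar x_A > 1 \lor \bar x_B > 1) \land \bar x_C > 1 \land \bar x_D > 1$
(strict inequalities), and the final set is the intersection over sites.
All genes are then rescaled, present or not. Per site:

| method | factor |
|---|---|
| FPM | $\bar x / x_{s,n}$ (average over site total per-library present-gene count) |
| median / UQ | site-average of per-library medians / 75th percentiles over the library's own |
| FPKM | FPM times $\bar\ell / \ell_k$ (average present-gene length over the gene's) |
| TMM / RLE | FPM divided by the robust factor $\hat f_{s,n}$ |

The TMM factor is the inverse-variance-weighted mean of M-values after
trimming 30% (two-sided) on M and 5% on A, with the reference library the
one whose present-gene upper quartile of library-size-scaled counts is
closest to the site mean — the method's original published defaults, since
only the implementing package is cited. We compute raw per-library factors
(reference factor exactly 1) rather than geometric-mean-centred ones, which
is what the $y = x\bar x/(x_{s,n}\hat f)$ form requires; the test suite
cross-checks factor *ratios* against edgeR, which centring leaves
invariant. RLE is the median over genes of the ratio to the gene-wise
geometric-mean pseudo-library, with zero-containing genes excluded.
Quantiles use linear interpolation (R type 7) throughout; this dialect
choice is fixed package-wide.

Cross-site joint normalization is deliberately not offered: the framework
normalizes within each site and averages metrics across sites afterwards.

## The three benchmark metrics

For a pipeline's normalized matrix and the reference genes (evaluated once
on all reference genes and once on the low-expressing subset, per site,
then averaged over sites — per-site values are retained):

* **Accuracy** — $\Delta_k = \lvert \log_2(\bar x_{A,k}/\bar x_{B,k}) -
  \log_2(\bar q_{A,k}/\bar q_{B,k})\rvert$, summarized by the median over
  genes. Smaller is better. The A/B pair is the default; other pairs are
  configurable. Note the metric is *not* invariant to a per-sample scale
  mismatch between platforms — that mismatch is part of what distinguishes
  normalization methods.
* **Precision** — the coefficient of variation of each gene in each sample
  across replicate libraries, with the $n-1$ standard deviation, median
  over all gene–sample cells. Dimensionless; smaller is better.
* **Reliability** — per gene, the intraclass correlation
  $\mathrm{ICC}(1,k) = (\mathrm{BMS} - \mathrm{WMS})/\mathrm{BMS}$ from the
  balanced one-way random-effects ANOVA with samples as groups and
  replicate libraries as observations; median over genes. Negative values
  (WMS > BMS) are reported as computed, not clamped; genes with BMS = 0 are
  dropped with a logged count.
* **Reproducibility** — the median Spearman correlation between replicate
  libraries of the same sample is provided (`reproducibility_metric()`)
  but, because its dynamic range is small, it is not part of the default
  report.

Whether a cross-site summary should pool libraries or average per-site
values is not fixed by the framework's sources; we average per-site values
and keep both.

## Variance decomposition, ranking, and the downstream harness

`anova_decomposition()` fits a linear model of a per-pipeline response on
the five categorical design factors (mapping algorithm, mapping strategy,
mapping reporting, quantification, normalization) and all two-way
interactions, and reports the sequential (Type-I) table with
% of total sum of squares per term. The factors are partially confounded —
strategy and reporting are attributes of the algorithm — so some
interactions are fully aliased; the fit drops them and the decomposition
lists them in `dropped`. Sums of squares plus residual always reproduce
the total, and percentages sum to 100 (asserted in tests).

Ranking uses average ranks (rank 1 = best; accuracy and precision are
better-lower, reliability better-higher; ties get average ranks) over any
of the 12 metric subsets: {all three metrics, each pair} × {all genes,
low-expressing, both}. `select_extremes()` takes the round-half-up
10% deciles with boundary ties broken by pipeline ID, so selection is
deterministic. The good-vs-poor comparison is a one-sided Wilcoxon
rank-sum test; for combined sizes ≤ 25 the p-value is computed exactly by
dynamic programming over doubled midranks (so ties are handled exactly),
larger samples use the normal approximation with continuity and tie
corrections.

The phase-2 harness dichotomizes survival at a threshold (2 years for
event-free survival, 3 for overall survival, by convention): events at or
before the threshold are high-risk, events after it — or censoring with
follow-up reaching it — low-risk, and patients censored *before* the
threshold are excluded, because their class at the threshold is unknowable;
the exclusion list is reported. Features are $\log_2(x+1)$ expression;
mRMR (difference form, relevance minus mean redundancy of mutual
information on equal-frequency 3-bin discretizations) orders genes, and
nested cross-validation — 3-fold inner selection of the feature size over
{5, 10, …, 40} by mean inner AUC, 5-fold outer evaluation, 10 iterations by
default — produces per-iteration AUC and MCC from pooled held-out
predictions. Greedy mRMR orderings are nested, so one ordering per inner
fold serves every candidate size as a prefix. Classifiers are pluggable
fit/score pairs; logistic regression, a radial SVM and gradient-boosted
stumps (depth-1 xgboost, the adaptive-boosting role) ship with fixed small
hyperparameters. Inner-fold model selection optimizes AUC (configurable in
principle; the choice among AUC/MCC/accuracy is not dictated by the
framework's sources). Kaplan–Meier stratification of predicted risk groups
is tested with the two-tailed log-rank test, and the stratification success
rate is the fraction of runs with p < 0.05.

## What the simulator emulates — and what it does not

`simulate_benchmark()` draws per-gene true expression for A (log-normal,
`meanlog` 3, `sdlog` 1.2) and symmetric log₂ A/B fold changes (SD 1.5),
derives C and D from the mixing law, and emits

* a single-replicate qPCR table with independent multiplicative log-normal
  noise at CoV `qpcr_cov` (default 0.15, the conventional figure for
  single qPCR measurements);
* count matrices for 2 sites × 4 samples × 4 replicate libraries with
  expected counts proportional to expression × gene length, scaled to a
  uniformly drawn library size (default 0.5–2 million fragments), with
  negative-binomial noise (dispersion default 0.005, giving replicate CoVs
  of a few percent at this depth; dispersion 0 turns count noise off
  entirely, yielding deterministic expected counts — required for the
  exact pass-rate checks);
* planted **violators**: a configured fraction of genes has C multiplied or
  divided by a factor beyond $(a/b)^2$, guaranteeing the EMR filter detects
  them in the noiseless limit (flag count is exactly
  round(`violator_fraction` × `n_genes`)).

`simulate_clinical()` draws a balanced latent risk group, lognormal
(accelerated-failure-time) event times with medians 1 year (high risk) and
8 years (low risk) and `sdlog` 0.5 — chosen so the usual 2–3-year
dichotomization thresholds mislabel only a few percent of either group —
independent exponential censoring calibrated to the configured marginal
rate, and log-normal expression in which `signal_genes` genes are shifted
between risk groups by `effect_size` within-group SDs on the log₂ scale.

The simulator does **not** model reads (no FASTQ, no sequencing-error or
positional-bias models), batch effects between sites beyond library-size
differences, correlated qPCR errors across samples, gene–gene expression
correlation, or competing risks. Passing tests on simulated data therefore
demonstrate the estimators' correctness and the framework's internal
consistency, not the behaviour of any particular aligner or quantifier on
real libraries.

One consequence of the independent qPCR noise model is worth stating
plainly: the observed C/D ratio of a conforming gene carries log-noise
$\sqrt2\,\sigma \approx 0.21$ (plus the EMR side's ≈ 0.10) against an
acceptance band of ±log(1.3529) ≈ 0.30, so the EMR filter can retain at
most ~80–85% of conforming genes at CoV 0.15 no matter the gene mix, while
the TO filter retains ≈ 96%. The filters are intentionally conservative: a
smaller, cleaner reference set is preferred over a larger contaminated
one.

## Numerical and design choices

* Round-half-up for subset sizes (low-expressing genes, selection deciles);
  base R's round-half-even would be invisible at the canonical sizes but
  the convention is fixed and tested.
* Quantile type 7 everywhere a quartile or median of data is taken.
* Huber regression uses the standard tuning constant 1.345 (95% Gaussian
  efficiency) via IRLS; an exact fit is returned as the OLS solution, since
  a zero scale estimate makes the reweighting degenerate.
* `distribution_profile()` computes entropy as Shannon entropy (bits) of a
  64-bin equal-width histogram of $\log_2(x+1)$ with empty bins
  contributing zero — entropy of an expression distribution has no unique
  definition, so a reproducible convention is fixed; constant vectors have
  entropy 0. Kurtosis is excess kurtosis; skewness and kurtosis of a
  constant vector are reported as 0.
* The exact Wilcoxon threshold is a combined n of 25; the DP over doubled
  midranks makes the exact branch tie-correct without enumeration.
* All simulation and cross-validation code is seeded; identical
  configurations reproduce byte-identical outputs, and each CV iteration
  refolds with `seed + iteration`.

## Problem sizes used in the validation suite

The self-validation experiments are sized for a single CPU: filter
exactness on 1,000-gene simulations, retention under noise on 4,000 genes,
ICC recovery on 5,000 genes × 50 groups × 4 replicates (50 groups rather
than 4 so the median of the per-gene ICC estimate sits within ±0.01 of the
population value 0.8 — with 4 groups the estimator's median bias is ≈ 0.04),
distortion recovery on 800 genes, and a 40-pipeline distortion panel whose
top and bottom deciles (4 + 4 pipelines) are evaluated by nested CV with 2
iterations on a 200-patient, 300-gene cohort with 20 signal genes. The
distortion panel perturbs the benchmark matrix with per-gene-per-sample
log₂ biases (degrading accuracy) and per-cell noise (degrading precision
and reliability), and the clinical matrix with per-cell noise only, all
scaled by a severity grid from 0 to 1, so better-ranked "pipelines" are
exactly those with less distortion.

## Known limitations

* The gene universe intersection with count matrices is a plain ID
  intersection; no transcriptome annotation matching is performed.
* TMM/RLE homogeneity under rescaling of a single library holds only up to
  re-estimation of the robust factor on unchanged gene proportions.
* The ANOVA is sequential; with the confounded factor structure, term
  order matters and is fixed to the conventional listing (mapping
  algorithm, strategy, reporting, quantification, normalization).
* `nested_cv` assumes both classes survive stratified folding; degenerate
  folds are skipped rather than refolded when a class is extremely rare.
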