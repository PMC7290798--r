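---
title: "Methods: QC filtering, normalization and differential analysis of untargeted LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC filtering, normalization and differential analysis of untargeted LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboflow)
```

## The problem

An untargeted UHPLC-MS experiment produces a matrix of peak areas: one row
per *feature* (an m/z–retention-time pair), one column per injection. The
injections mix three roles: biological samples, *pooled QC* injections (an
aliquot mixture of every study sample, injected repeatedly to measure purely
technical variability), and *blank* extractions (no tissue; signal there
marks non-biological contaminants). Before any biology can be read off the
matrix, the table has to be cleaned of unreliable features, missing values
have to be filled in, per-sample dilution has to be corrected, and the
heavy-tailed intensity scale has to be stabilized. `metaboflow` implements
that whole chain as small pipeable functions on one container, the
`metab_table`, plus a seeded simulator that generates batches with known
ground truth so every stage can be tested for *recovery*, not just for
running without error.

The run design the simulator emulates is a typical three-group rodent
study: non-diabetic vehicle (`ND-V`), diabetic vehicle (`DIAB-V`) and
diabetic treated (`DIAB-LAV`), n = 6 per group by default, with ten lead QC
injections, a QC every sixth injection, two closing QCs and two blanks.
Published descriptions of such batches are internally inconsistent about
blank placement (a blank as the 6th injection versus ten leading QCs); the
generator resolves this as 5 QCs, 1 blank, 5 QCs for the lead block, with
the second blank immediately before the two tail QCs.

## The simulator

Peak areas are positive and their technical noise is characterized by
relative standard deviation, so all noise is multiplicative log-normal, not
additive Gaussian. For feature $f$ with log-normal baseline $b_f$:

* biological sample $s$ in group $g$:
  $x_{fs} = b_f \cdot 2^{e_{fg}} \cdot d_s \cdot \varepsilon$, with planted
  log2 effect $e_{fg}$, dilution factor $d_s$ drawn log-uniformly from
  $[0.7, 1.4]$ (so PQN has something to recover), and
  $\varepsilon = \exp(N(0, \sigma_{bio}))$ with $\sigma_{bio}$ set from a
  25% biological CV;
* pooled QC at injection $k$:
  $x_{fk} = \bar{x}_f \cdot \varepsilon' \cdot (1 + \delta)^k$, the pooled
  mean of the biological expectations times technical noise (10% CV) and a
  geometric injection-order drift ($\delta = 0.002$ per injection) — the
  simplest model of the signal drift that pooled QCs exist to monitor;
* blanks: no signal (missing) except for *contaminant* features (5% of
  features by default), which appear in blanks at sample-like level.

Missingness is intensity-dependent (each feature's values below its 5%
quantile are censored) plus 2% missing completely at random. A *disease*
effect is shared by both diabetic groups — so it cancels in the
treated-vs-untreated contrast — while a *treatment* effect shifts only the
treated group; effect prevalences (25% disease, 3.5% treatment, the latter
95% upward) and the noise CVs are documented stand-ins for a realistic
cardiac study, not measured values. Everything is drawn under one seed;
identical config and seed give byte-identical output.

What the simulator deliberately does not model: retention-time drift,
isotope patterns, correlated co-eluting ion clusters, batch boundaries, or
heteroscedastic detector saturation. Passing recovery tests on simulated
batches therefore shows the pipeline's arithmetic and decision rules are
right under the stated error model; it does not certify performance on any
particular instrument's quirks.

## The QC filter cascade

`run_qc_cascade()` applies, in the narrative order of standard QA/QC
practice, with every removal recorded in a serializable `filter_report`:

1. **Equilibration removal** — the first five QC injections condition the
   column and are dropped before any statistic is computed.
2. **Blank ratio** — a feature is removed when its mean QC intensity is
   *less than* 20 times its mean blank intensity. A missing blank value is
   a true absence and counts as zero; a missing QC value is an unreliable
   measurement and is excluded from the mean rather than zero-filled
   (zero-filling would deflate QC means and over-remove).
3. **Sample missingness** — any sample, of any role, with more than 50%
   missing values is excluded.
4. **Pooled-QC RSD** — features with $100 \cdot sd/\bar{x} > 30$ over their
   observed QC values are removed. The $n-1$ sample standard deviation is
   used, the convention for repeatability estimates; features with fewer
   than two observed QC values cannot be assessed and are removed.
5. **QC detection rate** — removed if detected in less than 90% of QCs.
6. **Overall detection rate** — removed if detected in less than 50% of all
   remaining samples (all roles by default; `overall_detection_bio_only`
   restricts it to biological samples).

Two cross-cutting decisions: every boundary comparison is **strict** —
exactly 20×, exactly 30% RSD, exactly 90% / 50% detection all survive — and
all filters evaluate **raw** (pre-normalization) intensities, since
filtering precedes the analysis transforms. The stage list is configurable
(`qc_config(stages = ...)`) but the default order above is the reference
behaviour. Each stage is idempotent, and the report's counts reconcile
exactly (`n_in − Σ removed = n_out` per axis).

## Imputation, normalization, transformation

**kNN imputation** (`knn_impute()`, k = 5) works in feature space: a
missing cell is predicted from the k features most similar to its row,
because co-varying features carry information about each other (the
microarray-era convention). Distance is Euclidean over the samples where
both features are observed, scaled by the number of shared samples so that
sparsely-shared neighbours are not favoured; the imputed value is the
inverse-distance-weighted mean of the neighbours' values in that sample,
with zero-distance neighbours taking all the weight. Observed values are
never modified.

**PQN** (`pqn_normalize()`) estimates each sample's dilution as the median
of its feature-wise quotients against a reference spectrum — the
per-feature median over the pooled QCs by default, since the QCs are the
batch's technical reference (an all-sample median is available). Dividing
by the factor corrects dilution exactly when a sample is a scalar multiple
of the reference, and the returned factors make the correction auditable.
PQN is exactly idempotent only on such pure-dilution data; on noisy data
the recomputed reference makes second-pass factors deviate from 1 by
roughly the median-quotient sampling error (about 1% at a few hundred
features), which the tests document.

**glog** (`glog_transform()`) replaces $x$ with
$\ln\!\big((x + \sqrt{x^2 + \lambda^2})/2\big)$: logarithmic for
$x \gg \lambda$, linear near zero, variance-stabilizing for the standard
two-component (multiplicative + additive) error model. The natural-log base
only shifts scale and never affects test statistics. When $\lambda$ is not
supplied, `estimate_glog_lambda()` picks it on a 61-point log-spaced grid
(10⁻⁴ to 10³ times the median QC intensity) by minimizing the mean absolute
deviation of per-feature QC variances from their grand mean, *relative to
that mean*. The normalization matters: large $\lambda$ shrinks every
variance toward zero, so an unnormalized spread criterion would be
trivially minimized by $\lambda \to \infty$ instead of by stabilization.
Ties take the smallest grid value, making the estimate deterministic.

**TPA** (`tpa_normalize()`) divides each sample by its total peak area;
`median_total` rescaling (the default) multiplies back by the median of the
original totals so magnitudes stay on the familiar scale, `unit_sum` leaves
columns summing to 1. The choice is a display convention — fold changes and
tests are invariant to it.

Two processing branches mirror standard practice: **branch A**
(impute → PQN → glog) feeds the PCA used to check that QC injections
cluster tightly inside the biological spread; **branch B** (impute → TPA)
feeds the univariate analysis, with t-tests run on glog-TPA values and fold
changes computed on un-glogged TPA values, so the ratio estimate is never
distorted by the transform. Whether fold changes should use imputed data is
not settled practice; here they do, and the choice is configurable only by
filtering harder upstream.

## Differential analysis and contrast classification

Per feature and contrast, `run_differential()` computes a two-sided t-test
p-value (Welch by default — unequal group variances are typical of disease
models; pooled-variance Student optional) and the fold change
$\bar{x}_A / \bar{x}_B$. A feature is called differential iff $p < 0.05$
**and** the fold change lies strictly outside $[0.8, 1.2]$; both boundaries
survive. No multiple-testing correction is applied by default — the raw-p +
fold-change-window rule is the reference behaviour — but
`stats_config(p_adjust = "BH")` enables Benjamini–Hochberg, and with it the
planted-effect calls dominate false positives by an order of magnitude in
the recovery tests. Degenerate inputs never crash: fewer than two
observations per group gives an `NA` p-value with a warning, and
essentially-constant data takes the limit of the t statistic (p = 1 for
equal means, 0 otherwise), which is what makes noise-free recovery tests
exact.

`compare_contrasts()` partitions the significant sets of two contrasts into
unique/shared, with percentages relative to each contrast's significant set
(full precision kept; display rounds to integer percent).
`classify_reversion()` splits the shared features by the sign product of
the two log2 fold changes: treatment *reverts* a feature when it moves it
against the disease shift (product < 0), *exacerbates* it when it pushes
the same way, with a zero effect classed `mixed`.

Two small validation statistics round out the module: `mann_whitney()`
(exact two-sided p by full enumeration of all group labelings for combined
n ≤ 12 — 924 labelings at worst, exact even under ties via midranks —
normal approximation with tie and continuity correction above that) and
`ddct_fold_change()`, the 2^−ΔΔCt relative-quantification formula for qPCR
with a reference gene.

## Putative annotation

`match_features()` is a deliberately simplified stand-in for full
correlation-based annotation workflows: every (compound, adduct) pair whose
polarity matches a feature and whose theoretical m/z
$(M + \text{shift})/|z|$ lies within the assay's ppm tolerance (12 ppm
HILIC, 14 ppm LIPIDS, **inclusive** boundary) is emitted as a hit at
Metabolomics Standards Initiative level 2 — putative, never collapsed to
one hit per feature, because isomers and multiple ion forms are genuinely
ambiguous at accurate mass alone. The default adduct set is protonated,
sodiated and ammoniated ions in positive mode, deprotonated and formate in
negative; shifts include the electron mass ([M+Na]⁺ is +22.989218 Da). The
bundled ~50-compound list spans amino acids, organic acids,
acyl-carnitines, glycerophospholipids, ceramides, TAGs and a cardiolipin;
it is a testing aid with masses verified against its formulas at load time,
not a curated resource. `group_features_by_rt()` provides the companion
co-elution grouping: single linkage with a 2 s window, so chains of
features each within 2 s of the next form one group, invariant to input
order.

## Numerical and design notes

* Missing is `NA`, never 0; `zero_is_missing` (default on) maps literal
  zeros to missing on ingest because peak-picking exports use both
  conventions. Retention times are stored in seconds (`rt_unit` converts).
* All user-facing files are keyed by id, never by position; subsetting a
  `metab_table` keeps matrix and metadata aligned by construction.
* The alpha rule is strictly-less-than and the fold-change window strictly
  outside; every filter boundary is strict as documented above.
* kNN ties at equal distance share weight equally; the lambda grid breaks
  ties toward the smallest value; RT grouping sorts by (rt, id) so group
  numbering is reproducible.
* `run_pipeline()` writes every intermediate table to disk so each stage is
  independently inspectable, and the summary JSON is byte-identical across
  runs with the same seed.

Test problem sizes were chosen to make the stochastic properties sharp but
quick: 600 features × 21 biological samples for dilution-recovery (measured
correlation ≈ 0.996 against planted factors), 1000 features for the type-I
error check (fraction of null features at p < 0.05 within two binomial
standard errors of 0.05), 2000 features with 200 planted two-fold effects
for power (≈ 89% recovery at n = 6 per group, 25% biological CV), and 300–
1000 features for end-to-end determinism. The empirical mean QC RSD of a
simulated batch sits within half a point of the configured 10% — the
residual being the small-sample downward bias of a sample RSD at ~15 QC
injections, which is why the convergence test uses a ±0.5-point band rather
than a standard-error band.

## Known limitations

Feature-space kNN assumes informative co-variation, which the simulator's
independent features only weakly provide; imputation on real correlated
data should do better than in these tests, not worse. PQN assumes most
features are not changing; at very high planted prevalence the dilution
estimate biases toward the effect. TPA normalization transfers part of any
large, unbalanced effect into every null feature's fold change, which is
visible as a mild excess of false positives when many features shift one
way. Annotation by accurate mass alone cannot distinguish isomers and is
reported at MSI level 2 accordingly. Drift is monitored (via QC RSD) but
not corrected — signal-correction methods are out of scope.
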