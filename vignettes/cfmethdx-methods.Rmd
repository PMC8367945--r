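---
title: "Methods: cfDNA methylation diagnostics with cfmethdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation diagnostics with cfmethdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmethdx)
```

# The problem

Tumours shed DNA into the bloodstream, and that circulating cell-free DNA
(cfDNA) carries the tumour's methylation marks. A blood-based cancer test
can therefore be built in four steps: find CpG markers that are
differentially methylated between tumour and normal *tissue*; keep only the
markers whose signal survives the journey into *plasma*; select a compact
diagnostic panel on a training cohort of case and control plasma samples;
and evaluate the resulting classifier on held-out cohorts, stratified by
disease stage. `cfmethdx` implements this whole chain, plus a synthetic
cohort generator so that every stage is testable without access to
controlled patient data.

# Read-level co-methylation scoring

Single bisulfite reads are noisy: individual CpG calls flip for technical
reasons. Tumour-derived fragments, however, tend to carry *runs* of
methylated CpGs. The package therefore scores each read, not each CpG: a
read is **co-methylated** when at least 3 of its CpG calls are methylated
within a sliding window of 3 to 5 consecutive CpG sites, and the per-region
**methylation level** is

$$\text{level} = \frac{\#\,\text{co-methylated reads}}
                     {\#\,\text{reads with} \ge 3 \text{ CpGs}}.$$

Two reading choices deserve a note. First, "window of 3–5 CpGs" is
interpreted as windows of *consecutive CpG sites* (not base pairs), and the
\(\ge 3\) methylated calls need not be consecutive inside the window.
Second, because any qualifying 3- or 4-site window lies inside a 5-site
window, the rule is equivalent to scanning only windows of length
`min(5, read length)`; the implementation keeps the general scan and a
property test asserts the equivalence against exhaustive enumeration.
Reads with fewer than 3 CpGs are excluded from numerator *and* denominator;
a region with no eligible read gets a missing level (never 0), imputed
downstream by the per-marker cohort median, which is direction-neutral.

# Marker discovery in tissue

Candidate markers are discovered by comparing tumour against matched normal
tissue per marker with the Wilcoxon rank-sum test (exact null distribution
when the combined sample size is at most 20 without ties; normal
approximation with tie and continuity correction otherwise),
Benjamini–Hochberg control of the false discovery rate at 0.05, and a floor
of 0.2 on the absolute difference in mean beta value. The delta floor is
inclusive (\(|\Delta\beta| \ge 0.2\)); testing is two-sided throughout
because diagnostically useful markers are both hyper- and hypomethylated.

# Tissue–plasma concordance filtering

A marker that is differential in tissue is only useful in a blood test if
matched patient plasma recapitulates the tissue signal. With typically only
a few dozen matched pairs, per-marker variance estimates are unstable, so
paired tissue–plasma differences are tested with a **moderated
t-statistic**: per-marker variances \(s^2_g\) are shrunk towards a pooled
prior \(s_0^2\) with weight given by prior degrees of freedom \(d_0\),

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
  \tilde{t}_g = \frac{\bar{d}_g}{\sqrt{\tilde{s}^2_g / n}},$$

with \(\tilde{t}_g\) referred to a t distribution on \(d_0 + d\) degrees of
freedom. The prior \((d_0, s_0^2)\) is estimated by matching the first two
moments of \(\log s^2_g\) to a scaled F distribution (the standard
empirical-Bayes formulation, implemented here with a Newton inversion of
the trigamma function and cross-checked in the test suite against the
`limma` reference). When the observed variances are essentially constant
the dispersion equation has no positive solution; \(d_0\) is then reported
at a large finite cap (\(10^6\)) and \(s_0^2\) as the common variance.
Setting \(d_0 = 0\) recovers the ordinary paired t-test exactly, which the
tests assert.

Retention supports two modes because "filter by a moderated t-test between
tissue and plasma at FDR < 0.05" admits two readings. The default,
`keep_concordant`, retains markers whose compartments do *not* differ
(\(q \ge 0.05\)) — the filter's purpose is to discard markers whose plasma
behaviour contradicts the tissue signal. The literal reading,
`keep_significant`, is also implemented and the applied mode is recorded on
the result. In both modes a marker must show a **dynamic methylation
range** — max minus min plasma level across the matched cohort — of at
least 0.1, a definition chosen here because the term is used in the field
without a formula; a constant marker carries no diagnostic information
regardless of concordance.

# Panel selection by stability

Two resampling procedures run on the training cohort and their selections
are intersected:

* **Repeated LASSO.** Each of 500 repetitions draws a stratified half
  subsample without replacement, standardizes markers, and fits an
  L1-penalized logistic model with the penalty chosen by internal 5-fold
  cross-validated deviance under the one-standard-error rule (sparser, more
  stable selections). A marker qualifies when it receives a nonzero
  coefficient in *strictly more than* 300 of the 500 repetitions — i.e. a
  selection frequency above 60%. The resampling scheme (half-sampling) is
  the classic stability-selection choice and is recorded in the provenance
  block.
* **Repeated cross-validated random forests.** In each of 20 repetitions
  the samples are split into two stratified folds and a 500-tree forest is
  fit on each; impurity-decrease importances are averaged over all 40 fits
  and the top 50 markers by mean importance qualify (ties broken
  lexicographically by marker id). Permutation importance is available
  behind a flag.

The final panel is the intersection, ordered by forest importance rank. An
empty intersection is returned with a warning and the downstream trainer
refuses to fit. The whole procedure is a pure function of (matrix, labels,
seed).

# Diagnostic model and evaluation

A probability random forest (500 trees) is trained on the panel columns
only. The decision threshold is fixed **on training data alone** by
maximizing Youden's J over out-of-bag scores; among J ties the largest
threshold wins, favouring specificity — the operating regime a screening
test wants. Evaluation reports:

* AUROC as the Mann–Whitney rank statistic (ties count 1/2) with a DeLong
  95% CI;
* AUPRC by step-wise precision–recall integration (tied scores handled
  block-wise, so a constant classifier scores exactly the prevalence) with
  a stratified bootstrap percentile CI (2000 resamples);
* sensitivity and specificity at the fixed threshold with Clopper–Pearson
  95% CIs, plus the full confusion partition;
* per-stage (correct, total) counts whose pooled ratio equals the overall
  sensitivity — an arithmetic identity the tests assert.

None of the CI methods is dictated by the underlying study design; they are
the standard choices for each quantity and are named in the report.
Percentages print rounded half away from zero to two decimals, matching
clinical-table convention.

Single-marker diagnostic power is assessed by one-covariate logistic
regression. Since the fitted probability is monotone in the covariate, its
AUROC equals the raw marker's AUROC oriented by the coefficient sign; both
are reported and their equality is asserted. Simplified models take the
top-k markers (default 4) among those with oriented AUROC strictly above
0.75.

A combined model appends the binary mammography reading as one additional
forest feature. Two score vectors over the same samples are compared by a
stratified paired bootstrap of the AUROC difference: the two-sided p-value
comes from recentring the bootstrap distribution at zero, and the effect
size is the observed difference divided by the bootstrap SD (a Cohen's-d
analogue; the report labels the method "bootstrap" to avoid implying any
other construction).

# Clinicopathologic association

Per-patient burden is the mean level over the panel's hypermethylated
markers (and separately the hypomethylated ones). One-way fixed-effects
ANOVA compares burden across the levels of each clinical feature, with
Bonferroni correction over the scan; `m` defaults to the number of
(feature × direction) tests actually performed and is echoed in the
output. Tumour size is binned at \(\le 20\), 20–50, \(> 50\) mm, nodal
burden at 0, 1–3, 4–9, \(\ge 10\) positive nodes, and age by decade band —
standard clinical groupings, configurable because subgroup conventions
vary. Feature levels with fewer than two observations are dropped and
single-level features skipped with a warning.

# The synthetic cohort generator

The generator emulates the *shape* of a targeted cfDNA methylation study —
matched tumour/normal tissue pairs (default 40), a case/control plasma
cohort (default 204 cancer / 129 control with a 160/69/104
train/validation/test split), a planted panel of 26 informative markers
among 200 targeted regions, per-read CpG state vectors, and a binary
mammography call (default sensitivity 0.70, specificity 0.92, typical
screening performance).

Marker levels are drawn from truncated normals: group means plus Gaussian
noise (SD 0.1), clipped to \([0,1]\). Beta distributions would be the other
natural choice; truncated normals give direct moment control and nothing
downstream depends on higher moments. Informative markers shift tissue
means by \(\pm 0.3\); baselines are drawn leaving headroom so clipping
stays rare. Cancer stages follow the whole-cohort mix 11 : 68 : 91 : 32
for stages 0–III (stage IV accepted but absent by default), and tumour
size and nodal burden are drawn stage-dependently so that the
clinicopathologic scan faces realistic correlated covariates.

Two aspects of the plasma model deserve explanation because they carry the
generator's realism:

* **Dilution.** Tumour-derived fragments are a minority of plasma cfDNA,
  so the plasma effect is the tissue shift attenuated by `plasma_frac`
  (default 0.7).
* **Per-patient detection budget.** No single cfDNA marker is altered in
  every patient — that is precisely why panels beat single markers. Each
  cancer patient therefore displays the planted aberration on a
  fixed-size random subset of the informative markers
  (`round(marker_sens * n_informative)` of them, default rate 0.7), the
  subset varying per patient. Sampling the subset without replacement,
  rather than independently per marker, reflects a roughly constant
  per-tumour marker yield and means each marker covers a unique slice of
  patients, so the selection procedures must retain the panel jointly
  rather than any small representative subset. A design with a homogeneous
  shift on all markers in all patients makes the informative markers
  mutually redundant, and repeated-LASSO selection frequencies then
  plateau well below the 60% rule for a sizeable fraction of them — a
  known property of L1 selection among exchangeable correlated predictors,
  not a defect of the markers.

The stage gradient adds `stage_gradient` (default 0.05) per stage to the
detected shift, emulating methylation burden growing with tumour burden.
With per-stage validation cohorts as small as 3–6 patients, *observed*
per-stage sensitivities are too granular for a strict monotonicity
assertion (one saturated stage-0 cell flips it); the test suite therefore
asserts monotonicity of the per-stage mean predicted case score over the
pooled held-out cancers — the same property, measured continuously — and
checks that sensitivity does not decrease from the earliest to the latest
stage.

Everything is a pure function of the configuration seed; identical
configurations reproduce byte-identical outputs.

## What the generator does not emulate

No sequencing error, bisulfite conversion failure, fragment-length
structure, batch effects, or population structure in the controls. The
matched tissue/plasma pairs used by the concordance stage are generated at
full signal (plasma = tissue + noise), emulating the high-burden surgical
patients such experiments enrol; the case/control plasma cohort is
attenuated and heterogeneous as described. Passing tests therefore show
that the *pipeline machinery* recovers planted truth under a fair model of
cohort structure — not that any particular clinical performance figure
would be attained on real plasma.

# Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
study-shaped sizes (40 tissue pairs; 333 plasma samples split
160/69/104; 200 markers with 26 informative) with 100 LASSO repetitions —
the repetition count is the one knob reduced from the 500 used in
full-scale runs, keeping the selection threshold at the same 60% frequency;
selection frequencies at 100 repetitions carry a binomial SE of about 5
percentage points, so panel recovery fluctuates a few markers around its
expectation from seed to seed. Forests use 500 trees and single-threaded
prediction so that results are bit-reproducible under a fixed seed.

# Known limitations

* The moderated-t prior estimation assumes a common residual df across
  markers (true for complete matched pairs, not for ragged missingness).
* The dynamic-range filter uses the raw max − min, which is sensitive to a
  single outlying sample; a quantile range would be more robust but less
  transparent.
* Univariate logistic AUROC equals oriented rank AUROC only while the
  single covariate enters monotonically — true for one-covariate logistic
  models, asserted in the tests, but not a property that survives adding
  covariates.
* The AUROC-difference bootstrap treats the two score vectors as fixed
  functions of the resampled samples; it does not account for variability
  in model training.
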