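---
title: "methylBench: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylBench: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylBench)
```

methylBench evaluates how quantification scale (β versus M), feature
selection strategy (WF, VF, SPCA), ranking statistic (ordinary,
regression or moderated *t*) and prediction algorithm behave on
Infinium-style DNA methylation matrices. This vignette documents the
models the package implements, every tunable parameter that matters, and
the reasoning behind choices that were genuinely open.

## Quantification

For each CpG the array reports a methylated (`methy`) and an
unmethylated (`unmethy`) probe intensity, measured in the same colour
channel and possibly negative after background subtraction. The two
measures are

$$\beta = \frac{\max(methy,0)}{\max(methy,0)+\max(unmethy,0)+100},
\qquad
M = \log_2\frac{\max(methy,0)+1}{\max(unmethy,0)+1}.$$

The offsets (100 fluorescence units; 1 unit) are fixed constants of the
definitions, not parameters. Because typical loci have combined
intensity above 1,000, the two measures are related approximately by the
logistic map $\beta = 2^M/(2^M+1)$, implemented exactly by
`beta_to_m()` / `m_to_beta()`. The approximation is good for mid-range
loci and degrades at the extremes, where one probe's intensity stays
small no matter how bright the locus: the package's tests assert the
shrinking discrepancy over loci with $\beta \in [0.1, 0.9]$ only.
`beta_to_m()` refuses boundary values 0/1 unless the caller opts into a
clamp — silent clamping would hide data problems.

## The synthetic-data generator

`simulate_beta_matrix()` emits a CpG × sample β matrix, a phenotype and
the ground-truth CpG set. The model, per CpG $j$ and sample $i$:

1. **Baseline.** A logit-scale baseline $b_j$ drawn from a tri-modal
   mixture: 45% unmethylated (mean −3), 10% hemi-methylated (0), 45%
   methylated (+3), SD 0.5 — the standard tri-modal Infinium landscape.
2. **Effect.** For the `n_true` associated CpGs, the logit mean shifts by
   $s_j\,\delta_j\,e_i$, where $s_j = \pm 1$ is a random direction,
   $e_i$ is the per-sample value of the phenotype-linked factor, and
   $\delta_j$ is a per-CpG shift size set by calibration (below). For a
   binary phenotype $e_i = y_i - \tfrac12$; for a continuous one,
   $e_i$ is the standardized phenotype. With `shared_factor_sd`
   $= \tau > 0$, Gaussian noise of SD $\tau$ is added to $e_i$: all
   truth CpGs then respond to one noisy latent factor, making them
   mutually correlated beyond their phenotype association and capping
   the attainable effect size. This emulates regimes where associations
   are mediated by a variable biological process — blood cell-type
   composition in case/control blood studies, or "biological age" in
   age studies — and is switched off by default.
3. **Noise.** The realized logit mean receives biological logit-normal
   noise (SD `bio_sd`, default 0.35), is squashed through the inverse
   logit, and the emitted value is drawn from a beta distribution with
   that mean and concentration `precision` (default 200, the technical
   sampling layer), finally clamped to $(10^{-6}, 1-10^{-6})$.

The two-layer noise model is the load-bearing choice. A single
beta-distribution layer would make the log-variance spread identical on
the β and M scales (merely inverted between the extremes and the
middle), so neither measure would be statistically preferable and the
small-sample comparison below would have no mechanism. With a dominant
logit-normal layer, the β scale shows the severe heteroscedasticity of
real arrays (SD maximal near 0.5, collapsing at the extremes — roughly
$(\mu(1-\mu))\,\sigma_{bio}$) while the M scale is close to
homoscedastic, which is exactly the structure reported for real Infinium
cohorts. The beta sampling layer keeps values strictly inside $(0,1)$
and adds the mean-dependent technical variance
$\mu(1-\mu)/(1+\phi)$.

**Effect-size calibration.** `target_effect_size` is the Cohen's-d-like
ratio the package measures on the β scale: difference in class means
over the pooled SD (binary), or the standardized slope — β change per
phenotype SD over the residual SD (continuous). For every truth CpG the
shift $\delta_j$ is found by bisection (50 iterations, 1% tolerance) so
that the CpG's *expected* effect, computed deterministically by
quadrature over the noise layers, equals the target. Calibrating each
CpG individually — rather than one global logit shift — decouples
detectability from baseline variance: a truth CpG sitting near the
methylated extreme (tiny β-scale variance) carries the same effect size
as a hemi-methylated one. This matters for the variance-filtering
comparison, whose scientific content is precisely that low-variance CpGs
can carry real effects. A target that cannot be reached inside $(0,1)$
at the configured precision/heterogeneity raises an error naming the
offending baseline class. `effect_size_spread` (log-normal SD, deviate
truncated at ±2; default 0) optionally spreads per-CpG targets around
the median to emulate the effect-size heterogeneity of real studies.

`simulate_intensities()` wraps the same model in a lognormal
total-intensity layer (median 10,000 units by default, so ~99% of loci
exceed the 1,000-unit level of real arrays) with additive Gaussian probe
noise; negative intensities are left in place for the quantification
clamp to handle.

**What the generator does not model** — and hence what passing tests do
not establish about real data: batch/beadchip effects, detection
failures, probe-design classes, and co-methylation networks beyond the
single phenotype-linked factor. The last limitation is visible in the
results: with CpGs conditionally independent given the factor, ranking
by the per-CpG training statistic is already near-optimal, so SPCA
feature selection — whose real-data advantage exploits reproducible
correlation structure among CpGs — beats variance filtering here but
does not overtake unfiltered ranking (the acceptance suite records this
as a failing expectation rather than hiding it).

## Association statistics

`t_test_by_feature()` uses the pooled-variance two-sample *t* (Welch
available but off by default) because the moderated *t* is built on
pooled variances and reduces to it exactly at $d_0 = 0$.
`linear_assoc()` is the per-CpG simple regression slope *t* on $n-2$
degrees of freedom. Zero-variance CpGs get `NA` statistics, are excluded
from ranking, q-value estimation and prior fitting.

`fit_variance_prior()` fits the scaled inverse-χ² prior
$(d_0, s_0^2)$ by matching the mean and variance of $\log s^2$ to their
digamma/trigamma expressions; the trigamma inverse is a monotone Newton
iteration (`trigamma_inverse()`, accurate to ~1e−8). When the observed
spread of log-variances is no larger than sampling alone implies, the
prior degrees of freedom are infinite; the degenerate all-equal case
returns the common variance itself. The fit agrees with limma's moment
estimator to 1e−6 (asserted in the tests with limma as an independent
oracle — limma is never used as the implementation).

`moderated_t()` shrinks each pooled variance to
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$ and refers
$\tilde t$ to $d_0 + d_g$ degrees of freedom, capped at $10^6$ when
$d_0 = \infty$. This is the ranking statistic for the 2–3-samples-per-
class regime, where ordinary *t* statistics are unusable.

`qvalues()` uses the fixed-λ estimator
$\hat\pi_0 = \#\{p > 0.5\}/(m/2)$, bounded into $(0,1]$ — deterministic
and robust at small $m$; the spline-smoothing variant is deliberately
not implemented. With $\pi_0 = 1$ the q-values equal Benjamini–Hochberg
adjusted p-values exactly (asserted against `p.adjust`).

## Feature selection

All three methods return a deterministic ranking; ties are broken by
larger absolute statistic, then lexicographic CpG ID.

* **WF** ranks every CpG by p-value and keeps the top `k` (default
  1,500).
* **VF** first keeps the 5,000 most variable CpGs (variance computed on
  the training matrix, phenotype-blind), then ranks those and keeps
  $\min(k, \#\{p<0.05\})$.
* **SPCA** keeps the 5,000 most significant CpGs, takes the SVD of that
  feature-centered submatrix, picks the component whose score vector has
  maximal $|r|$ with the phenotype (components up to
  $\min(n-1, 30)$), and ranks by absolute loading. A CpG's direction is
  $\mathrm{sign}(u_j \cdot r)$, which absorbs the arbitrary sign of the
  singular vectors.

Whether the SPCA submatrix should be centered or standardized was open;
centering only (no variance scaling) is used, the standard PCA
convention. Row-standardization was evaluated and rejected: it removes
the variance confound in the loadings but makes component selection
fragile — after a supervised pre-filter the chance-selected null CpGs
form an artifact component whose training correlation with the phenotype
can exceed the real factor's, and standardization amplifies it.

## PPV evaluation

`make_partitions()` draws 50 independent 50/50 splits, stratified per
class (binary) or per phenotype-quartile bin (continuous); training and
test halves are always equal-sized so p-values are comparable, and an
odd stratum drops one randomly chosen sample per partition. The
true-positive rule: a training-selected CpG validates when its test-half
statistic has $p<0.05$ *and* the same sign. Under the null this happens
with probability $0.05 \times \tfrac12 = 0.025$ — the package's
null-calibration check. `ppv_curve()` records PPV for evaluation sizes
50, 100, …, 1500 (sizes beyond a truncated VF list are scored on the
full list and flagged). `small_sample_ppv()` subsamples disjoint
2–3-per-class train/test sets and forces the moderated *t*.
`compare_ppv()` is the unpaired two-sided Wilcoxon rank-sum test by
default (the partitions are shared by design but treated as independent
samples; a paired signed-rank option exists because the pairing is
real). `choose_evaluation_sizes()` scans candidate PPV levels and picks
per-study sizes minimizing between-study PPV variance, ties toward
smaller sizes.

## Classification

All predictors train on one partition half and score the other; the
C-index (concordant pairs + half the prediction ties, over comparable
pairs) evaluates continuous-phenotype predictions and is invariant to
monotone transforms.

* **SPCA-1/2/3**: univariate regression statistics rank the CpGs; a
  7-point log-spaced grid of feature counts between 10 and 5,000 is
  scored by internal 10-fold CV (ranking, SVD and regression refit
  inside each fold; pooled out-of-fold predictions scored by C-index);
  the final model regresses the phenotype on the first 1–3 component
  scores. The SVD per threshold and fold is shared across the three
  component counts.
* **LASSO / ELNET**: `glmnet` behind the module surface, α = 1 and
  α = 0.05 respectively, standardized features, λ chosen by internal
  10-fold CV (minimum mean squared error) over a 100-point path down to
  $10^{-3}\lambda_{max}$; folds are phenotype-stratified and seeded. By
  default the 5,000 most variable training CpGs enter the fit (matching
  the computational scale of the other methods; `n_filter = NULL`
  disables).
* **SVM**: ε-SVR with radial kernel, fixed γ = 3, ε = 0.1, C = 1
  (C is the conventional default; only γ and ε are prescribed).
  Features and the outcome are standardized internally, and γ is
  interpreted per standardized feature — the kernel is
  $\exp(-\gamma\|x-z\|^2/p)$. This is the only dimension-independent
  reading of a fixed bandwidth: on the raw summed distance,
  $\gamma = 3$ over thousands of standardized CpGs gives kernel entries
  $\exp(-{\sim}6p) \approx 0$, an identity kernel matrix, and a constant
  predictor. ε is a tube width on the unit-variance outcome scale.

## Unsupervised modelling

`estimate_n_components()` compares the singular values of the
feature-centered matrix with those of matrices whose entries are
permuted *within each CpG row*. Row-wise permutation destroys all
between-sample structure while preserving each CpG's marginal
distribution; permuting all entries jointly would homogenize the
severely heteroscedastic row variances and was found to misstate the
null in both directions (inflating the estimate on pure noise,
deflating it on structured data). Defaults — 50 permutations, 0.95
exceedance quantile — are package choices; the estimate is the leading
run of observed values above the matched-rank permutation quantile.

`nndsvd_init()` is the textbook non-negative double SVD: leading triplet
used directly, later components keep the dominant nonnegative section of
each singular-vector pair, zeros left as zeros — fully deterministic, so
NMF from this start reproduces bit-for-bit. `nmf_brunet()` runs the
classical multiplicative updates for the generalized Kullback–Leibler
divergence, stopping at relative objective change $<10^{-6}$ or 2,000
iterations, with the trace recorded (non-increase is asserted on random
fixtures). One numerical adjustment: the exact zeros of the
initialization are floored at $10^{-3}\,\overline{V}$ before iterating,
because multiplicative updates can never move mass into an entry that
starts at zero (zero locking), which stalls the factorization far from
planted optima; the floor is deterministic and preserves the NNDSVD
structure.

`compare_svd_nmf()` runs both decompositions at the shared permutation-
estimated rank (raised to 2 when the estimate is smaller, since the
summary — the average R² of the two best components against the
phenotype — needs two components; a rank-1 nonnegative factorization of
a centered contrast merely tracks overall intensity). R² is the squared
Pearson correlation between component scores and phenotype, identical
whichever variable is the regressor. NMF runs on β values only — its
justification is the positivity of the β scale — and M-valued input is
rejected. On diagnostic-style data with one strong group contrast, NMF's
two components align with the two class centroids so both correlate with
the phenotype, while orthogonality forces SVD's second component into
noise: the average-of-best-two favours NMF, as the acceptance suite
verifies.

## Problem sizes and numerical conventions

The checked scenarios use 2,000–25,000 CpGs, 2–150 samples per group, 50
partitions, effect sizes 0.6–2.5 and signal strengths 0–4,000 — spanning
the regimes of interest at workstation scale. Other conventions:
p-values are floored at the smallest positive double (so exact fits
remain rankable); statistics with zero variance are `NA` and excluded
everywhere; every stochastic routine takes an explicit seed and restores
the caller's RNG state; all rankings and both matrix factorizations are
bit-reproducible given the inputs.

## Known limitations

* The generator's CpGs are conditionally independent given one latent
  factor; co-methylation blocks, batch structure and probe-design
  effects are out of scope, and conclusions about SPCA's real-data
  advantage must respect that (see above).
* The β/M comparison inherits the generator's premise that biological
  variation is logit-normal; a different real-data noise shape would
  shift the small-sample contrast quantitatively.
* `choose_evaluation_sizes()` does a discrete grid scan; with many
  studies and very fine grids an exact joint optimum could differ from
  the scanned one on ties.
* The SVM bandwidth interpretation is an assumption (documented above);
  results at a literal summed-distance γ = 3 would be degenerate.
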