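---
title: "Models and measures of motion complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measures of motion complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(motioncomplexity)
```

# The problem

A subject repeatedly draws a self-chosen closed pattern with their hand —
N = 10 repetitions of the same shape inside a 10 × 10 cm workspace — and we
want a number that says how *complex* that motion pattern is. The package
treats the repetitions of one trial as draws from an underlying trajectory
distribution, estimates that distribution in two different probabilistic
frameworks, and reads complexity off as the differential entropy of the
estimated distribution. Two symbol-sequence measures and a plain variance
control complete a set of five scores per pattern, which can then be
correlated with human creativity judgments (or simulated ones).

All trajectories are resampled to `T = 150` points, equidistant in recorded
time (not arc length), each repetition over its own duration; repetitions
are then compared index by index, with no time warping. Coordinates are in
cm, x rightward, y upward, origin at the workspace's lower-left corner.

# Gaussian-process complexity

Each movement dimension is modelled as a zero-mean Gaussian process over the
time index with a squared-exponential covariance
$k(t, t') = \sigma_f^2 \exp(-|t - t'|^2 / \lambda^2)$ plus i.i.d.
observation noise $\sigma_n^2$. The log marginal likelihood of the data
splits into a goodness-of-fit term and a data-independent model-complexity
term; the latter is, up to an additive constant, the differential entropy of
the model's trajectory distribution. A wiggly pattern forces a short length
scale $\lambda$ and hence a high-entropy prior; a smooth ellipse is
explained by a long length scale with low entropy.

Identifiability choices (`fit_gp()`):

* Each dimension's concatenated observations are standardized — centred and
  scaled to unit variance. Centring matters because the prior mean is fixed
  at zero while raw coordinates live around the workspace centre.
* The unit data variance is partitioned between signal and noise,
  $\sigma_f^2 = 1 - \sigma_n^2$. This keeps both of the model's competing
  explanations available: "rough signal, no noise" and "smooth (or no)
  signal, high noise". The second is exactly how the model accounts for
  erratic scribbles, and it is what pushes their complexity *down*.
* $(\lambda, \sigma_n^2)$ are fitted by maximum marginal likelihood: a grid
  of 30 log-spaced $\lambda$ values in [0.5, 500] time indices by 10
  log-spaced $\sigma_n^2$ values approaching 1, followed by Nelder–Mead
  refinement in log space. Grid ties break toward the smallest $\lambda$,
  and a fit on the $\lambda$ grid boundary is flagged with a warning.
* The N repetitions are treated by default as independent realizations
  sharing hyperparameters (a block-diagonal covariance, so only T × T
  solves are needed and the result is invariant to repetition order);
  `concat = "continuous"` instead strings them onto one continuous index
  `1..N*T`, the more literal reading of concatenation.

The reported score is
$\tfrac12 \log\det\!\big(2\pi e\, (\hat\sigma_f^2 K_{\hat\lambda} +
\sigma^2_{\mathrm{ref}} I)\big)$
summed over blocks and dimensions, with a *fixed* reference noise floor
$\sigma^2_{\mathrm{ref}} = 10^{-2}$ common to all patterns. The per-pattern
fitted noise is deliberately excluded from the determinant: the score is
then determined entirely by the fitted length scale and signal variance and
is comparable across patterns, and a pattern explained away as noise
($\hat\sigma_f^2 \to 0$) scores at the floor rather than at the white-noise
ceiling. The floor is a reporting constant, not a model parameter: it only
shifts all scores by the same amount wherever the signal dominates.
Numerically, all determinants and quadratic forms go through Cholesky
factorizations with diagonal jitter escalated over $\{0, 10^{-10}, 10^{-8},
10^{-6}\}$ relative to the mean diagonal.

# Probabilistic movement primitives

A trajectory is compressed into a weight vector $\omega \in \mathbb{R}^{2n}$
over `n = 20` normalized Gaussian bases per dimension
(`pmp_basis()`), evaluated on a linear phase $z \in [0, 1]$. Centres are
equally spaced on [0, 1] and the width is $h = 1/(n-1)$, giving adjacent
bases an overlap of about $e^{-1/2}$; both are configurable. Weights are
fitted per repetition by ridge least squares (penalty $10^{-8}$, guarding
rank deficiency only).

The weight vectors of a pattern's repetitions are modelled as draws from a
Gaussian $N(\mu_\omega, \Sigma_\omega)$ with a Normal-inverse-Wishart prior
($\kappa_0 = 0.1$, $\nu_0 = 10$). The conjugate posterior update and the MAP
estimate $\{\mu_\omega = \mu,\ \Sigma_\omega = \Psi/\nu\}$ are implemented
in `niw_posterior()` and `map_estimate()`. Two remarks:

* With $2n = 40$ weight dimensions, $\nu_0 = 10$ sits below the usual
  inverse-Wishart properness bound $\nu > d - 1$. The MAP covariance is
  nevertheless well defined and positive definite as long as the prior
  scale matrix is, so the package only requires $\nu > 0$.
* The empirical-Bayes prior (`pmp_prior()`) sets $\mu_0$ to the grand mean
  of all fitted weights in the collection and $\Psi_0 = \nu_0$ times the
  pooled *within-pattern* covariance (each pattern centred on its own mean
  before pooling, plus a relative $10^{-6}$ diagonal regularizer). The
  inverse-Wishart part of the prior governs the within-pattern covariance,
  so pooling within-pattern scatter is the matching moment; between-pattern
  mean spread is information about $\mu_0$, not $\Psi_0$. Pooling the grand
  covariance instead would bury each pattern's covariance signal under
  between-pattern spread and compress all entropies toward a common value.

The complexity score is the differential entropy of the predictive
trajectory distribution
$N(\Psi \mu_\omega,\ \Psi \Sigma_\omega \Psi^\top + \Sigma_\tau)$ with
$\Sigma_\tau = 10^{-10} I$ (negligible trajectory noise). The
$2T \times 2T$ determinant is evaluated with the matrix determinant lemma,
so only a $2n \times 2n$ factorization is formed; the lemma route matches a
dense log-determinant to $10^{-8}$ at noise floors where dense LU is itself
numerically trustworthy.

Why the two entropies disagree about pure randomness: the GP can explain an
erratic scribble as a smooth trajectory plus high observation noise, so its
complexity collapses; the primitive has no such escape — representing
mutually unrelated repetitions requires a broad distribution in feature
space, so its entropy is maximal there. For repeatable patterns the two
scores agree in ordering.

Both probabilistic scores are reported as entropies proper,
$\tfrac12 \log\det(2\pi e \Sigma)$, which differ from the raw
model-complexity terms of the marginal likelihoods only by additive
constants at fixed T — rank correlations are unaffected.

# Symbolic measures

`symbolize()` tessellates the workspace into 1 × 1 cm cells (half-open
cells; the top/right boundary belongs to the last cell) and writes one
letter from {l, r, u, d} per cell-boundary crossing. Segments crossing
several boundaries are subdivided at the exact line–grid intersections and
crossings are emitted in traversal order, an exact corner hit emitting the
x-crossing first — a deterministic convention, chosen because no standard
one exists. Same-cell samples emit nothing.

Ten repetitions are far too few transitions for stable sequence statistics,
so `build_corpus()` samples trajectories from the *fitted primitive* (clipped
to the workspace) and concatenates their symbol sequences until at least
10,000 transitions are available. On such corpora:

* `lz76_count()` implements the 1976 exhaustive-history parsing (the final
  block counts whether or not it is novel), and `lz76_normalized()` scales
  it by $\log_k(n)/n$ — a conventional normalization approaching 1 for long
  i.i.d. equiprobable sequences; both raw and normalized values are exposed.
* `emc()` estimates the effective measure complexity
  $\mathrm{EMC} = \sum_{L \ge 0} (h_L - h)$ from plug-in block entropies
  (base 2, overlapping blocks), with $h_L = H(L+1) - H(L)$, the entropy
  rate taken as the last reliable $h_L$, and history lengths considered
  reliable while the number of distinct observed blocks stays below
  $\sqrt{n}$ (an undersampling guard; profile entries are flagged). These
  estimator details are conventional choices — the measure's definition
  fixes neither $L_{\max}$ nor the guard.

# The synthetic generator

`generate_pattern()` emulates four qualitative classes of drawing behaviour
with controllable spatial complexity and repetition variability:
ellipses with small (0.08 cm) or large (0.6 cm) variability, a rich closed
harmonic curve (8 random Fourier components, no amplitude decay) drawn very
repeatably (0.12 cm — intricate shapes are slightly harder to repeat), and
patternless repetitions (independent heavily low-pass-filtered walks plus
1 cm white jitter). A `graded` class interpolates from a pure ellipse by
scaling harmonic amplitudes, for dose–response experiments. All curves are
affinely scaled into the workspace and clamped to it.

Repetition variability mimics imperfect *memory*, not sensor noise: each
repetition re-draws the base curve at smoothly jittered phase (timing
error) and adds a smooth drift field, both low-pass filtered with a
correlation length of a quarter repetition, and each calibrated to
contribute $\sigma_{\mathrm{rep}}/\sqrt2$ cm of positional spread. The
timing component is essential to the complexity–variability dissociation:
on a high-frequency curve a small timing error produces a large excursion
in feature space while the positional variance stays small, which is
exactly why a repeatable complex pattern carries a broader weight
distribution than a sloppy ellipse. A purely additive spatial field cannot
produce that dissociation — it projects into feature space identically for
every base shape.

These generator constants were chosen once so that the four classes
separate visually and statistically, and are all overridable. What passing
the ordering tests shows is that the five measures behave as designed on
data *generated under these mechanisms*; human drawings differ in ways the
generator does not emulate (velocity profiles, workspace anchoring,
drift over a session), so ordering results on synthetic classes are a
validation of the measures' logic, not of any empirical claim about
subjects.

`simulate_jury()` ranks the patterns compared within a trial by a true
score plus juror noise, ranks 1..m with m = most creative and deterministic
tie-breaking toward the lower subject index.

# The correlation stage

`spearman_cor()` rank-transforms with midranks and reports the Pearson
correlation of ranks, with a t-approximation p-value by default and a
seeded permutation option for small samples. Per-subject analyses report
uncorrected significance bands (p < 0.001 / 0.01 / 0.05 / ns), matching the
convention of reporting each subject separately.

One subtlety is documented rather than hidden: jury ranks are
*trial-relative*. A pooled Spearman correlation between average ranks and a
raw measure therefore cannot reach exactly 1 even for a noiseless jury that
ranks by the measure itself — tied ranks face untied measure values, and
cross-trial measure levels carry no rank information. The exact identity
holds on the within-trial rank representation of the measure, which is what
`rank_rank_analysis()` computes and what the identity tests assert. At the
study's dimensions (10 subjects × 55 trials) the attenuation of the raw
pooled correlation is a factor of about $\sqrt{1 - 1/100} \approx 0.995$.

# Problem sizes and costs

Defaults follow the study conditions: T = 150, N = 10, n = 20 bases per
dimension, 10 × 10 cm workspace with 1 cm cells, corpora of at least 10,000
transitions, $\kappa_0 = 0.1$, $\nu_0 = 10$, $\Sigma_\tau = 10^{-10} I$.
The packaged validation suite scores 20 patterns per synthetic class with
all five measures, runs 50-fold length-scale recovery at T = 150, a
550-pattern null-jury calibration, and prior-robustness over ±1 order of
magnitude in $(\kappa_0, \nu_0)$ — sizes at which the whole suite completes
in a few minutes on a single core. The LZ-76 and rasterization inner loops
are compiled (Rcpp); everything else is plain R and LAPACK.

# Known limitations

* Repetition alignment is index-by-index after per-repetition resampling;
  systematic speed differences between repetitions leak into all variance-
  and covariance-based measures. Dynamic time warping is out of scope.
* Plug-in entropies are biased downward at long block lengths; the
  undersampling guard truncates rather than corrects (no Miller–Madow or
  NSB correction).
* The GP uses a stationary kernel; strongly non-stationary drawings (e.g. a
  dense region plus a long excursion) are averaged over.
* 3-D trajectories, forces, and velocity channels are not modelled.

```{r example, eval = FALSE}
# a minimal end-to-end run
classes <- c("random_high_var", "complex_low_var",
             "ellipse_high_var", "ellipse_low_var")
pats <- unlist(lapply(classes, function(cl) {
  lapply(1:5, function(i) generate_pattern(cl, seed = i, subject = cl, trial = i))
}), recursive = FALSE)
scores <- score_patterns(pats, seed = 1)
aggregate(cbind(gp, pmp, lzc, emc, var) ~ subject, scores, median)
```
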