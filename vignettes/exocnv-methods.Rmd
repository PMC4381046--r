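---
title: "Normalization and CNV calling for whole-exome read depth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization and CNV calling for whole-exome read depth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
null model and its fitting algorithm, how the latent dimension is chosen,
the segmentation and genotyping procedure, what the simulator does and does
not emulate, and the numerical decisions taken where the design was open.

## The problem

Whole-exome sequencing (WES) coverage is shaped far more by the capture and
amplification chemistry than by the underlying copy number: exon-to-exon
depth varies by orders of magnitude, GC-dependent amplification differs
between libraries, and batch-level artifacts correlate samples. A CNV
changes depth by a factor of 1/2 (heterozygous deletion) or 3/2 (one extra
copy) — far less than the technical variation. CNV detection from WES is
therefore first and foremost a normalization problem: estimate what
coverage *would* look like without CNVs ("control coverage"), then test the
observed counts against it.

## The null model

For exon $i = 1..n$ and sample $j = 1..m$ with read count $Y_{ij}$:

$$Y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
\lambda_{ij} = N_j \, f_j(GC_i)\, \beta_i \exp\Big(\sum_{k=1}^{K} g_{ik} h_{jk}\Big)$$

* $N_j$ — total mapped reads of sample $j$ (genome-wide, not the on-target
  sum); fixes the library-size scale.
* $f_j(\cdot)$ — a per-sample smooth GC-bias curve. It is non-parametric
  (cubic smoothing spline) because GC curves differ between samples in
  shape, not just scale — some are unimodal, some bimodal — so no common
  parametric form or linear factor can absorb them.
* $\beta_i$ — exon-specific bias from length and capture/amplification
  efficiency. These causes are intentionally confounded in a single free
  parameter per exon; nothing downstream needs them separated.
* $g_{ik} h_{jk}$ — latent Poisson factors, the log-bilinear term absorbing
  systemic artifacts (batch, center, capture-kit structure) that are not
  directly measurable.

A Poisson log-linear model is used rather than an SVD on (log) coverage
because counts at the low-coverage exons carry their own variance scale;
Gaussian-noise factor models mis-weight exactly the exons where CNV
evidence is weakest.

## Fitting algorithm

Blockwise maximum likelihood with the following outer iteration
(initialized at $\beta = 1$, $g = h = 0$):

1. **GC splines.** For each sample, fit a cubic smoothing spline of
   $Y_{ij} / (N_j \beta_i e^{(gh^\top)_{ij}})$ against $GC_i$ and floor the
   prediction at a small positive value.
2. **Exon bias.** $\beta_i \leftarrow$ median over samples of
   $Y_{ij} / (N_j f_j(GC_i) e^{(gh^\top)_{ij}})$. The median is the point
   of the design: a minority of CNV carriers at an exon does not drag the
   exon's null estimate.
3. **Latent block.** With $Z = N f(GC)\beta$ fixed, alternate (a) $n$
   exon-wise Poisson log-linear regressions of $Y_{i\cdot}$ on $h$ with
   offset $\log Z_{i\cdot}$ to update $g$; (b) the $m$ symmetric sample-wise
   regressions to update $h$; (c) SVD of the row-centered $g h^\top$,
   keeping the $K$ right singular vectors as the new (orthonormal) $h$.
   The SVD step enforces identifiability (orthonormal $h$, exon-centered
   latent term).

Until the total Poisson log-likelihood changes by less than `outer_tol`
(default $10^{-6}$, cap 20 outer iterations; the latent alternation runs to
a $10^{-4}$ relative change in $gh^\top$ or 10 iterations).

Numerical choices worth recording:

* **The regressions are batched.** All $n$ exon-wise regressions share the
  covariate matrix $h$, so they are solved by one damped-Newton sweep in
  compiled code (linear predictors clamped to $\pm 30$, steps to max-norm
  4, non-convergent rows fall back to zero coefficients with a warning).
  `glm(y ~ 0 + h, family = poisson, offset = log z)` solves the identical
  score equations and serves as the cross-check in the test suite.
* **The centering step is lossless.** Row-centering $g h^\top$ removes the
  exon-level mean $g\,\overline{h}$; that component is pushed into
  $\log\beta$ rather than discarded, so the reparameterization leaves every
  $\lambda_{ij}$ — and hence the likelihood — unchanged, and the truncated
  SVD of the centered rank-$K$ matrix is exact.
* **Spline weights and a frozen smoothing parameter.** The spline is
  weighted by the model denominator, making the least-squares smoothing the
  quadratic approximation of the penalized Poisson fit; its smoothing
  parameter is selected by GCV per sample at the first outer iteration and
  then frozen, so the curve's flexibility does not drift as the latent term
  absorbs structure.
* **Backtracked bias updates.** The spline and median steps are robust
  approximations of conditional maximum-likelihood updates, not exact
  ascent steps. After the first iteration their joint proposal is taken
  with backtracking on the log scale — the step is halved until the move
  does not lower the likelihood, and skipped entirely if no step length
  helps — which leaves the fixed point unchanged (at convergence the
  proposals equal the current values). Since the latent block is exact
  conditional ascent, the outer-loop log-likelihood is non-decreasing by
  construction (asserted to $10^{-6}$ relative slack in the tests).
* **Zeros.** $\log(Y/Z)$ for the SVD initialization uses $Y + 0.5$ at
  zeros; ratios are floored at $10^{-6}$ of their positive median wherever
  divisions by model terms occur.
* **Determinism.** SVD signs are fixed by making the largest-magnitude
  entry of each singular vector positive, so fits are bitwise reproducible
  and invariant to sample order.

### Choosing K

$K$ is the critical tuning parameter: too large and common CNV signal is
absorbed into the normalization (unrecoverable), too small and residual
artifacts inflate the false-positive rate. The package reports, per
candidate $K$: $AIC = 2\ln L - 2k$, $BIC = 2\ln L - k \ln(nm)$ (both
maximized) and the percentage of the $K{=}0$ model's Poisson deviance
explained. The parameter count is $k = K(n + m)$ — exactly the parameters
added per unit of latent dimension — and the sample size in the BIC is the
number of observed counts $nm$; the criteria are used to *rank* $K$, so
only the per-$K$ increments matter. BIC is the default (ties broken toward
smaller $K$): normalization should err conservative because
post-segmentation false positives can still be screened, but signal removed
here is gone. Because BIC penalizes each $K$ more strongly, the AIC choice
is never below the BIC choice.

### Case–control mode

For cohorts with recurrent large aberrations (tumors), a pooled fit would
absorb shared aberrations into the exon-side parameters. `fit_case_control()`
fits the full model on the control cohort only, freezes the exon-side
quantities ($\beta$ and the loadings $g$), and gives each case sample its
sample-side terms — its GC curve $f_j$ and factor coefficients $h_{j\cdot}$
— by per-sample spline and regression steps. A `frozen = "latent"` variant
freezes only $g$ and re-estimates $\beta$ from the case medians, for
cohorts where capture efficiency differs but case CNVs are rare. The
default freezes the exon side because that is the side a new sample cannot
supply: sample-side terms must be estimated per sample either way.

## Segmentation and genotyping

With control coverage $\hat\lambda$ in hand, each sample is segmented per
chromosome. For a window of exons $s..t$ with sums $y_{s:t}$ and
$\lambda_{s:t}$, the generalized log-likelihood ratio of a free Poisson
mean against the null is

$$U(s,t) = y_{s:t}\log(y_{s:t}/\lambda_{s:t}) - (y_{s:t}-\lambda_{s:t}),$$

with $U = \lambda_{s:t}$ at $y_{s:t}=0$. The circular-binary-segmentation
recursion repeatedly splits the current segment, producing a nested
sequence of models with $P = 0, 1, 2, \dots$ change points, scored by the
modified BIC

$$\mathrm{mBIC}(P) = \log\frac{L_\tau}{L_0}
 - \tfrac12 \sum_{\rho=0}^{P}\log(\hat\tau_{\rho+1}-\hat\tau_\rho)
 + (\tfrac12 - P)\log n,$$

with boundary convention $1 = \tau_0 < \tau_1 < \dots < \tau_{P+1} = n$ and
$\log(L_\tau/L_0)$ equal to the sum of per-segment $U$ values (each segment
at its Poisson MLE, the segment count sum). The model maximizing mBIC over
the nested sequence is returned. Design details:

* **The greedy step is steered by the penalized gain.** At each split the
  window chosen is the one whose excision most increases the mBIC — the
  likelihood gain of the split plus the (separable) change in the spacing
  and change-point-count penalties — not the window with the largest bare
  $U$. The bare statistic is maximized by the whole segment itself whenever
  the segment is uniformly shifted (proposing no split at all), and always
  prefers two change points where one suffices; the penalized gain fixes
  both, and on small instances the recursion then reproduces the exhaustive
  mBIC optimum exactly (property-tested against full enumeration).
* **Boundary convention.** With $\tau_0 = 1$, a change point at position 1
  has zero spacing and mBIC $-\infty$; the formula is followed as printed,
  so such models are simply unselectable (and the search never proposes
  them).
* **Ties** in the split choice break toward the smallest start, then the
  shortest window; minimum segment length is one exon.
* **Genotyping.** A segment's copy number is $2 y_{s:t}/\lambda_{s:t}$
  ("fraction" mode, appropriate for heterogeneous genetic composition) or
  that value rounded to a non-negative integer ("integer" mode, germline).
  Fraction-mode calls use thresholds 1.7/2.3 by default — midway guard
  bands around copy 2 common in read-depth practice — and the spike-in
  machinery tunes the margin to a specificity target instead when truth is
  available. Very short (1–2 exon) events are better served by direct
  thresholding of $\log(Y/\hat\lambda)$ (`ratio_calls()`), for which the
  evaluation module provides a threshold sweep (ROC).

## The simulator and what it shows

`simulate_null()` draws cohorts from the null model itself: GC uniform on
[0.2, 0.8] (the post-QC range), log-normal exon biases (log-sd 0.5, the
spread after QC removes capture failures), per-sample unimodal GC curves
with a bimodal minority (20%), mean target depth 80–120x (a modern exome
cohort), totals $N_j$ of 20–40M reads, and orthonormal latent factors
scaled so the latent log-rate term has sd 0.2 — artifacts comparable to,
but not dominating, a heterozygous-deletion signal of $\log 2 \approx 0.7$.
`spike_in()` implants events following the benchmark protocol: events
centered every 100th exon (stride configurable), $m \times p$ carriers
drawn at random, carrier depth multiplied by $c/2$ for het deletions
($3c/2$ for one-extra-copy duplications; counts rounded, $c \sim
N(1, 0.1)$ truncated at 0).

Evaluation is exon-by-sample against the population average: an event
spiked at frequency $p > 1/2$ *becomes* the cohort norm, so its carriers
are expected to look neutral and the non-carriers to carry the mirrored
state; carrier cells of such events are excluded from the specificity
denominator as ambiguous. This mirrors how any reference-free method must
behave and is what produces the characteristic power curve: sensitivity
dips near $p = 0.5$, where the signal is evenly split between the cohort
and its complement and partly absorbed by the sample-wise latent factors,
and recovers towards both ends. Duplication runs at $1-p$ are constructed
as true mirrors (complement carrier sets on the same base cohort), which is
how the deletion/duplication duality is property-tested.

Specificity "control" is implemented as a sweep: the symmetric fraction-mode
margin $\delta$ (call deletion below $2-\delta$, duplication above
$2+\delta$) is swept, and the loosest margin attaining the target
(specificity $\ge 0.99$) is selected; the sweep doubles as an ROC curve.

What the simulator does **not** emulate: real capture-kit exon spacing and
chromosome structure (targets are uniform 150 bp exons on one synthetic
chromosome), mappability artifacts, allelic (BAF) information, read-level
errors, GC effects at the fragment level, or inter-cohort batch mixtures.
Passing the benchmark therefore demonstrates the statistical machinery —
normalization that does not absorb minority signal, segmentation that
recovers change points, calibrated specificity control — under the model's
own noise structure, not performance on any particular real capture
platform.

## Problem sizes used in the checks

The packaged benchmarks run at desk scale, chosen to exercise the claims
while keeping the full suite in minutes: parameter-recovery fits at
$n = 200, m = 30$; the specificity benchmark at $n = 2000, m = 90$ with the
full frequency grid $p \in \{0.05, \dots, 0.95\}$ and both event lengths;
power curves at $n = 2000, m = 60$ over 3 seeds; segmentation oracle
equivalence on 100 instances of $n \le 12$ against full enumeration
($2^{n-1}$ models).

## Known limitations

* Exons are treated as exchangeable units; genomic distance between exons
  is not modeled (no distance-aware transition penalty), which is the price
  of an off-the-shelf, training-free segmentation.
* Common CNVs ($p$ near 0.5) lose power by design of any reference-free
  normalization; the case–control mode is the remedy when a clean cohort
  exists.
* The mBIC boundary convention makes a change point after the very first
  exon of a chromosome unrepresentable; a CNV covering exactly exon 1 will
  be merged into its neighbor segment.
* QC sample-level selection is limited to a 5x library-size warning;
  cross-platform harmonization is out of scope.
* Copy numbers are relative to the cohort average ploidy; no tumor
  purity/ploidy correction is attempted.
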