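---
title: "Methods: frequency tagging, inter-trial coherence and the Bayesian layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency tagging, inter-trial coherence and the Bayesian layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainKit)
```

# The measurement model

The package analyses a frequency-tagging design with two auditory
conditions. In the statistical-learning (SL) condition, four trisyllabic
pseudowords are concatenated into a continuous stream of 300-ms syllables
(100 ms consonant + 200 ms vowel). Word boundaries are marked only by the
transitional-probability structure: within a word each syllable predicts
the next with probability 1, across a boundary each of the other words'
initial syllables follows with probability ≈ 1/3. The acoustics therefore
contain a 3.33 Hz syllable rhythm, while a 1.11 Hz word rhythm exists only
for a listener who segments. In the rhythmic-ability (RA) condition, a
12-slot syncopated pattern of 200-ms counts (130 Hz tone bursts, 10 ms
rise / 50 ms fall) repeats every 2.4 s; the acoustic beat grid is 5 Hz and
the quadruple-meter grouping is 1.25 Hz. Following the stimulus
description, measure one plays all four tones, measure two omits the
first, and measure three plays only the third count — 8 tones and 4 silent
periods per pattern, every one of which carries a marker.

Neural entrainment at a frequency $f$ is quantified by the inter-trial
coherence over $N$ non-overlapping epochs,

$$\mathrm{ITC}(f) = \left| \frac{1}{N} \sum_{i=1}^{N} e^{i\,\Phi(f,i)} \right|,$$

where $\Phi(f,i)$ is the FFT phase of epoch $i$ at bin $f$. We take the
modulus (a resultant length), which makes the statistic real and bounded
in $[0, 1]$; without it the statistic would be complex, which is
inconsistent with its stated range. Under no phase locking the
expectation is the chance level $\sqrt{\pi/4N}$, not zero — tests compare
against this bias explicitly. Because ITC uses only phases, it is
invariant to per-epoch amplitude scaling.

Epochs are 9 s in SL (ten 0.9-s words) and 8 s in RA (ten 0.8-s
measures), so the FFT bin width ($1/T$: 0.111 Hz and 0.125 Hz) places bin
centres exactly on the four frequencies of interest (1.111, 3.333, 1.25,
5 Hz). A plain rectangular-window FFT of the full epoch is used; the
quoted bin widths imply no tapering or zero-padding. The grid is
restricted to 0.6–10 Hz.

## Assumptions and open choices

Several details are genuinely open in this design; the package makes the
following choices and exposes them as parameters:

* **Channel aggregation.** One ITC per infant per frequency is the
  arithmetic mean of the per-channel ITCs over the 21 retained channels.
  Per-channel values remain available in the `ITCSpectrum` object for ROI
  analyses.
* **Epoch placement.** The first epoch starts at the first marker; epochs
  are consecutive and non-overlapping, so alignment to the word/measure
  grid holds by construction (epoch lengths are exact multiples of the
  word and measure periods). After interval excision, the grid is kept
  fixed and epochs that would straddle a seam are skipped.
* **Centring.** ITC indices are centred across participants within each
  condition before correlation. Centring cannot change any Kendall
  statistic (rank order is preserved); it only eases comparison across
  conditions.
* **Exposure.** Records shorter than the minimum exposure (2.25 min SL /
  2 min RA, i.e. 15 epochs) are flagged as excluded via a typed error so
  cohort code can keep an exclusion ledger. Epoch counts per infant are
  carried through to the outputs; no statistical reweighting by N is
  attempted.

# The preprocessing chain

The cleaning chain runs in a fixed order — mastoid re-reference, filter,
bad-channel interpolation, interval excision, Artifact Blocking,
outer-ring removal — and every stage appends to an audit log on the
recording.

* **Re-referencing** subtracts the algebraic mastoid average (L+R)/2 and
  drops the mastoids, before any filtering.
* **Filtering** is an order-2 Butterworth bandpass at 0.5–20 Hz
  (12 dB/oct per edge) plus a narrow band-stop at 50 Hz, applied
  zero-phase (forward–backward). Zero-phase application preserves the
  phase structure that ITC depends on; it doubles the effective roll-off,
  which we accept and document.
* **Interpolation** replaces a bad channel by the inverse-distance-
  weighted (power 2) average of the good channels on a schematic 2-D
  10/20 layout. At 21–32 channels this is an adequate substitute for
  spherical splines; the reconstruction-quality test requires correlation
  > 0.9 with a smooth ground-truth field.
* **Artifact Blocking** builds a reference copy of the continuous record
  with every sample exceeding ±θ (θ = 50 µV) suppressed, then estimates
  one least-squares spatial smoothing matrix for the whole record
  ("total" approach), $B = X_\mathrm{ref} X^\top (X X^\top)^+$, and
  applies it. On clean data $X_\mathrm{ref} = X$ and $B$ is the identity;
  super-threshold stretches are reconstructed from their spatial
  correlation with clean channels. The Gram matrix is inverted with an
  SVD pseudoinverse because interpolation and re-referencing make the
  channel covariance exactly rank-deficient; this is benign. The failure
  mode that must be signalled — excessive artifacts preventing estimation
  of the smoothing matrix — is detected as more than half of all samples
  exceeding the threshold, and raises an error so the record can be
  excluded.
* **Outer-ring removal** drops the 11 most peripheral channels of the
  32-channel montage, leaving 21. The exact ring membership is a montage
  convention; it is configurable, and a non-21 result under the default
  layout warns rather than fails.

# The synthetic-data generator

The generator exists so that every downstream stage has a known ground
truth. A simulated recording is the sum of:

* **Entrained components**: global sinusoids (per-channel gain jitter
  ±20%) at stimulus frequencies whose phase at each analysis-epoch start
  is drawn from a von Mises distribution with concentration $\kappa_v$.
  $\kappa_v = 0$ gives uniform phases (ITC at chance), $\kappa_v \to
  \infty$ perfect locking (ITC → 1); in between, the expected ITC is the
  expected resultant length of $N$ von Mises phasors, computed by
  `expectedITC()` (large-$N$ limit $I_1(\kappa)/I_0(\kappa)$, finite-$N$
  value by Monte Carlo with a fixed internal seed). This makes ITC
  parameter recovery testable: generated $\kappa_v$ maps monotonically to
  measured ITC within Monte-Carlo error.
* **1/f background**: spectrally shaped Gaussian noise
  ($1/f^{\alpha}$, default $\alpha = 1$) scaled to a target RMS
  (default 10 µV), plus a 50 Hz line component. The pink background is
  what makes ITC at unrelated bins sit near chance.
* **Artifacts**: raised-cosine transients with amplitudes (default
  100–500 µV) strictly above the blocking threshold, at a configurable
  rate, logged in a ground-truth table.

Sampling rate defaults to 512 Hz with 32 named channels (plus two
noise-only mastoids); von Mises draws use the Best–Fisher rejection
sampler. What the generator does *not* emulate: realistic head-model
topographies, eye-blink/cardiac artifact morphology, non-stationary
background spectra, or evoked (amplitude-locked) responses. Passing tests
therefore demonstrate correctness of the measurement and inference chain
under controlled phase locking, not performance on real infant EEG.

The family-table generator produces parent-mean scores for the three
musicality instruments (two parents sharing a family-level latent trait,
each score missing with a configurable probability; a missing parent
leaves the other parent's score), engagement sums on the 4–16 scale (two
4-point items per parent per variable, summed over both parents; a
missing parent drops the sum), infant age uniform between 6;20 and 9;05
(months;days, encoded as days with months × 30.44), and log-ITC outcomes
from a linear model on standardized predictors with configurable
coefficients and residual SD.

# The Bayesian layer

## Kendall tau-b Bayes factors

The association test is a one-sided Bayes factor for Kendall's $\tau_b$.
The prior is a stretched beta: beta$(1/\kappa, 1/\kappa)$ rescaled to
$(-1, 1)$, placed on Pearson's $\rho$ and transported to the $\tau$ scale
through Greiner's relation $\tau = (2/\pi)\arcsin\rho$ with its Jacobian;
the default width $\kappa = 0.5$ gives a beta(2, 2) shape, and one-sided
variants truncate at zero and renormalize. The sampling distribution of
the observed $\hat\tau$ is taken as normal with mean $\tau$ and the
asymptotic null variance $2(2n+5)/(9n(n-1))$ for all $\tau$ — the
simplest defensible choice, validated against the printed Bayes factors
it must reproduce (a $\tau$-dependent variance is exposed as an option).
Then

$$\mathrm{BF}_{10} = \frac{\int p(\hat\tau \mid \tau, n)\, \pi_1(\tau)\,
d\tau}{p(\hat\tau \mid 0, n)},$$

evaluated by adaptive quadrature on the bounded support (relative
tolerance 10⁻⁶) and cross-checked in the tests against a Monte-Carlo
marginal likelihood to within 2%. The posterior over $\tau$ (normalized
product on a 2001-point grid) yields the central 95% credible interval on
the $\tau$ scale. A result counts as *robust* when BF₁₀ > 3 and no wider
prior in the grid (up to $\kappa = 2$) drops it below 3. Sequential
analysis recomputes the BF on growing prefixes.

## JZS model averaging

The regression layer places a Jeffreys–Zellner–Siow prior on the
standardized coefficients: a multivariate Cauchy with scale $r$
(medium $\sqrt{1/8} = 0.354$, wide 0.5, ultrawide 0.707), represented as
a normal g-prior mixed over $g \sim \mathrm{InvGamma}(1/2, n r^2/2)$. For
a model with $p$ predictors and fit $R^2$ the Bayes factor against the
intercept-only null is the one-dimensional integral

$$\mathrm{BF} = \int_0^\infty (1+g)^{(n-p-1)/2}\,
\bigl(1 + g(1-R^2)\bigr)^{-(n-1)/2} \pi(g)\, dg,$$

computed by adaptive quadrature after the substitution $t = \log g$
(which keeps the integrand smooth for very small prior scales); the
tests verify it against Monte-Carlo evaluation of the same mixture.
All $2^p$ predictor subsets are enumerated under a uniform model prior
(each $2^{-p}$) or a beta-binomial(1, 1) prior (equal mass per model
size). Posterior model probabilities are prior × BF, normalized;
per-predictor inclusion statistics follow, with
BF_inclusion the change from prior to posterior inclusion odds.
Model-averaged coefficient moments use the conditional posterior given
$g$ — the least-squares estimate shrunk by $g/(1+g)$, with its
multivariate-t covariance — integrated over the posterior of $g$ on a
shrinkage grid; excluding models contribute a point mass at zero and the
SD follows the law of total variance. The 95% credible interval comes
from the posterior mixture CDF. Everything is quadrature-based, so
results are deterministic and exactly reproducible.

Outcome handling mirrors the analysis workflow: the outcome is
log-transformed (on the raw, positive ITC scale) *before* centring when
requested — log of a centred value would be undefined for the negative
half — and all predictors, including infant age, are standardized with
the $n-1$ SD. Complete cases are taken per analysis. Collinearity is
screened with pairwise correlations (Pearson bound 0.80 ≙ $\tau_b$ 0.59
via Greiner) and variance inflation factors; a Shapiro–Wilk gate on the
best model's residuals suggests the log transform when normality is
rejected at $\alpha = 0.05$. A sensitivity harness reruns the analysis
over both model priors × the three JZS scales and reports whether the
best model changes.

# The cohort pipeline

`runCohort()` ties everything together: per infant it draws a listening
exposure and a pair of word/meter phase concentrations from a correlated
log-normal (the correlation is the *generative coupling* the pipeline
should recover), simulates both conditions, runs the full preprocessing
chain, epochs, and extracts ITC indices and the 11-pair grid; failures
land in an exclusion ledger and simulated n always reconciles with
analyzed + excluded n. The cohort report applies the Kendall BF to every
centred frequency pair and the model-averaging layer to the measured
log-ITC outcomes with simulated parental scores. One global seed fans out
as `seed + i·10007` per infant, so growing the cohort never reshuffles
earlier infants, and a repeated run with the same seed is byte-identical.

## Word-order pseudorandomization

The SL word order must contain each word exactly 75 times per block with
no immediate repeats (enforced across the block seam, since the two
blocks play as one seamless 9-minute stream). Accept–reject sampling over
uniform shuffles is not viable here: the probability that a uniform
300-word shuffle of four balanced words has no adjacent repeat is about
$e^{-75}$. Instead the generator draws words sequentially with
probability proportional to their remaining counts (excluding the
previous word), forcing a word whenever its remaining count exceeds half
the remaining slots (otherwise the sequence could become uncompletable),
and retries the rare dead ends within a bound of 10,000 attempts. This
produces near-uniform constraint-satisfying orders with exact counts.

## Numerical choices and problem sizes

Tolerances and degenerate inputs are handled as follows: timeline
contiguity is checked to 10⁻⁹ s; excision intervals are half-open
`[start, end)` with 0-based sample indexing, and overlapping intervals
merge; a frequency-of-interest further than half a bin from the retained
grid is an error (within the 0.6–10 Hz grid the nearest bin is always
within half a bin, so this fires only for out-of-range targets); an
all-tied margin makes $\tau_b$ undefined and errors; a constant column
cannot be standardized; perfect design collinearity errors with the
offending column names, while a duplicated predictor in the VIF screen
reports `Inf`.

Tests and the worked examples run the pipeline at reduced problem sizes —
64–128 Hz sampling, 2–16 channels, minimum-exposure recordings, cohorts
of 8–30 — chosen so the full suite completes in a couple of minutes while
every scientific property (exact epoch counts, bin placement, ITC
expectations, calibration rates) is unchanged by the scaling. The
generator's *defaults* remain the study conditions (512 Hz, 32 channels,
full 9/8-minute streams).

# Known limitations

* The under-H1 sampling variance of $\hat\tau$ is the null asymptotic
  variance; for large true $\tau$ this is conservative in the tails.
* The credible intervals for model-averaged coefficients use a normal
  approximation within each model when inverting the mixture CDF.
* Inverse-distance interpolation ignores scalp curvature; with dense
  montages spherical splines would be preferable.
* The synthetic EEG is a phase-locking forward model, not a biophysical
  one; absolute ITC magnitudes in real infant data depend on
  signal-to-noise properties the generator only coarsely matches.
* The placeholder SL audio renders syllables as distinguishable tone
  tokens; it is sufficient for marker/timing work but is not speech.
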