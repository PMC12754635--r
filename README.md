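# entrainKit

Tools for frequency-tagging studies of infant neural entrainment that link
**statistical learning** (SL — segmenting continuous speech by tracking
transitional probabilities between syllables) with **rhythmic ability**
(RA — perceiving the beat and inferring the meter of a rhythmic stimulus).

In this paradigm an infant hears (1) a continuous stream of four
trisyllabic pseudowords at a constant 3.33 Hz syllable rate, where the only
cue to word boundaries is the transitional-probability structure (1.0
within words, ≈ 1/3 across boundaries), and (2) a syncopated rhythm of
130 Hz tone bursts on a 5 Hz beat grid in quadruple (4/4) meter. If the
brain segments words, a 1.11 Hz word frequency emerges in the EEG that is
not present in the acoustics; if it infers the meter, a 1.25 Hz meter
frequency emerges likewise. Phase locking at those frequencies is
quantified by the **inter-trial coherence**

ITC(f) = | (1/N) Σᵢ exp(i·Φ(f, i)) |,

the modulus of the mean unit phasor of the per-epoch FFT phases Φ(f, i)
over N non-overlapping epochs (9 s in the SL condition, 8 s in RA, so the
frequency bins land exactly on the frequencies of interest). ITC is 1 for
perfect entrainment and ≈ √(π/4N) under no phase locking.

The package provides, end to end:

* **Stimulus generation** — pseudorandomized SL syllable streams (no
  immediate word repeats, exact per-word counts) and the 12-slot
  syncopated rhythm timeline, with placeholder audio rendering (WAV) and
  JSON marker sidecars.
* **Synthetic EEG** — multichannel recordings with oscillatory components
  whose per-epoch phase is von Mises distributed with known concentration
  (so downstream ITC has a computable expectation), 1/f background, mains
  line noise, and injected high-amplitude artifacts with a ground-truth
  log.
* **Preprocessing** — mastoid re-referencing, order-2 zero-phase 0.5–20 Hz
  bandpass + 50 Hz notch, bad-channel interpolation, manual-interval
  excision, the Artifact Blocking correction (least-squares spatial
  smoothing matrix with threshold θ = ±50 µV), and outer-ring removal to
  the 21 analysis channels.
* **Entrainment statistics** — epoching, ITC spectra (0.6–10 Hz), the four
  indices ITC_word, ITC_syll, ITC_meter, ITC_beat, and the 11-step
  frequency-pair grid from the word/meter frequencies to their first
  harmonics.
* **Bayesian inference** — one-sided Bayes factors for Kendall's τ_b under
  a stretched beta prior (width κ, default 0.5 ≙ beta(2, 2), transported
  to the τ scale via Greiner's relation τ = (2/π)·asin(ρ)), with
  robustness curves over κ and sequential analyses; and Bayesian model
  averaging for linear regression under the Jeffreys–Zellner–Siow prior
  (Cauchy scale r ∈ {0.354, 0.5, 0.707}) with uniform or beta-binomial
  model priors, posterior inclusion probabilities, inclusion Bayes
  factors, model-averaged coefficients, VIF collinearity checks and a
  residual-normality gate.
* **Cohort pipeline** — `runCohort()` simulates a whole infant cohort with
  a configurable generative word–meter coupling, runs every record through
  the full chain and emits the correlation and regression report tables.

## Worked example

```r
library(entrainKit)

## One-sided Kendall Bayes factor from summary statistics
res <- kendallBF(tauObs = 0.25, n = 40)   # kappa = 0.5, positive side
res
#> Kendall tau-b Bayes factor (side = positive, kappa = 0.5)
#>   tau-b = 0.250, n = 40, BF10 = 6.480, 95% CI [0.044, 0.433], robust: yes
```

A BF₁₀ of 6.5 is moderate evidence for a positive word–meter association
(criterion BF₁₀ > 3); the verdict survives widening the prior to κ = 2.

```r
## End-to-end simulated cohort (reduced problem size for speed)
cfg <- runConfig(seed = 11, cohortSize = 12, sampleRate = 128, nChannels = 8,
                 exposureSL = c(135, 135), exposureRA = c(120, 120),
                 coupling = 0.8,
                 preprocess = preprocessConfig(outerRing = character(0)))
bundle <- runCohort(cfg)
bundle$correlationReport[1, c("label", "tau_b", "bf10")]
#>                   label     tau_b     bf10
#> 1 RA1.250-SL1.111 (RQ1) 0.3939394 3.189637
```

With a strong generative coupling (0.8) between the per-infant word and
meter phase concentrations, the pipeline recovers a clearly positive
cohort-level rank correlation at the word–meter pair.

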