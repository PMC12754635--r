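# Shared fixtures: small, fast objects built in code.

# A short RA recording with known entrained components; low rate and few
# channels keep tests fast while the science (phases, ITC) is unchanged.
makeRARecording <- function(seconds = 120, kappaMeter = 3, kappaBeat = 3,
                            pink = 5, nChannels = 8, sampleRate = 64,
                            seed = 1, artifacts = NULL,
                            includeMastoids = FALSE) {
  tl <- truncateTimeline(buildRAStream(), seconds)
  simulateEEG(tl,
              entrainSpec(frequency = c(1.25, 5), amplitude = c(4, 8),
                          kappa = c(kappaMeter, kappaBeat)),
              noiseSpec(pinkAmplitude = pink, lineAmplitude = 0.5),
              artifacts = artifacts, nChannels = nChannels,
              sampleRate = sampleRate, seed = seed,
              includeMastoids = includeMastoids)
}

# Brute-force Kendall tau-b by pair enumeration with tie corrections.
bruteTauB <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Monte-Carlo marginal-likelihood oracle for the Kendall BF: draws tau
# from the stretched beta prior and averages the sampling density.
mcKendallBF <- function(tauObs, n, kappa = 0.5, side = "two_sided",
                        m = 2e5) {
  a <- 1 / kappa
  rho <- 2 * rbeta(m, a, a) - 1
  tau <- 2 / pi * asin(rho)
  if (side == "positive") tau <- abs(tau)
  if (side == "negative") tau <- -abs(tau)
  s <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  mean(dnorm(tauObs, tau, s)) / dnorm(tauObs, 0, s)
}

# Generate paired data with a given generative rank association.
rankCorrelatedPairs <- function(n, rho) {
  z <- rnorm(n)
  x <- z
  y <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}
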