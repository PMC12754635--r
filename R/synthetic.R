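#' Specification of phase-locked oscillatory components
#'
#' Describes the entrained components injected into a simulated recording.
#' Each component is a sinusoid at a stimulus-related frequency whose phase
#' at the start of each analysis epoch is drawn from a von Mises
#' distribution with concentration `kappa` around `basePhase`:
#' `kappa = 0` gives uniform phases (no locking, chance-level ITC) and
#' large `kappa` approaches perfect phase locking (ITC -> 1).
#'
#' @param frequency numeric vector, component frequencies in Hz.
#' @param amplitude numeric vector, amplitudes in microvolts.
#' @param kappa numeric vector, von Mises phase concentrations (>= 0).
#' @param basePhase numeric vector, preferred phases in radians.
#' @param perEpochJitter logical; when TRUE (default) the phase is redrawn
#'   at every epoch start, when FALSE it is held at `basePhase`.
#' @return a list of class `EntrainSpec`.
#' @export
#' @examples
#' entrainSpec(frequency = c(1.25, 5), amplitude = c(1, 2), kappa = c(2, 4))
entrainSpec <- function(frequency = numeric(0), amplitude = numeric(0),
                        kappa = numeric(0), basePhase = 0,
                        perEpochJitter = TRUE) {
  k <- length(frequency)
  stopifnot(all(frequency > 0), all(kappa >= 0), all(amplitude >= 0))
  structure(list(
    components = data.frame(
      frequency = frequency,
      amplitude = rep_len(amplitude, k),
      kappa = rep_len(kappa, k),
      basePhase = rep_len(basePhase, k)
    ),
    perEpochJitter = perEpochJitter
  ), class = "EntrainSpec")
}

#' Background-noise specification for simulated EEG
#'
#' @param pinkExponent spectral exponent of the 1/f background (1.0).
#' @param pinkAmplitude RMS amplitude of the pink background per channel,
#'   microvolts.
#' @param lineHz mains frequency in Hz (50).
#' @param lineAmplitude mains amplitude in microvolts.
#' @return a list of class `NoiseSpec`.
#' @export
noiseSpec <- function(pinkExponent = 1.0, pinkAmplitude = 10,
                      lineHz = 50, lineAmplitude = 1) {
  stopifnot(pinkAmplitude >= 0, lineAmplitude >= 0)
  structure(list(pinkExponent = pinkExponent, pinkAmplitude = pinkAmplitude,
                 lineHz = lineHz, lineAmplitude = lineAmplitude),
            class = "NoiseSpec")
}

#' Artifact-injection specification
#'
#' High-amplitude transients emulating movement artifacts (an infant being
#' fussy or pulling on the cap). Amplitudes must exceed the Artifact
#' Blocking threshold so injected events are detectable by construction.
#'
#' @param ratePerMin expected artifact count per minute.
#' @param amplitudeRange numeric(2), peak amplitude range in microvolts.
#' @param durationRange numeric(2), artifact duration range in seconds.
#' @param channelScope "single" (one random channel per artifact) or "all".
#' @param threshold the blocking threshold the amplitudes must exceed (50).
#' @return a list of class `ArtifactSpec`.
#' @export
artifactSpec <- function(ratePerMin = 2, amplitudeRange = c(100, 500),
                         durationRange = c(0.2, 1.0),
                         channelScope = c("single", "all"),
                         threshold = 50) {
  channelScope <- match.arg(channelScope)
  if (min(amplitudeRange) <= threshold) {
    stop("artifact amplitudes must exceed the blocking threshold (",
         threshold, " microvolts) to be detectable")
  }
  structure(list(ratePerMin = ratePerMin, amplitudeRange = amplitudeRange,
                 durationRange = durationRange, channelScope = channelScope),
            class = "ArtifactSpec")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` reduces to uniform
#' phases on (-pi, pi].
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- mu + sign(u3 - 0.5) * acos(f)
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Expected inter-trial coherence under von Mises phase locking
#'
#' The expectation of the mean resultant length of `n` unit phasors whose
#' phases are von Mises with concentration `kappa`. In the large-N limit
#' this equals the Bessel ratio I1(kappa)/I0(kappa); for finite N the value
#' is obtained by Monte Carlo over the resultant length (with `kappa = 0`
#' and large N it approaches the chance level sqrt(pi/(4N))).
#'
#' @param kappa von Mises concentration, >= 0; `Inf` means perfect locking.
#' @param n number of epochs; `Inf` requests the large-N Bessel-ratio limit.
#' @param nsim Monte Carlo replicates for finite `n` (default 2000).
#' @param seed internal seed for the Monte Carlo draw (default 1), so the
#'   oracle is reproducible.
#' @return the expected ITC, with attributes `sd` (standard deviation of a
#'   single measured ITC across replicates) and `mcse` (Monte Carlo
#'   standard error of the mean).
#' @export
#' @examples
#' expectedITC(2, Inf)                # I1(2)/I0(2), about 0.698
#' expectedITC(0, 60)                 # chance level, about 0.11
expectedITC <- function(kappa, n, nsim = 2000, seed = 1) {
  stopifnot(kappa >= 0, n >= 1)
  if (is.infinite(kappa)) {
    out <- 1
    attr(out, "sd") <- 0
    attr(out, "mcse") <- 0
    return(out)
  }
  if (is.infinite(n)) {
    out <- besselRatio(kappa)
    attr(out, "sd") <- 0
    attr(out, "mcse") <- 0
    return(out)
  }
  r <- withr_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      ph <- rvonmises(n, 0, kappa)
      Mod(mean(exp(1i * ph)))
    }, numeric(1))
  })
  out <- mean(r)
  attr(out, "sd") <- stats::sd(r)
  attr(out, "mcse") <- stats::sd(r) / sqrt(nsim)
  out
}

# I1(kappa)/I0(kappa), numerically stable for large kappa.
besselRatio <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Standard 32-channel layout with schematic head coordinates
#'
#' Channel names of the standard 32-electrode 10/20 montage used for
#' simulation, with schematic 2-D head coordinates (x towards the right
#' ear, y towards the nasion) used for distance-weighted interpolation.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
channelLayout32 <- function() {
  data.frame(
    channel = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
                "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
                "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
                "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"),
    x = c(-0.22, -0.25, -0.55, -0.30, -0.15, -0.45, -0.70, -0.35,
          -0.15, -0.45, -0.55, -0.30, 0.00, -0.25, -0.22, 0.00,
          0.22, 0.25, 0.30, 0.55, 0.45, 0.15, 0.35, 0.70,
          0.45, 0.15, 0.30, 0.55, 0.25, 0.22, 0.00, 0.00),
    y = c(0.65, 0.50, 0.40, 0.35, 0.18, 0.20, 0.00, 0.00,
          -0.18, -0.20, -0.40, -0.35, -0.35, -0.50, -0.65, -0.68,
          -0.65, -0.50, -0.35, -0.40, -0.20, -0.18, 0.00, 0.00,
          0.20, 0.18, 0.35, 0.40, 0.50, 0.65, 0.35, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Default outer-ring channels of the 32-channel layout
#'
#' The peripheral electrodes removed before Artifact Blocking, leaving 21
#' channels for analysis. The montage's exact outer-ring membership is a
#' configurable convention; this default removes the 11 most peripheral
#' positions.
#'
#' @return character vector of channel names.
#' @export
defaultOuterRing <- function() {
  c("Fp1", "Fp2", "F7", "F8", "T7", "T8", "P7", "P8", "O1", "O2", "Oz")
}

# 1/f^alpha noise of length n with RMS `amp`, via spectral shaping.
pinkNoise <- function(n, alpha, amp) {
  if (amp == 0) return(numeric(n))
  nf <- n %/% 2L
  f <- seq_len(nf)
  mag <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(real = 0, imaginary = 0, length.out = n)
  spec[2:(nf + 1L)] <- mag * exp(1i * ph)
  spec[n:(n - nf + 2L)] <- Conj(spec[2:(nf)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * amp / stats::sd(x)
}

# Smooth raised-cosine bump used as the injected artifact shape.
artifactBump <- function(len) {
  0.5 * (1 - cos(2 * pi * (seq_len(len) - 1L) / (len - 1L)))
}

#' Simulate a multichannel EEG recording for an event timeline
#'
#' Builds a channels-by-samples recording as the sum of phase-locked
#' oscillatory components, 1/f ("pink") background noise, mains-line
#' noise and injected high-amplitude artifact transients. Components are
#' global across channels with a per-channel gain jitter of +/- 20%. When
#' `perEpochJitter` is set, each component's phase is redrawn at the start
#' of every analysis epoch (9 s for SL, 8 s for RA timelines) from a von
#' Mises distribution, which makes the downstream ITC at that frequency a
#' known function of the concentration (see [expectedITC()]).
#'
#' Two mastoid channels ("M1", "M2") carrying only noise are appended when
#' `includeMastoids` is TRUE so the re-referencing stage has its inputs.
#' Injected artifacts are logged in the ground-truth table.
#'
#' @param timeline an [EventTimeline-class] giving markers and duration.
#' @param entrain an [entrainSpec()].
#' @param noise a [noiseSpec()].
#' @param artifacts an [artifactSpec()] or NULL for none.
#' @param nChannels number of scalp channels (default 32; must be <= 32
#'   when using the standard layout names).
#' @param sampleRate sampling rate in Hz (default 512).
#' @param seed integer seed; the same seed gives a bit-identical recording.
#' @param includeMastoids append noise-only mastoid channels (TRUE).
#' @param epochLength epoch length used for per-epoch phase draws;
#'   defaults to 9 s for SL and 8 s for RA timelines.
#' @return an [EEGRecording-class].
#' @export
simulateEEG <- function(timeline, entrain = entrainSpec(),
                        noise = noiseSpec(), artifacts = NULL,
                        nChannels = 32, sampleRate = 512, seed = 1,
                        includeMastoids = TRUE,
                        epochLength = if (timeline@condition == "SL") 9 else 8) {
  comp <- entrain$components
  if (nrow(comp) > 0L && max(comp$frequency) * 2 > sampleRate) {
    stop("component frequency exceeds the Nyquist limit")
  }
  layout <- channelLayout32()
  stopifnot(nChannels <= nrow(layout))
  chn <- layout$channel[seq_len(nChannels)]
  set.seed(seed)
  dur <- timeline@totalDuration
  n <- round(dur * sampleRate)
  t <- (seq_len(n) - 1L) / sampleRate

  base <- numeric(n)
  ev <- timeline@events
  firstOnset <- if (nrow(ev) > 0L) ev$onset_s[1L] else 0
  epochStarts <- seq(firstOnset, dur - epochLength, by = epochLength)
  if (nrow(comp) > 0L) {
    for (j in seq_len(nrow(comp))) {
      f <- comp$frequency[j]; A <- comp$amplitude[j]
      if (A == 0) next
      phase <- rep(comp$basePhase[j], n)
      if (entrain$perEpochJitter && length(epochStarts) > 0L) {
        ph <- rvonmises(length(epochStarts), comp$basePhase[j], comp$kappa[j])
        for (e in seq_along(epochStarts)) {
          i0 <- round(epochStarts[e] * sampleRate) + 1L
          i1 <- min(n, round((epochStarts[e] + epochLength) * sampleRate))
          # phase is referenced to the epoch start so the FFT phase of the
          # epoch at bin f equals the drawn angle up to a fixed offset
          phase[i0:i1] <- ph[e] - 2 * pi * f * t[i0]
        }
      }
      base <- base + A * cos(2 * pi * f * t + phase)
    }
  }

  gains <- 1 + stats::runif(nChannels, -0.2, 0.2)
  X <- matrix(0, nrow = nChannels, ncol = n)
  for (c0 in seq_len(nChannels)) {
    ch <- gains[c0] * base
    ch <- ch + pinkNoise(n, noise$pinkExponent, noise$pinkAmplitude)
    if (noise$lineAmplitude > 0) {
      ch <- ch + noise$lineAmplitude *
        sin(2 * pi * noise$lineHz * t + stats::runif(1, 0, 2 * pi))
    }
    X[c0, ] <- ch
  }

  truth <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      amplitude = numeric(0), channel = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(artifacts)) {
    nArt <- stats::rpois(1, artifacts$ratePerMin * dur / 60)
    for (a in seq_len(nArt)) {
      adur <- stats::runif(1, artifacts$durationRange[1L], artifacts$durationRange[2L])
      amp <- stats::runif(1, artifacts$amplitudeRange[1L], artifacts$amplitudeRange[2L])
      onset <- stats::runif(1, 0, dur - adur)
      i0 <- round(onset * sampleRate) + 1L
      len <- max(3L, round(adur * sampleRate))
      idx <- i0:min(n, i0 + len - 1L)
      bump <- amp * artifactBump(length(idx)) * sample(c(-1, 1), 1)
      if (artifacts$channelScope == "single") {
        chSel <- sample(nChannels, 1)
        X[chSel, idx] <- X[chSel, idx] + bump
        chLab <- chn[chSel]
      } else {
        X[, idx] <- X[, idx] + matrix(rep(bump, each = nChannels), nrow = nChannels)
        chLab <- "all"
      }
      truth <- rbind(truth, data.frame(onset_s = onset, duration_s = adur,
                                       amplitude = amp, channel = chLab,
                                       stringsAsFactors = FALSE))
    }
  }

  if (includeMastoids) {
    M <- rbind(pinkNoise(n, noise$pinkExponent, noise$pinkAmplitude),
               pinkNoise(n, noise$pinkExponent, noise$pinkAmplitude))
    X <- rbind(X, M)
    chn <- c(chn, "M1", "M2")
  }
  rownames(X) <- chn

  mk <- data.frame(
    onset_s = ev$onset_s,
    onset_sample = round(ev$onset_s * sampleRate),
    label = ev$label,
    level = ev$level,
    stringsAsFactors = FALSE
  )
  new("EEGRecording", data = X, sampleRate = sampleRate, channelNames = chn,
      markers = mk, condition = timeline@condition,
      log = data.frame(stage = "simulate",
                       detail = sprintf("seed=%d channels=%d rate=%g", seed,
                                        nChannels, sampleRate),
                       stringsAsFactors = FALSE),
      seams = numeric(0), artifactTruth = truth)
}

#' Family-effect specification for score-table simulation
#'
#' @param nFamilies number of families.
#' @param coefficients named numeric vector of standardized effects of the
#'   predictors (`cabat`, `proms`, `goldmsi`, `age`, `pme`, `pcme`) on the
#'   log-ITC outcomes; absent names mean zero effect.
#' @param residualSd residual standard deviation of the outcome model.
#' @param missingness probability that one parent's score on a task is
#'   missing.
#' @return a list of class `FamilyEffectSpec`.
#' @export
familyEffectSpec <- function(nFamilies = 44, coefficients = c(),
                             residualSd = 1, missingness = 0.05) {
  stopifnot(residualSd > 0, missingness >= 0, missingness <= 1)
  structure(list(nFamilies = nFamilies, coefficients = coefficients,
                 residualSd = residualSd, missingness = missingness),
            class = "FamilyEffectSpec")
}

# months;days to days, months taken as 30.44 days
ageDays <- function(months, days) months * 30.44 + days

#' Simulate a per-family score table
#'
#' Generates the cohort covariate table: infant age (uniform between 6;20
#' and 9;05 months;days, encoded in days), parent-mean CA-BAT, PROMS and
#' Gold-MSI scores, parent musical engagement sums (`pme`, `pcme`, each the
#' sum of both parents' four 4-point items, range 4-16), and log-ITC
#' outcomes generated from the stated linear model on standardized
#' predictors. Each parent's task score can be missing with the configured
#' probability; when one parent is missing a task the remaining parent's
#' score is used alone, and an engagement sum with a missing parent is
#' dropped (NA).
#'
#' @param spec a [familyEffectSpec()].
#' @param seed integer seed.
#' @return data.frame with one row per family.
#' @export
simulateFamilyTable <- function(spec = familyEffectSpec(), seed = 1) {
  set.seed(seed)
  n <- spec$nFamilies
  age <- stats::runif(n, ageDays(6, 20), ageDays(9, 5))
  latent <- stats::rnorm(n)  # family-level musical aptitude
  parentScore <- function(center, scale, share = 0.6) {
    p1 <- center + scale * (share * latent + sqrt(1 - share^2) * stats::rnorm(n))
    p2 <- center + scale * (share * latent + sqrt(1 - share^2) * stats::rnorm(n))
    miss1 <- stats::runif(n) < spec$missingness
    miss2 <- stats::runif(n) < spec$missingness
    p1[miss1] <- NA; p2[miss2] <- NA
    rowMeans(cbind(p1, p2), na.rm = TRUE)
  }
  cabat <- parentScore(0, 1)
  proms <- parentScore(50, 10)
  goldmsi <- parentScore(70, 15)
  engagementSum <- function() {
    # two 4-point items per parent per variable; summing both parents'
    # items gives the documented 4-16 range
    items1 <- matrix(sample(1:4, n * 2, replace = TRUE), n)
    items2 <- matrix(sample(1:4, n * 2, replace = TRUE), n)
    s <- rowSums(items1) + rowSums(items2)
    s[stats::runif(n) < spec$missingness] <- NA  # one parent missing -> excluded
    s
  }
  pme <- engagementSum()
  pcme <- engagementSum()
  std <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  Z <- cbind(cabat = std(cabat), proms = std(proms), goldmsi = std(goldmsi),
             age = std(age), pme = std(pme), pcme = std(pcme))
  lp <- function() {
    out <- numeric(n)
    for (nm in names(spec$coefficients)) {
      z <- Z[, nm]
      z[is.na(z)] <- 0
      out <- out + spec$coefficients[[nm]] * z
    }
    out
  }
  logITCm <- log(0.15) + lp() + stats::rnorm(n, 0, spec$residualSd)
  logITCw <- log(0.12) + lp() + stats::rnorm(n, 0, spec$residualSd)
  data.frame(
    family = seq_len(n),
    infant_age_days = age,
    cabat = cabat, proms = proms, goldmsi = goldmsi,
    pme = pme, pcme = pcme,
    log_itc_meter = logITCm, log_itc_word = logITCw,
    itc_meter = pmin(1, exp(logITCm)), itc_word = pmin(1, exp(logITCw)),
    stringsAsFactors = FALSE
  )
}
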