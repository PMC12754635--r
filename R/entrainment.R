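#' Cut a recording into fixed-length analysis epochs
#'
#' Extracts consecutive, non-overlapping epochs time-locked to the event
#' grid: the first epoch starts at the first marker, and epoch lengths are
#' exact multiples of the word (0.9 s) or measure (0.8 s) period, so every
#' epoch spans ten words (SL, 9 s) or ten measures (RA, 8 s) and stays
#' aligned by construction. Epochs that would straddle an excision seam
#' are skipped (the grid itself is kept fixed). A recording whose
#' listening duration falls short of the minimum exposure (2.25 min SL /
#' 2 min RA) is flagged as excluded via an error of class
#' `exposureError`.
#'
#' A full 9-min SL recording yields 60 epochs; the minimum exposure yields
#' 15 in either condition.
#'
#' @param rec an [EEGRecording-class] with markers.
#' @param condition "SL" or "RA"; defaults to the recording's condition.
#' @param minExposure minimum listening time in seconds (135 SL / 120 RA).
#' @param maxEpochs cap on the number of epochs (default unlimited).
#' @param epochLength epoch duration in seconds (9 SL / 8 RA).
#' @return an [EpochSet-class].
#' @export
epochize <- function(rec,
                     condition = rec@condition,
                     minExposure = if (condition == "SL") 135 else 120,
                     maxEpochs = Inf,
                     epochLength = if (condition == "SL") 9 else 8) {
  stopifnot(condition %in% c("SL", "RA"))
  mk <- rec@markers
  if (nrow(mk) == 0L) stop("no markers present; cannot epoch")
  fs <- rec@sampleRate
  n <- ncol(rec@data)
  listened <- n / fs
  if (listened < minExposure) {
    stop(structure(class = c("exposureError", "error", "condition"),
                   list(message = sprintf(
                     "listening duration %.1f s below minimum exposure %.1f s; record excluded",
                     listened, minExposure), call = sys.call())))
  }
  first <- mk$onset_s[1L]
  starts <- seq(first, n / fs - epochLength, by = epochLength)
  if (length(starts) == 0L) stop("record too short for a single epoch")
  ok <- vapply(starts, function(s) {
    !any(rec@seams > s & rec@seams < s + epochLength)
  }, logical(1))
  starts <- starts[ok]
  if (is.finite(maxEpochs)) starts <- utils::head(starts, maxEpochs)
  ns <- round(epochLength * fs)
  nc <- nrow(rec@data)
  ep <- array(0, dim = c(length(starts), nc, ns))
  for (e in seq_along(starts)) {
    i0 <- round(starts[e] * fs) + 1L
    ep[e, , ] <- rec@data[, i0:(i0 + ns - 1L), drop = FALSE]
  }
  new("EpochSet", epochs = ep, epochLength = epochLength, sampleRate = fs,
      channelNames = rec@channelNames, condition = condition,
      alignment = if (condition == "SL") "syllable" else "beat")
}

#' Inter-trial coherence spectrum of an epoch set
#'
#' For every channel and frequency bin, ITC(f) = | (1/N) sum_i
#' exp(i Phi(f, i)) |, where Phi(f, i) is the FFT phase of epoch i at bin
#' f (plain FFT of the full epoch, rectangular window; the bin width is
#' the reciprocal of the epoch length). The modulus makes the statistic
#' real-valued and bounded in `[0, 1]`: 1 means perfect phase alignment
#' across epochs, and under no phase locking the expected value is the
#' chance level sqrt(pi/(4N)). The grid is restricted to 0.6-10 Hz. The
#' channel average is reported alongside; the statistic is insensitive to
#' per-epoch amplitude scaling because only phases enter.
#'
#' @param epochs an [EpochSet-class] with at least 2 epochs.
#' @param fmin,fmax frequency band retained, Hz (0.6, 10).
#' @return an [ITCSpectrum-class].
#' @export
itcSpectrum <- function(epochs, fmin = 0.6, fmax = 10) {
  d <- dim(epochs@epochs)
  N <- d[1L]; nc <- d[2L]; ns <- d[3L]
  if (N < 2L) stop("at least 2 epochs required")
  binWidth <- 1 / epochs@epochLength
  freqsAll <- (seq_len(ns) - 1L) * epochs@sampleRate / ns
  sel <- which(freqsAll >= fmin - 1e-9 & freqsAll <= fmax + 1e-9)
  freqs <- freqsAll[sel]
  phases <- array(0, dim = c(N, nc, length(sel)))
  itc <- matrix(0, nrow = nc, ncol = length(sel))
  for (ch in seq_len(nc)) {
    spec <- t(apply(epochs@epochs[, ch, , drop = FALSE][, 1L, ], 1L, stats::fft))
    ph <- Arg(spec[, sel, drop = FALSE])
    phases[, ch, ] <- ph
    itc[ch, ] <- Mod(colMeans(exp(1i * ph)))
  }
  rownames(itc) <- epochs@channelNames
  new("ITCSpectrum", frequencies = freqs, itc = itc,
      itcAvg = colMeans(itc), binWidth = binWidth, nEpochs = as.integer(N),
      phases = phases, channelNames = epochs@channelNames,
      condition = epochs@condition)
}

# Nearest grid bin to `target`, error when further than half a bin away.
nearestBin <- function(spectrum, target) {
  i <- which.min(abs(spectrum@frequencies - target))
  if (abs(spectrum@frequencies[i] - target) > spectrum@binWidth / 2 + 1e-9) {
    stop(sprintf("target frequency %.4g Hz not representable on this grid (bin width %.4g Hz)",
                 target, spectrum@binWidth))
  }
  i
}

#' Extract the four entrainment indices
#'
#' Nearest-bin lookup of the channel-mean ITC at the word (1.111 Hz) and
#' syllable (3.333 Hz) frequencies on the SL grid and the meter (1.25 Hz)
#' and beat (5 Hz) frequencies on the RA grid. With 9-s and 8-s epochs the
#' bin centres land exactly on these targets; a target further than half a
#' bin from any grid point is an error.
#'
#' @param specSL the SL-condition [ITCSpectrum-class].
#' @param specRA the RA-condition [ITCSpectrum-class].
#' @return data.frame with columns `itc_word`, `itc_syll`, `itc_meter`,
#'   `itc_beat` and the per-condition epoch counts.
#' @export
extractIndices <- function(specSL, specRA) {
  data.frame(
    itc_word = specSL@itcAvg[nearestBin(specSL, 10 / 9)],
    itc_syll = specSL@itcAvg[nearestBin(specSL, 30 / 9)],
    itc_meter = specRA@itcAvg[nearestBin(specRA, 1.25)],
    itc_beat = specRA@itcAvg[nearestBin(specRA, 5)],
    n_epochs_sl = specSL@nEpochs,
    n_epochs_ra = specRA@nEpochs
  )
}

#' The eleven-step frequency-pair grid
#'
#' Between the word/meter frequencies and their first harmonics there are
#' exactly eleven grid steps in each condition (0.111-Hz steps on the SL
#' grid, 0.125-Hz steps on the RA grid). The pairs are (RA: 1.25 + k/8,
#' SL: 10/9 + k/9) for k = 0..10; k = 0 is the word-meter pair of primary
#' interest and k = 10 the first harmonics. When spectra are supplied the
#' channel-mean ITC at each pair is extracted.
#'
#' @param specSL,specRA optional [ITCSpectrum-class] objects.
#' @return data.frame with columns `k`, `ra_hz`, `sl_hz`, `label`, and,
#'   when spectra are given, `itc_ra`, `itc_sl`.
#' @export
frequencyPairGrid <- function(specSL = NULL, specRA = NULL) {
  k <- 0:10
  ra <- 1.25 + k * 0.125
  sl <- 10 / 9 + k / 9
  label <- sprintf("RA%.3f-SL%.3f", ra, sl)
  label[1L] <- paste0(label[1L], " (RQ1)")
  label[11L] <- paste0(label[11L], " (1st harmonics)")
  out <- data.frame(k = k, ra_hz = ra, sl_hz = sl, label = label,
                    stringsAsFactors = FALSE)
  if (!is.null(specSL) && !is.null(specRA)) {
    out$itc_sl <- vapply(sl, function(f) specSL@itcAvg[nearestBin(specSL, f)], numeric(1))
    out$itc_ra <- vapply(ra, function(f) specRA@itcAvg[nearestBin(specRA, f)], numeric(1))
  }
  out
}

#' Centre a cohort score vector
#'
#' Subtracts the cross-participant mean (NAs ignored). Centring leaves the
#' rank order, and hence every Kendall statistic, unchanged.
#'
#' @param values numeric vector, one value per participant.
#' @return the centred vector.
#' @export
#' @examples
#' centerScores(c(0.2, 0.4))  # -0.1, 0.1
centerScores <- function(values) {
  stopifnot(sum(!is.na(values)) >= 2)
  values - mean(values, na.rm = TRUE)
}
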