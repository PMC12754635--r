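#' Preprocessing configuration
#'
#' Bundles the cleaning-chain parameters: 0.5-20 Hz order-2 bandpass
#' (12 dB/oct roll-off), 50-Hz notch, Artifact Blocking threshold of
#' +/- 50 microvolts, the outer ring of channels to drop (leaving 21 of
#' the 32), bad channels to interpolate and intervals to excise.
#'
#' @param bandpass numeric(2), bandpass edges in Hz.
#' @param filterOrder filter order (2).
#' @param notchHz mains notch frequency in Hz (50).
#' @param abThreshold Artifact Blocking threshold theta in microvolts (50).
#' @param outerRing channels removed before analysis; default leaves 21.
#' @param badChannels channels to interpolate.
#' @param rejectionLog data.frame with `start_s`, `end_s`, `reason` of
#'   manually rejected intervals.
#' @return a list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(bandpass = c(0.5, 20), filterOrder = 2,
                             notchHz = 50, abThreshold = 50,
                             outerRing = defaultOuterRing(),
                             badChannels = character(0),
                             rejectionLog = data.frame(
                               start_s = numeric(0), end_s = numeric(0),
                               reason = character(0))) {
  stopifnot(bandpass[1L] < bandpass[2L], abThreshold > 0, filterOrder >= 1)
  structure(list(bandpass = bandpass, filterOrder = filterOrder,
                 notchHz = notchHz, abThreshold = abThreshold,
                 outerRing = outerRing, badChannels = badChannels,
                 rejectionLog = rejectionLog),
            class = "PreprocessConfig")
}

appendLog <- function(rec, stage, detail) {
  rec@log <- rbind(rec@log,
                   data.frame(stage = stage, detail = detail,
                              stringsAsFactors = FALSE))
  rec
}

#' Re-reference to the algebraic mastoid average
#'
#' Subtracts (left + right)/2 from every scalp channel and removes the
#' mastoid channels from the analysis set.
#'
#' @param rec an [EEGRecording-class].
#' @param left,right mastoid channel names.
#' @return the re-referenced recording without the mastoid channels.
#' @export
rereferenceMastoids <- function(rec, left = "M1", right = "M2") {
  chn <- rec@channelNames
  if (!left %in% chn || !right %in% chn) {
    stop("missing mastoid channel: need both '", left, "' and '", right, "'")
  }
  ref <- (rec@data[match(left, chn), ] + rec@data[match(right, chn), ]) / 2
  keep <- !chn %in% c(left, right)
  rec@data <- sweep(rec@data[keep, , drop = FALSE], 2, ref, "-")
  rec@channelNames <- chn[keep]
  rownames(rec@data) <- rec@channelNames
  validObject(rec)
  appendLog(rec, "rereference", sprintf("mastoids %s/%s", left, right))
}

#' Bandpass and notch filtering
#'
#' Applies an order-2 Butterworth bandpass (12 dB/oct, 40 dB/dec roll-off
#' per edge) and a narrow Butterworth band-stop around the mains frequency,
#' both zero-phase (forward-backward), so event latencies and the phase
#' structure entering the ITC are preserved. Zero-phase application doubles
#' the effective roll-off; this is accepted and documented.
#'
#' @param rec an [EEGRecording-class].
#' @param cfg a [preprocessConfig()].
#' @return the filtered recording.
#' @export
filterChain <- function(rec, cfg = preprocessConfig()) {
  fs <- rec@sampleRate
  if (fs <= 2 * cfg$bandpass[2L]) {
    stop("sampling rate must exceed twice the bandpass upper edge")
  }
  bp <- signal::butter(cfg$filterOrder, cfg$bandpass / (fs / 2), type = "pass")
  doNotch <- cfg$notchHz < fs / 2
  if (doNotch) {
    nt <- signal::butter(cfg$filterOrder,
                         c(cfg$notchHz - 1, cfg$notchHz + 1) / (fs / 2),
                         type = "stop")
  }
  for (ch in seq_len(nrow(rec@data))) {
    x <- signal::filtfilt(bp, rec@data[ch, ])
    if (doNotch) x <- signal::filtfilt(nt, x)
    if (any(!is.finite(x))) stop("unstable filter design at this sampling rate")
    rec@data[ch, ] <- x
  }
  appendLog(rec, "filter",
            sprintf("bandpass %g-%g Hz order %d%s", cfg$bandpass[1L],
                    cfg$bandpass[2L], cfg$filterOrder,
                    if (doNotch) sprintf(", notch %g Hz", cfg$notchHz) else ""))
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted average of
#' the good channels, using the schematic layout coordinates. At 21-32
#' channels this distance weighting is an adequate stand-in for spherical
#' splines.
#'
#' @param rec an [EEGRecording-class].
#' @param bad character vector of channel names to interpolate.
#' @param power inverse-distance weighting exponent (2).
#' @return the recording with bad channels replaced.
#' @export
interpolateBadChannels <- function(rec, bad, power = 2) {
  if (length(bad) == 0L) return(appendLog(rec, "interpolate", "none"))
  chn <- rec@channelNames
  if (!all(bad %in% chn)) stop("bad channels not present: ",
                               paste(setdiff(bad, chn), collapse = ", "))
  layout <- channelLayout32()
  pos <- layout[match(chn, layout$channel), c("x", "y")]
  if (anyNA(pos)) stop("no layout coordinates for some channels")
  good <- setdiff(chn, bad)
  if (length(good) < 3L) stop("too few good channels to interpolate from")
  for (b in bad) {
    bi <- match(b, chn)
    gi <- match(good, chn)
    d <- sqrt((pos$x[gi] - pos$x[bi])^2 + (pos$y[gi] - pos$y[bi])^2)
    w <- 1 / pmax(d, 1e-6)^power
    w <- w / sum(w)
    rec@data[bi, ] <- as.numeric(w %*% rec@data[gi, , drop = FALSE])
  }
  appendLog(rec, "interpolate", paste(bad, collapse = ", "))
}

#' Artifact Blocking correction
#'
#' Implements the Artifact Blocking method on continuous data: a reference
#' copy of the record is built with every sample exceeding the threshold
#' (in absolute value) suppressed to zero, and the least-squares spatial
#' smoothing matrix B minimizing ||B X - X_ref||^2 is estimated once for
#' the whole record ("total" approach) and applied to it. Because the
#' artifactual excursions are absent from the reference, B reconstructs
#' super-threshold stretches from the spatial correlation with the clean
#' channels, while on artifact-free data X_ref = X and B is the identity.
#'
#' When artifacts are excessive (most of the record exceeds the threshold)
#' the least-squares problem no longer identifies a meaningful smoothing
#' matrix; this is signalled as an error so callers can exclude the
#' record.
#'
#' @param rec an [EEGRecording-class].
#' @param theta blocking threshold in microvolts (50).
#' @param maxBlockedFrac largest tolerable fraction of super-threshold
#'   samples; beyond it the reference record is mostly suppressed and the
#'   least-squares problem no longer identifies a meaningful smoothing
#'   matrix (the excessive-artifact exclusion case).
#' @return the corrected recording.
#' @export
artifactBlock <- function(rec, theta = 50, maxBlockedFrac = 0.5) {
  X <- rec@data
  Xref <- X
  Xref[abs(Xref) > theta] <- 0
  blockedFrac <- mean(abs(X) > theta)
  if (blockedFrac > maxBlockedFrac) {
    stop("Artifact Blocking failed: smoothing matrix could not be estimated ",
         "(", round(100 * blockedFrac), "% of samples exceed the threshold)")
  }
  G <- X %*% t(X)
  # the channel covariance is legitimately rank-deficient after
  # interpolation or average re-referencing, so invert on its numerical
  # row space (SVD pseudoinverse) rather than demanding full rank
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * sv$d[1L]
  pos <- sv$d > tol
  if (!any(pos) || !all(is.finite(sv$d))) {
    stop("Artifact Blocking failed: smoothing matrix could not be estimated ",
         "(degenerate channel covariance)")
  }
  Ginv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  B <- Xref %*% t(X) %*% Ginv
  rec@data <- B %*% X
  rownames(rec@data) <- rec@channelNames
  nBlocked <- sum(abs(X) > theta)
  appendLog(rec, "artifact_block",
            sprintf("theta=%g, %d super-threshold samples", theta, nBlocked))
}

# Merge overlapping [start, end) intervals.
mergeIntervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- nrow(out)
    if (iv$start_s[i] <= out$end_s[j]) {
      out$end_s[j] <- max(out$end_s[j], iv$end_s[i])
      out$reason[j] <- paste(unique(c(out$reason[j], iv$reason[i])), collapse = ";")
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Excise rejected intervals
#'
#' Removes manually rejected intervals (half-open, `[start_s, end_s)`)
#' from the record, merging overlaps. Markers inside an excision are
#' dropped; later markers are shifted so the marker stream stays aligned
#' with the concatenated data. Seam positions are recorded so epoching can
#' skip epochs that would straddle a cut.
#'
#' @param rec an [EEGRecording-class].
#' @param rejectionLog data.frame with `start_s`, `end_s`, `reason`.
#' @return the shortened recording.
#' @export
exciseIntervals <- function(rec, rejectionLog) {
  if (is.null(rejectionLog) || nrow(rejectionLog) == 0L) {
    return(appendLog(rec, "excise", "none"))
  }
  fs <- rec@sampleRate
  n <- ncol(rec@data)
  iv <- mergeIntervals(rejectionLog)
  iv$start_s <- pmax(0, iv$start_s)
  iv$end_s <- pmin(n / fs, iv$end_s)
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(iv))) {
    i0 <- floor(iv$start_s[i] * fs) + 1L
    i1 <- ceiling(iv$end_s[i] * fs)
    keep[i0:min(n, i1)] <- FALSE
  }
  mk <- rec@markers
  if (nrow(mk) > 0L) {
    shift <- numeric(nrow(mk))
    drop <- logical(nrow(mk))
    for (i in seq_len(nrow(iv))) {
      inI <- mk$onset_s >= iv$start_s[i] & mk$onset_s < iv$end_s[i]
      drop <- drop | inI
      after <- mk$onset_s >= iv$end_s[i]
      shift[after] <- shift[after] + (iv$end_s[i] - iv$start_s[i])
    }
    mk <- mk[!drop, , drop = FALSE]
    mk$onset_s <- mk$onset_s - shift[!drop]
    mk$onset_sample <- round(mk$onset_s * fs)
    rownames(mk) <- NULL
  }
  # seam positions in the new time base
  cut <- cumsum(iv$end_s - iv$start_s)
  seams <- iv$start_s - c(0, cut[-length(cut)])
  rec@data <- rec@data[, keep, drop = FALSE]
  rec@markers <- mk
  rec@seams <- sort(unique(c(rec@seams, seams)))
  appendLog(rec, "excise",
            sprintf("%d interval(s), %.3f s removed", nrow(iv), sum(iv$end_s - iv$start_s)))
}

#' Drop the outer ring of channels
#'
#' Removes the peripheral channels before analysis. With the default
#' 32-channel layout and default ring this leaves 21 channels; any other
#' remaining count triggers a warning (not an error).
#'
#' @param rec an [EEGRecording-class].
#' @param ring channel names to remove.
#' @return the reduced recording.
#' @export
dropOuterRing <- function(rec, ring = defaultOuterRing()) {
  chn <- rec@channelNames
  if (!all(ring %in% chn)) {
    ring <- intersect(ring, chn)
  }
  keep <- !chn %in% ring
  rec@data <- rec@data[keep, , drop = FALSE]
  rec@channelNames <- chn[keep]
  rownames(rec@data) <- rec@channelNames
  if (length(chn) == 32L && sum(keep) != 21L) {
    warning("outer-ring removal left ", sum(keep), " channels (expected 21 ",
            "with the default layout)")
  }
  appendLog(rec, "drop_outer_ring",
            sprintf("%d dropped, %d remain", length(ring), sum(keep)))
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: mastoid re-referencing, filtering, bad-channel
#' interpolation, interval excision, Artifact Blocking, outer-ring
#' removal. Every stage appends to the recording's audit log.
#'
#' @param rec an [EEGRecording-class] (with mastoid channels present when
#'   `rereference` is TRUE).
#' @param cfg a [preprocessConfig()].
#' @param rereference apply the mastoid re-reference stage (TRUE).
#' @return the analysis-ready recording.
#' @export
preprocessChain <- function(rec, cfg = preprocessConfig(), rereference = TRUE) {
  if (rereference) rec <- rereferenceMastoids(rec)
  rec <- filterChain(rec, cfg)
  rec <- interpolateBadChannels(rec, cfg$badChannels)
  rec <- exciseIntervals(rec, cfg$rejectionLog)
  rec <- artifactBlock(rec, cfg$abThreshold)
  dropOuterRing(rec, cfg$outerRing)
}
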