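test_that("mastoid re-referencing subtracts the algebraic average", {
  rec <- makeRARecording(seconds = 20, nChannels = 4, includeMastoids = TRUE)
  # zero mastoids: identity on scalp channels
  r0 <- rec
  r0@data[match(c("M1", "M2"), channelNames(r0)), ] <- 0
  out0 <- rereferenceMastoids(r0)
  expect_equal(signalData(out0),
               signalData(r0)[seq_len(4), , drop = FALSE])
  # arithmetic: scalp 5, L 2, R 4 -> 2
  r1 <- rec
  r1@data[] <- 5
  r1@data[match("M1", channelNames(r1)), ] <- 2
  r1@data[match("M2", channelNames(r1)), ] <- 4
  expect_true(all(signalData(rereferenceMastoids(r1)) == 2))
  # algebraic identity: the mastoid pair itself re-references to mean zero
  L <- signalData(rec)[match("M1", channelNames(rec)), ]
  R <- signalData(rec)[match("M2", channelNames(rec)), ]
  ref <- (L + R) / 2
  expect_equal(max(abs((L - ref) + (R - ref))), 0, tolerance = 1e-9)
  expect_error(rereferenceMastoids(out0), "missing mastoid")
})

test_that("the filter chain attenuates mains and drift but passes 3.33 Hz", {
  fs <- 128
  t <- (0:(fs * 30 - 1)) / fs
  mk <- data.frame(onset_s = 0, onset_sample = 0, label = "x", level = "beat")
  wrap <- function(x) new("EEGRecording", data = matrix(x, 1), sampleRate = fs,
                          channelNames = "Cz", markers = mk, condition = "RA")
  s50 <- sin(2 * pi * 50 * t)
  out50 <- signalData(filterChain(wrap(s50)))[1, ]
  expect_lt(sd(out50) / sd(s50), 0.05)
  s33 <- sin(2 * pi * (10 / 3) * t)
  mid <- (fs * 5):(fs * 25)
  out33 <- signalData(filterChain(wrap(s33)))[1, ]
  expect_equal(sd(out33[mid]) / sd(s33[mid]), 1, tolerance = 0.1)
  sdr <- sin(2 * pi * 0.05 * t)
  outdr <- signalData(filterChain(wrap(sdr)))[1, ]
  expect_lt(20 * log10(sd(outdr) / sd(sdr)), -20)
  expect_error(filterChain(wrap(s33), preprocessConfig(bandpass = c(0.5, 70))),
               "sampling rate")
})

test_that("bad-channel interpolation recovers smooth spatial fields", {
  layout <- channelLayout32()
  tc <- sin(2 * pi * (1:500) / 100)
  # spatially smooth field: value depends smoothly on electrode position
  gains <- 1 + 0.8 * layout$x + 0.5 * layout$y + 0.4 * layout$x * layout$y
  X <- outer(gains, tc)
  rec <- new("EEGRecording", data = X, sampleRate = 100,
             channelNames = layout$channel,
             markers = data.frame(onset_s = 0, onset_sample = 0,
                                  label = "x", level = "beat"),
             condition = "RA")
  # identical neighbours reproduce the common signal exactly
  rSame <- rec
  rSame@data <- matrix(rep(tc, each = 32), nrow = 32)
  outSame <- interpolateBadChannels(rSame, "Pz")
  expect_equal(signalData(outSame)[match("Pz", layout$channel), ], tc)
  # no bad channels: identity
  expect_equal(signalData(interpolateBadChannels(rec, character(0))),
               signalData(rec))
  # smooth-field reconstruction correlates > 0.9 with the truth
  truth <- signalData(rec)[match("C3", layout$channel), ]
  rBad <- rec
  rBad@data[match("C3", layout$channel), ] <- rnorm(500) * 10
  out <- interpolateBadChannels(rBad, "C3")
  expect_gt(cor(signalData(out)[match("C3", layout$channel), ], truth), 0.9)
})

test_that("Artifact Blocking is near-identity on clean data and attenuates transients", {
  rec <- makeRARecording(seconds = 60, nChannels = 16, sampleRate = 128,
                         seed = 5)
  clean <- artifactBlock(rec, 50)
  expect_lt(max(abs(signalData(clean) - signalData(rec))) /
              sd(signalData(rec)), 0.01)
  # idempotence on already-clean data
  again <- artifactBlock(clean, 50)
  expect_lt(sd(signalData(again) - signalData(clean)) /
              sd(signalData(clean)), 0.01)
  # a single 400 uV transient is pulled back toward threshold
  rArt <- rec
  idx <- 3000:3080
  rArt@data[3, idx] <- rArt@data[3, idx] +
    400 * 0.5 * (1 - cos(2 * pi * (seq_along(idx) - 1) / (length(idx) - 1)))
  fixed <- artifactBlock(rArt, 50)
  expect_lte(max(abs(signalData(fixed)[3, idx])), 50 * 1.5)
  cleanIdx <- setdiff(seq_len(ncol(signalData(rArt))), idx)
  expect_lt(abs(sd(signalData(fixed)[, cleanIdx]) -
                  sd(signalData(rArt)[, cleanIdx])) /
              sd(signalData(rArt)[, cleanIdx]), 0.1)
  # near-total saturation: smoothing matrix inestimable
  rSat <- rec
  rSat@data[, seq_len(round(0.9 * ncol(rSat@data)))] <- 500
  expect_error(artifactBlock(rSat, 50), "could not be estimated")
})

test_that("interval excision reshapes data, markers and seams consistently", {
  rec <- makeRARecording(seconds = 60, nChannels = 4)
  expect_equal(signalData(exciseIntervals(rec, NULL)), signalData(rec))
  out <- exciseIntervals(rec, data.frame(start_s = 20, end_s = 30,
                                         reason = "movement"))
  expect_equal(ncol(signalData(out)) / sampleRate(out), 50)
  mkIn <- markers(rec); mkOut <- markers(out)
  expect_equal(nrow(mkOut), sum(mkIn$onset_s < 20 | mkIn$onset_s >= 30))
  # markers after the cut are shifted by its length
  expect_equal(mkOut$onset_s[mkOut$onset_s >= 20][1L],
               mkIn$onset_s[mkIn$onset_s >= 30][1L] - 10)
  expect_equal(out@seams, 20)
  # overlapping intervals merge rather than error
  out2 <- exciseIntervals(rec, data.frame(start_s = c(10, 12),
                                          end_s = c(14, 18),
                                          reason = c("a", "b")))
  expect_equal(ncol(signalData(out2)) / sampleRate(out2), 52)
  # a marker inside the excision is dropped
  expect_false(any(mkOut$onset_s >= 20 & mkOut$onset_s < 30 &
                     mkOut$onset_s + 1e-9 < 20))
})

test_that("outer-ring removal leaves 21 channels on the default layout", {
  tl <- truncateTimeline(buildRAStream(), 10)
  rec <- simulateEEG(tl, entrainSpec(), noiseSpec(), nChannels = 32,
                     sampleRate = 64, seed = 2, includeMastoids = FALSE)
  out <- dropOuterRing(rec)
  expect_equal(length(channelNames(out)), 21L)
  expect_false(any(defaultOuterRing() %in% channelNames(out)))
  small <- makeRARecording(seconds = 10, nChannels = 4)
  expect_equal(channelNames(dropOuterRing(small, character(0))),
               channelNames(small))
  expect_warning(dropOuterRing(rec, c("Fp1", "Fp2")), "expected 21")
})

test_that("the full chain runs in order and logs every stage", {
  rec <- makeRARecording(seconds = 130, nChannels = 32, sampleRate = 128,
                         seed = 8, includeMastoids = TRUE)
  out <- preprocessChain(rec, preprocessConfig(
    badChannels = "Pz",
    rejectionLog = data.frame(start_s = 5, end_s = 7, reason = "fuss")))
  expect_equal(length(channelNames(out)), 21L)
  expect_equal(processingLog(out)$stage,
               c("simulate", "rereference", "filter", "interpolate",
                 "excise", "artifact_block", "drop_outer_ring"))
  expect_equal(sampleRate(out), sampleRate(rec))
})
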