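test_that("epoch counts match full and minimum exposures", {
  recRA <- makeRARecording(seconds = 480, sampleRate = 64, nChannels = 2,
                           pink = 3, seed = 21)
  expect_equal(nEpochs(epochize(recRA)), 60L)
  recMin <- makeRARecording(seconds = 120, sampleRate = 64, nChannels = 2,
                            pink = 3, seed = 22)
  expect_equal(nEpochs(epochize(recMin)), 15L)
  # SL: full stream -> 60 nine-second epochs, minimum exposure -> 15
  tlSL <- buildSLStream(seed = 23)
  recSL <- simulateEEG(tlSL, entrainSpec(), noiseSpec(pinkAmplitude = 3),
                       nChannels = 2, sampleRate = 64, seed = 23,
                       includeMastoids = FALSE)
  expect_equal(nEpochs(epochize(recSL)), 60L)
  recSLmin <- simulateEEG(truncateTimeline(tlSL, 135), entrainSpec(),
                          noiseSpec(pinkAmplitude = 3), nChannels = 2,
                          sampleRate = 64, seed = 24,
                          includeMastoids = FALSE)
  expect_equal(nEpochs(epochize(recSLmin)), 15L)
  # below minimum exposure: excluded with a typed condition
  recShort <- simulateEEG(truncateTimeline(tlSL, 100), entrainSpec(),
                          noiseSpec(pinkAmplitude = 3), nChannels = 2,
                          sampleRate = 64, seed = 25,
                          includeMastoids = FALSE)
  expect_error(epochize(recShort), class = "exposureError")
})

test_that("epochs skip excision seams, matching a brute-force enumeration", {
  rec <- makeRARecording(seconds = 480, sampleRate = 64, nChannels = 2,
                         pink = 3, seed = 26)
  rx <- exciseIntervals(rec, data.frame(start_s = 101, end_s = 110,
                                        reason = "t"))
  got <- nEpochs(epochize(rx))
  fs <- sampleRate(rx)
  first <- markers(rx)$onset_s[1L]
  starts <- seq(first, ncol(signalData(rx)) / fs - 8, by = 8)
  oracle <- sum(vapply(starts, function(s) {
    !any(rx@seams > s & rx@seams < s + 8)
  }, logical(1)))
  expect_equal(got, oracle)
})

test_that("ITC equals 1 for identical epochs and 0 for antiphase pairs", {
  ns <- 64 * 8
  t <- (0:(ns - 1)) / 64
  onEpoch <- sin(2 * pi * 1.25 * t) + 0.3 * sin(2 * pi * 5 * t)
  ep <- array(rep(onEpoch, each = 6), dim = c(6, 1, ns))
  for (e in 1:6) ep[e, 1, ] <- onEpoch
  es <- new("EpochSet", epochs = ep, epochLength = 8, sampleRate = 64,
            channelNames = "Cz", condition = "RA", alignment = "beat")
  sp <- itcSpectrum(es)
  bins <- which(abs(outer(sp@frequencies, c(1.25, 5), "-")) < 1e-9,
                arr.ind = TRUE)[, 1L]
  expect_equal(unname(sp@itc[1L, bins]), c(1, 1), tolerance = 1e-9)
  # alternating 0 / pi phases cancel exactly at that bin
  ep2 <- ep
  for (e in 1:6) ep2[e, 1, ] <- sin(2 * pi * 1.25 * t + ifelse(e %% 2, 0, pi))
  sp2 <- itcSpectrum(new("EpochSet", epochs = ep2, epochLength = 8,
                         sampleRate = 64, channelNames = "Cz",
                         condition = "RA", alignment = "beat"))
  b125 <- which(abs(sp2@frequencies - 1.25) < 1e-9)
  expect_lt(sp2@itc[1L, b125], 1e-9)
})

test_that("ITC is a phase-only statistic with the documented bounds", {
  rec <- makeRARecording(seconds = 160, seed = 27)
  ep <- epochize(rec)
  sp <- itcSpectrum(ep)
  expect_true(all(sp@itc >= 0 & sp@itc <= 1))
  expect_true(all(sp@itcAvg <= apply(sp@itc, 2, max) + 1e-12))
  expect_equal(sp@binWidth, 0.125)
  expect_true(all(sp@frequencies >= 0.6 & sp@frequencies <= 10))
  # per-epoch amplitude rescaling leaves ITC unchanged
  ep2 <- ep
  sc <- runif(nEpochs(ep), 0.2, 5)
  for (e in seq_len(nEpochs(ep))) ep2@epochs[e, , ] <- sc[e] * ep@epochs[e, , ]
  expect_equal(itcSpectrum(ep2)@itc, sp@itc, tolerance = 1e-9)
})

test_that("measured ITC tracks the von Mises expectation", {
  # kappa = 2 component at 1.25 Hz, N = 60: within 3 SE of the expectation
  tl <- buildRAStream()
  rec <- simulateEEG(tl, entrainSpec(frequency = 1.25, amplitude = 4,
                                     kappa = 2),
                     noiseSpec(pinkAmplitude = 0, lineAmplitude = 0),
                     nChannels = 4, sampleRate = 64, seed = 28,
                     includeMastoids = FALSE)
  sp <- itcSpectrum(epochize(rec))
  exp60 <- expectedITC(2, 60, nsim = 3000)
  meas <- sp@itcAvg[which.min(abs(sp@frequencies - 1.25))]
  expect_lt(abs(meas - as.numeric(exp60)), 3 * attr(exp60, "sd"))
})

test_that("index extraction lands exactly on the frequencies of interest", {
  recRA <- makeRARecording(seconds = 160, seed = 29)
  spRA <- itcSpectrum(epochize(recRA))
  tlSL <- truncateTimeline(buildSLStream(seed = 30), 135)
  recSL <- simulateEEG(tlSL, entrainSpec(frequency = c(10 / 9, 30 / 9),
                                         amplitude = c(4, 8),
                                         kappa = c(3, 3)),
                       noiseSpec(pinkAmplitude = 5), nChannels = 8,
                       sampleRate = 64, seed = 30, includeMastoids = FALSE)
  spSL <- itcSpectrum(epochize(recSL))
  expect_equal(spSL@binWidth, 1 / 9)
  expect_true(any(abs(spSL@frequencies - 10 / 9) < 1e-9))
  expect_true(any(abs(spRA@frequencies - 1.25) < 1e-9))
  expect_true(any(abs(spRA@frequencies - 5) < 1e-9))
  idx <- extractIndices(spSL, spRA)
  expect_named(idx, c("itc_word", "itc_syll", "itc_meter", "itc_beat",
                      "n_epochs_sl", "n_epochs_ra"))
  expect_true(all(idx[1, 1:4] >= 0 & idx[1, 1:4] <= 1))
  # a target outside the retained grid is further than half a bin away
  expect_error(entrainKit:::nearestBin(spRA, 10.4), "not representable")
})

test_that("the frequency-pair grid spans word/meter to the first harmonics", {
  g <- frequencyPairGrid()
  expect_equal(nrow(g), 11L)
  expect_equal(g$ra_hz[1L], 1.25)
  expect_equal(g$sl_hz[1L], 10 / 9, tolerance = 1e-12)
  expect_equal(g$ra_hz[11L], 2.5)
  expect_equal(g$sl_hz[11L], 20 / 9, tolerance = 1e-12)
  expect_match(g$label[1L], "RQ1")
  expect_match(g$label[11L], "harmonics")
})

test_that("centring shifts means without touching rank statistics", {
  expect_equal(centerScores(c(0.2, 0.4)), c(-0.1, 0.1))
  expect_equal(centerScores(rep(3, 5)), rep(0, 5))
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(kendallTauB(centerScores(x), y), kendallTauB(x, y))
})

test_that("pure-noise cohorts sit at the ITC chance level", {
  # mean ITC over channels/bins under no phase locking ~ sqrt(pi/(4N))
  tl <- truncateTimeline(buildRAStream(), 160)
  rec <- simulateEEG(tl, entrainSpec(), noiseSpec(pinkAmplitude = 10,
                                                  lineAmplitude = 0),
                     nChannels = 8, sampleRate = 64, seed = 32,
                     includeMastoids = FALSE)
  sp <- itcSpectrum(epochize(rec))
  N <- nEpochs(sp)
  chance <- sqrt(pi / (4 * N))
  expect_equal(mean(sp@itc), chance, tolerance = 0.15)
})
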