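test_that("SL stream has exact word counts, durations and no adjacent repeats", {
  tl <- buildSLStream(seed = 3)
  ev <- events(tl)
  expect_equal(nrow(ev), 1800L)
  expect_equal(tl@totalDuration, 540)
  expect_true(all(ev$duration_s == 0.3))
  # word-count conservation: 75 reps x 2 blocks each
  wordIdx <- ev$word[ev$position == 1L]
  expect_equal(unname(as.vector(table(wordIdx))), rep(150L, 4L))
  # no adjacent repeats anywhere, including the block seam
  expect_false(any(wordIdx[-1L] == wordIdx[-length(wordIdx)]))
  # event grid implies the stimulus rates: 3.333 Hz syllables, 1.111 Hz words
  expect_equal(1 / ev$duration_s[1L], 10 / 3)
  onsetsW <- ev$onset_s[ev$position == 1L]
  expect_equal(unique(round(diff(onsetsW), 9)), 0.9)
})

test_that("small SL streams satisfy the constraint exhaustively and errors fire", {
  tl <- buildSLStream(repsPerWordPerBlock = 5, nBlocks = 1, seed = 11)
  w <- events(tl)$word[events(tl)$position == 1L]
  expect_length(w, 20L)
  expect_equal(unname(as.vector(table(w))), rep(5L, 4L))
  for (i in seq_len(length(w) - 1L)) expect_true(w[i] != w[i + 1L])
  oneWord <- new("Lexicon", words = list(c("a", "b", "c")),
                 syllableDuration = 0.3, consonantDuration = 0.1,
                 vowelDuration = 0.2)
  expect_error(buildSLStream(oneWord, repsPerWordPerBlock = 2, nBlocks = 1),
               "unsatisfiable|at least 2")
})

test_that("no-adjacent-repeat property holds across many seeds", {
  for (s in 1:100) {
    w <- events(buildSLStream(repsPerWordPerBlock = 8, nBlocks = 2,
                              seed = s))$word
    w <- w[seq(1, length(w), by = 3)]
    expect_false(any(w[-1L] == w[-length(w)]))
  }
})

test_that("RA stream bookkeeping matches the pattern structure", {
  tl <- buildRAStream()
  ev <- events(tl)
  expect_equal(nrow(ev), 2400L)
  expect_equal(tl@totalDuration, 480)
  expect_equal(sum(ev$level == "beat"), 1600L)   # 8 of 12 slots per pattern
  one <- buildRAStream(nPatternRepeats = 1)
  expect_equal(nrow(events(one)), 12L)
  expect_equal(one@totalDuration, 2.4)
  ten <- events(buildRAStream(nPatternRepeats = 10))
  expect_equal(sum(ten$level == "beat"), 80L)
  expect_equal(sum(ten$level == "rest"), 40L)
  # beat grid 5 Hz, meter 1.25 Hz from the event grid itself
  expect_equal(unique(round(diff(ev$onset_s), 9)), 0.2)
  measureOnsets <- ev$onset_s[seq(1, nrow(ev), by = 4L)]
  expect_equal(unique(round(diff(measureOnsets), 9)), 0.8)
})

test_that("transitional probabilities are 1.0 within words, ~1/3 at boundaries", {
  lex <- defaultLexicon()
  tl <- buildSLStream(seed = 5)
  tp <- transitionMatrix(tl, lex)
  expect_true(all(abs(rowSums(tp) - 1) < 1e-12))
  for (w in lex@words) {
    expect_equal(tp[w[1L], w[2L]], 1.0)
    expect_equal(tp[w[2L], w[3L]], 1.0)
  }
  # between-word transitions: ~1/3 to each OTHER word's initial syllable
  # (a word never follows itself in the no-repeat design)
  finals <- vapply(lex@words, function(w) w[3L], character(1))
  initials <- vapply(lex@words, function(w) w[1L], character(1))
  for (wi in seq_along(finals)) for (wj in seq_along(initials)) {
    if (wi == wj) {
      expect_equal(tp[finals[wi], initials[wj]], 0)
    } else {
      expect_lt(abs(tp[finals[wi], initials[wj]] - 1 / 3), 0.05)
    }
  }
  # degenerate stream from a single repeated word: all TPs 1 (incl. wrap)
  ev <- data.frame(onset_s = (0:8) * 0.3, duration_s = 0.3,
                   label = rep(c("a", "b", "c"), 3),
                   level = "syllable", stringsAsFactors = FALSE)
  tl1 <- new("EventTimeline", events = ev, condition = "SL", fade = 1.5,
             totalDuration = 2.7)
  lex1 <- new("Lexicon", words = list(c("a", "b", "c")),
              syllableDuration = 0.3, consonantDuration = 0.1,
              vowelDuration = 0.2)
  tp1 <- transitionMatrix(tl1, lex1)
  expect_true(all(tp1 %in% c(0, 1)))
  expect_true(all(abs(rowSums(tp1) - 1) < 1e-12))
  # unknown label signals corruption
  evBad <- ev; evBad$label[2L] <- "zz"
  tlBad <- new("EventTimeline", events = evBad, condition = "SL",
               fade = 1.5, totalDuration = 2.7)
  expect_error(transitionMatrix(tlBad, lex1), "corrupted")
})

test_that("rendered audio has the right bursts, fades and markers", {
  one <- buildRAStream(nPatternRepeats = 1)
  au <- renderAudio(one, 44100)
  expect_equal(nrow(au$markers), 12L)
  # 8 non-silent 200-ms bursts, silence in the rest slots
  ev <- events(one)
  for (i in seq_len(12L)) {
    i0 <- round(ev$onset_s[i] * 44100)
    seg <- au$wave[(i0 + 1):(i0 + 0.2 * 44100)]
    if (ev$level[i] == "beat") expect_gt(max(abs(seg)), 0.5)
    else expect_equal(max(abs(seg)), 0)
  }
  # fade: zero at t=0, untouched right after the fade window
  three <- buildRAStream(nPatternRepeats = 3)  # 7.2 s > 2 x 1.5 s fade
  auF <- renderAudio(three, 8000)
  expect_equal(auF$wave[1L], 0)
  nf <- round(1.5 * 8000)
  noFade <- three; noFade@fade <- 0
  au0 <- renderAudio(noFade, 8000)
  expect_equal(auF$wave[(nf + 1):(nf + 100)], au0$wave[(nf + 1):(nf + 100)],
               tolerance = 1e-3)
  expect_equal(nrow(auF$markers), nrow(events(three)))
  # WAV writer round-trips the sample count
  tmp <- tempfile(fileext = ".wav")
  writeWavPcm(au$wave, 44100, tmp)
  expect_equal(file.size(tmp), 44 + 2 * length(au$wave))
  unlink(tmp)
})
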