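#' Default pseudoword lexicon
#'
#' Four trisyllabic pseudowords (ASCII transliterations of the original
#' Dutch-phonotactics items) with 300-ms syllables (100 ms consonant,
#' 200 ms vowel). All twelve syllables are unique, so transitional
#' probabilities are 1.0 within words by construction.
#'
#' @return a [Lexicon-class] object.
#' @export
#' @examples
#' defaultLexicon()
defaultLexicon <- function() {
  new("Lexicon",
      words = list(
        c("su", "xi", "ta"),
        c("to", "ba", "moe"),
        c("sy", "toe", "bo"),
        c("xoe", "by", "ti")
      ),
      syllableDuration = 0.300,
      consonantDuration = 0.100,
      vowelDuration = 0.200)
}

#' Default syncopated rhythm pattern
#'
#' Three measures of four 200-ms counts in quadruple meter: measure one
#' plays all four tones, measure two omits the first tone, measure three
#' plays only the third count. Tones are 130-Hz bursts with a 10-ms rise
#' and 50-ms fall. The pattern lasts 2.4 s; the 5-Hz beat grid and the
#' 1.25-Hz meter arise from the 200-ms count and 800-ms measure periods.
#'
#' @return a [RhythmPattern-class] object.
#' @export
#' @examples
#' defaultRhythmPattern()
defaultRhythmPattern <- function() {
  new("RhythmPattern",
      slots = c(TRUE, TRUE, TRUE, TRUE,
                FALSE, TRUE, TRUE, TRUE,
                FALSE, FALSE, TRUE, FALSE),
      eventDuration = 0.200,
      toneHz = 130,
      riseTime = 0.010,
      fallTime = 0.050)
}

# Pseudorandomize one block's word multiset with no adjacent repeats,
# including against the final word of the preceding block. Words are drawn
# sequentially with probability proportional to their remaining counts
# (excluding the previous word); when one word's remaining count exceeds
# half the remaining slots it must be placed to keep the sequence
# completable. Dead ends are retried up to maxAttempts times. (A plain
# accept-reject over uniform shuffles is hopeless at the default block
# size: the no-repeat probability of a random 300-word shuffle is ~e^-75.)
shuffleNoRepeat <- function(pool, prevLast, maxAttempts) {
  if (length(unique(pool)) == 1L && length(pool) > 1L) {
    stop("adjacency constraint unsatisfiable: a single word cannot repeat ",
         "without adjacent duplicates")
  }
  counts <- table(pool)
  words <- as.integer(names(counts))
  for (a in seq_len(maxAttempts)) {
    cnt <- as.integer(counts)
    seqOut <- integer(length(pool))
    prev <- prevLast
    ok <- TRUE
    for (pos in seq_along(pool)) {
      remaining <- sum(cnt)
      allowed <- which(cnt > 0L & (if (is.null(prev)) TRUE else words != prev))
      if (length(allowed) == 0L) { ok <- FALSE; break }
      forced <- allowed[cnt[allowed] > (remaining + 1L) %/% 2L]
      pick <- if (length(forced) > 0L) {
        forced[1L]
      } else if (length(allowed) == 1L) {
        allowed
      } else {
        sample(allowed, 1L, prob = cnt[allowed])
      }
      seqOut[pos] <- words[pick]
      cnt[pick] <- cnt[pick] - 1L
      prev <- words[pick]
    }
    if (ok) return(seqOut)
  }
  stop("could not place words without adjacent repeats within ",
       maxAttempts, " attempts; configuration is invalid")
}

#' Build the statistical-learning speech-stream timeline
#'
#' Concatenates pseudorandomized word orders into a continuous stream of
#' syllable events. Per block, every word occurs exactly
#' `repsPerWordPerBlock` times and no word immediately repeats, with the
#' no-repeat constraint enforced across the block seam as well (the blocks
#' are presented as one seamless stream). Word order is pseudorandomized
#' by sequential draws proportional to the words' remaining counts, with a
#' completability rule forcing a word whose remaining count exceeds half
#' the remaining slots; dead ends are retried, bounded at `maxAttempts`
#' per block.
#'
#' With the defaults (4 words x 75 repetitions x 2 blocks of 4.5 min) the
#' stream contains 600 words / 1800 syllable events over 540 s, giving a
#' 3.333-Hz syllable rate and 1.111-Hz word rate.
#'
#' @param lexicon a [Lexicon-class]; defaults to [defaultLexicon()].
#' @param repsPerWordPerBlock repetitions of each word per block (75).
#' @param nBlocks number of blocks (2).
#' @param seed optional integer seed for the word-order shuffles.
#' @param maxAttempts shuffle bound before signalling an invalid
#'   configuration (10000).
#' @return an [EventTimeline-class] with one event per syllable.
#' @export
#' @examples
#' tl <- buildSLStream(repsPerWordPerBlock = 5, nBlocks = 1, seed = 1)
#' nrow(events(tl))  # 4 words x 5 reps x 3 syllables = 60
buildSLStream <- function(lexicon = defaultLexicon(),
                          repsPerWordPerBlock = 75,
                          nBlocks = 2,
                          seed = NULL,
                          maxAttempts = 10000) {
  stopifnot(repsPerWordPerBlock >= 1, nBlocks >= 1)
  if (length(lexicon@words) < 2L && repsPerWordPerBlock * nBlocks > 1L) {
    stop("adjacency constraint unsatisfiable: need at least 2 distinct words")
  }
  if (!is.null(seed)) set.seed(seed)
  nw <- length(lexicon@words)
  wordSeq <- integer(0)
  prevLast <- NULL
  for (b in seq_len(nBlocks)) {
    pool <- rep(seq_len(nw), repsPerWordPerBlock)
    blockSeq <- shuffleNoRepeat(pool, prevLast, maxAttempts)
    wordSeq <- c(wordSeq, blockSeq)
    prevLast <- blockSeq[length(blockSeq)]
  }
  wlen <- length(lexicon@words[[1L]])
  sylls <- unlist(lexicon@words[as.integer(wordSeq)])
  nEv <- length(sylls)
  dur <- lexicon@syllableDuration
  ev <- data.frame(
    onset_s = (seq_len(nEv) - 1L) * dur,
    duration_s = rep(dur, nEv),
    label = sylls,
    level = rep("syllable", nEv),
    word = rep(as.integer(wordSeq), each = wlen),
    position = rep(seq_len(wlen), times = length(wordSeq)),
    stringsAsFactors = FALSE
  )
  new("EventTimeline", events = ev, condition = "SL",
      fade = 1.5, totalDuration = nEv * dur)
}

#' Build the rhythmic-ability timeline
#'
#' Repeats the twelve-slot syncopated pattern `nPatternRepeats` times,
#' emitting one event per 200-ms count -- including silent periods, so a
#' marker exists for every beat-grid position. The defaults (200 repeats)
#' give 2400 events over 480 s: a 5-Hz beat grid and 1.25-Hz meter.
#'
#' @param pattern a [RhythmPattern-class]; defaults to
#'   [defaultRhythmPattern()].
#' @param nPatternRepeats number of pattern repetitions (200).
#' @return an [EventTimeline-class] with one event per count.
#' @export
#' @examples
#' tl <- buildRAStream(nPatternRepeats = 1)
#' events(tl)$level  # 8 beats, 4 rests
buildRAStream <- function(pattern = defaultRhythmPattern(),
                          nPatternRepeats = 200) {
  stopifnot(nPatternRepeats >= 1)
  slots <- rep(pattern@slots, nPatternRepeats)
  nEv <- length(slots)
  dur <- pattern@eventDuration
  ev <- data.frame(
    onset_s = (seq_len(nEv) - 1L) * dur,
    duration_s = rep(dur, nEv),
    label = ifelse(slots, "tone", "rest"),
    level = ifelse(slots, "beat", "rest"),
    stringsAsFactors = FALSE
  )
  new("EventTimeline", events = ev, condition = "RA",
      fade = 1.5, totalDuration = nEv * dur)
}

#' Syllable-level transitional-probability table
#'
#' Estimates P(next syllable | current syllable) over every attested bigram
#' of an SL timeline. In the no-repeat design, transitions are 1.0 within
#' words and approximately 1/3 from a word-final syllable to each of the
#' other words' initial syllables.
#'
#' @param timeline an SL [EventTimeline-class].
#' @param lexicon the [Lexicon-class] the stream was built from.
#' @return a row-stochastic matrix of transitional probabilities, rows =
#'   current syllable, columns = next syllable.
#' @export
#' @examples
#' tl <- buildSLStream(repsPerWordPerBlock = 5, nBlocks = 1, seed = 1)
#' tp <- transitionMatrix(tl, defaultLexicon())
#' all(rowSums(tp) == 1)
transitionMatrix <- function(timeline, lexicon = defaultLexicon()) {
  ev <- timeline@events
  known <- unlist(lexicon@words)
  if (!all(ev$label %in% known)) {
    stop("timeline contains syllable labels not in the lexicon: corrupted timeline")
  }
  labs <- ev$label
  cur <- factor(labs[-length(labs)], levels = known)
  nxt <- factor(labs[-1L], levels = known)
  counts <- table(cur, nxt)
  attested <- rowSums(counts) > 0
  tp <- sweep(counts[attested, , drop = FALSE], 1,
              rowSums(counts[attested, , drop = FALSE]), "/")
  m <- as.matrix(unclass(tp))
  names(dimnames(m)) <- NULL
  m
}

# Linear rise/fall envelope for a tone burst of n samples.
burstEnvelope <- function(n, sr, rise, fall) {
  env <- rep(1, n)
  nr <- round(rise * sr)
  nf <- round(fall * sr)
  if (nr > 0L) env[seq_len(nr)] <- seq(0, 1, length.out = nr)
  if (nf > 0L) env[(n - nf + 1L):n] <- seq(1, 0, length.out = nf)
  env
}

#' Render an event timeline to audio
#'
#' RA tones are rendered as 130-Hz sinusoid bursts with the pattern's
#' linear rise/fall ramps; rests are silence. SL syllables are rendered as
#' placeholder tone tokens, one distinguishable carrier frequency per
#' syllable label (speech synthesis is out of scope: the analysis consumes
#' event timelines, not audio content). A global linear fade-in and
#' fade-out of the timeline's fade duration (1.5 s) is applied; markers
#' are kept during the fades.
#'
#' @param timeline an [EventTimeline-class].
#' @param sampleRate audio sampling rate in Hz (default 44100).
#' @return list with `wave` (numeric vector in `[-1, 1]`), `sampleRate`,
#'   and `markers` (data.frame with `onset_s`, `onset_sample` 0-based,
#'   `duration_s`, `label`, `level`).
#' @export
renderAudio <- function(timeline, sampleRate = 44100) {
  ev <- timeline@events
  maxHz <- if (timeline@condition == "RA") defaultRhythmPattern()@toneHz else 880
  if (sampleRate < 2 * maxHz) stop("sampleRate below Nyquist for rendered tones")
  n <- round(timeline@totalDuration * sampleRate)
  wave <- numeric(n)
  if (timeline@condition == "RA") {
    pat <- defaultRhythmPattern()
    for (i in which(ev$level == "beat")) {
      i0 <- round(ev$onset_s[i] * sampleRate)
      len <- round(ev$duration_s[i] * sampleRate)
      t <- (seq_len(len) - 1L) / sampleRate
      burst <- sin(2 * pi * pat@toneHz * t) *
        burstEnvelope(len, sampleRate, pat@riseTime, pat@fallTime)
      wave[i0 + seq_len(len)] <- burst
    }
  } else {
    labs <- unique(ev$label)
    freqs <- 220 * 2^((seq_along(labs) - 1L) / 12)
    names(freqs) <- labs
    for (i in seq_len(nrow(ev))) {
      i0 <- round(ev$onset_s[i] * sampleRate)
      len <- round(ev$duration_s[i] * sampleRate)
      t <- (seq_len(len) - 1L) / sampleRate
      burst <- sin(2 * pi * freqs[[ev$label[i]]] * t) *
        burstEnvelope(len, sampleRate, 0.010, 0.010)
      wave[i0 + seq_len(len)] <- burst
    }
  }
  nf <- round(timeline@fade * sampleRate)
  if (nf > 0L && n >= 2L * nf) {
    wave[seq_len(nf)] <- wave[seq_len(nf)] * seq(0, 1, length.out = nf + 1L)[-(nf + 1L)]
    wave[(n - nf + 1L):n] <- wave[(n - nf + 1L):n] * rev(seq(0, 1, length.out = nf + 1L)[-(nf + 1L)])
  }
  mk <- data.frame(
    onset_s = ev$onset_s,
    onset_sample = round(ev$onset_s * sampleRate),
    duration_s = ev$duration_s,
    label = ev$label,
    level = ev$level,
    stringsAsFactors = FALSE
  )
  list(wave = wave, sampleRate = sampleRate, markers = mk)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer for the rendered stimuli; samples are clipped
#' to `[-1, 1]` and scaled to 16-bit integers.
#'
#' @param wave numeric vector in `[-1, 1]`.
#' @param sampleRate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWavPcm <- function(wave, sampleRate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  dataSize <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write a marker sidecar as JSON
#'
#' @param markers data.frame as produced by [renderAudio()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMarkerSidecar <- function(markers, path) {
  jsonlite::write_json(list(events = markers), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
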