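#' @import methods
NULL

#' Lexicon of trisyllabic pseudowords
#'
#' Holds the pseudoword inventory of the statistical-learning (SL) speech
#' stream together with the syllable timing. The default lexicon contains
#' four trisyllabic pseudowords whose twelve syllables are unique across
#' lexicon positions, so every syllable label identifies its word and its
#' within-word position unambiguously.
#'
#' @slot words list of character vectors; each element is one word given as
#'   its ordered syllable labels.
#' @slot syllableDuration numeric, syllable duration in seconds (0.300).
#' @slot consonantDuration numeric, consonant portion in seconds (0.100).
#' @slot vowelDuration numeric, vowel portion in seconds (0.200).
#' @name Lexicon-class
#' @aliases Lexicon-class
#' @exportClass Lexicon
setClass("Lexicon",
  representation(
    words = "list",
    syllableDuration = "numeric",
    consonantDuration = "numeric",
    vowelDuration = "numeric"
  )
)

setValidity("Lexicon", function(object) {
  msgs <- character()
  lens <- lengths(object@words)
  if (length(object@words) < 1L) msgs <- c(msgs, "lexicon must contain at least one word")
  if (length(unique(lens)) > 1L) msgs <- c(msgs, "all words must have the same number of syllables")
  sylls <- unlist(object@words)
  if (anyDuplicated(sylls)) msgs <- c(msgs, "syllable labels must be unique across the lexicon")
  if (object@syllableDuration <= 0 || object@consonantDuration <= 0 ||
      object@vowelDuration <= 0) {
    msgs <- c(msgs, "durations must be positive")
  }
  if (abs(object@consonantDuration + object@vowelDuration -
          object@syllableDuration) > 1e-9) {
    msgs <- c(msgs, "consonant + vowel duration must equal the syllable duration")
  }
  if (length(msgs)) msgs else TRUE
})

#' Syncopated rhythm pattern
#'
#' The twelve-slot rhythmic pattern of the rhythmic-ability (RA) condition:
#' three measures of four 200-ms counts each (quadruple meter). Slots are
#' TRUE for a played tone and FALSE for a silent period; the default pattern
#' plays all four tones of measure one, omits the first tone of measure two,
#' and plays only the third count of measure three (8 tones, 4 rests,
#' 2.4 s per pattern).
#'
#' @slot slots logical(12); tone (TRUE) or rest (FALSE) per 200-ms count.
#' @slot eventDuration numeric, slot duration in seconds (0.200).
#' @slot toneHz numeric, carrier frequency of the tone in Hz (130).
#' @slot riseTime numeric, linear onset ramp in seconds (0.010).
#' @slot fallTime numeric, linear offset ramp in seconds (0.050).
#' @name RhythmPattern-class
#' @aliases RhythmPattern-class
#' @exportClass RhythmPattern
setClass("RhythmPattern",
  representation(
    slots = "logical",
    eventDuration = "numeric",
    toneHz = "numeric",
    riseTime = "numeric",
    fallTime = "numeric"
  )
)

setValidity("RhythmPattern", function(object) {
  msgs <- character()
  if (length(object@slots) != 12L) msgs <- c(msgs, "pattern must have exactly 12 slots")
  if (object@eventDuration <= 0) msgs <- c(msgs, "eventDuration must be positive")
  if (object@toneHz <= 0) msgs <- c(msgs, "toneHz must be positive")
  if (object@riseTime < 0 || object@fallTime < 0) msgs <- c(msgs, "ramp times must be non-negative")
  if (object@riseTime + object@fallTime > object@eventDuration) {
    msgs <- c(msgs, "ramps must fit within the event duration")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ordered stimulus event timeline
#'
#' The marker stream shared by audio rendering and EEG epoching: an ordered,
#' contiguous sequence of stimulus events. For the SL condition every event
#' is a 300-ms syllable; for the RA condition every 200-ms count is an
#' event, including silent periods, so markers exist for every slot.
#'
#' @slot events data.frame with columns `onset_s`, `duration_s`, `label`,
#'   `level` (one of "syllable", "beat", "rest") and, for SL timelines,
#'   `word` and `position`.
#' @slot condition character, "SL" or "RA".
#' @slot fade numeric, linear fade-in/out applied to rendered audio (s).
#' @slot totalDuration numeric, total stream duration in seconds.
#' @name EventTimeline-class
#' @aliases EventTimeline-class
#' @exportClass EventTimeline
setClass("EventTimeline",
  representation(
    events = "data.frame",
    condition = "character",
    fade = "numeric",
    totalDuration = "numeric"
  )
)

setValidity("EventTimeline", function(object) {
  ev <- object@events
  msgs <- character()
  needed <- c("onset_s", "duration_s", "label", "level")
  if (!all(needed %in% names(ev))) {
    return(paste("events must have columns", paste(needed, collapse = ", ")))
  }
  if (nrow(ev) > 0L) {
    if (is.unsorted(ev$onset_s, strictly = TRUE)) msgs <- c(msgs, "onsets must be strictly increasing")
    gaps <- ev$onset_s[-1L] - (ev$onset_s[-nrow(ev)] + ev$duration_s[-nrow(ev)])
    if (any(abs(gaps) > 1e-9)) msgs <- c(msgs, "events must be contiguous (next onset = previous onset + duration)")
    if (abs(sum(ev$duration_s) - object@totalDuration) > 1e-6) {
      msgs <- c(msgs, "totalDuration must equal the sum of event durations")
    }
    if (!all(ev$level %in% c("syllable", "beat", "rest"))) {
      msgs <- c(msgs, "level must be syllable, beat or rest")
    }
  }
  if (!object@condition %in% c("SL", "RA")) msgs <- c(msgs, "condition must be SL or RA")
  if (length(msgs)) msgs else TRUE
})

#' Multichannel EEG recording
#'
#' A channels-by-samples signal matrix in microvolts with its sampling
#' rate, channel names, the stimulus marker sidecar, a processing log and
#' (for simulated data) an artifact ground-truth table. `seams` records
#' time points (in the current time base) where intervals were excised, so
#' that later epoching never straddles a cut.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot sampleRate numeric, Hz.
#' @slot channelNames character, one per row of `data`.
#' @slot markers data.frame with `onset_s`, `onset_sample` (0-based),
#'   `label`, `level`.
#' @slot condition character, "SL", "RA" or "" when unknown.
#' @slot log data.frame with columns `stage`, `detail` (audit trail).
#' @slot seams numeric, excision seam positions in seconds.
#' @slot artifactTruth data.frame of injected artifacts (simulation only).
#' @name EEGRecording-class
#' @aliases EEGRecording-class
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    sampleRate = "numeric",
    channelNames = "character",
    markers = "data.frame",
    condition = "character",
    log = "data.frame",
    seams = "numeric",
    artifactTruth = "data.frame"
  ),
  prototype(
    condition = "",
    log = data.frame(stage = character(), detail = character(),
                     stringsAsFactors = FALSE),
    seams = numeric(0),
    artifactTruth = data.frame()
  )
)

setValidity("EEGRecording", function(object) {
  msgs <- character()
  if (nrow(object@data) != length(object@channelNames)) {
    msgs <- c(msgs, "channelNames must match the number of data rows")
  }
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0) {
    msgs <- c(msgs, "sampleRate must be a single positive number")
  }
  mk <- object@markers
  if (nrow(mk) > 0L) {
    if (!all(c("onset_s", "onset_sample", "label", "level") %in% names(mk))) {
      msgs <- c(msgs, "markers must have onset_s, onset_sample, label, level")
    } else if (is.unsorted(mk$onset_s)) {
      msgs <- c(msgs, "marker onsets must be non-decreasing")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of fixed-length analysis epochs
#'
#' Non-overlapping epochs cut from a continuous recording, time-locked to
#' the event grid: 9 s (ten word repetitions) in the SL condition, 8 s (ten
#' measures) in the RA condition.
#'
#' @slot epochs numeric array, epochs x channels x samples.
#' @slot epochLength numeric, epoch duration in seconds.
#' @slot sampleRate numeric, Hz.
#' @slot channelNames character.
#' @slot condition character, "SL" or "RA".
#' @slot alignment character, marker level the epochs are locked to.
#' @name EpochSet-class
#' @aliases EpochSet-class
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    epochLength = "numeric",
    sampleRate = "numeric",
    channelNames = "character",
    condition = "character",
    alignment = "character"
  )
)

setValidity("EpochSet", function(object) {
  msgs <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msgs <- c(msgs, "epochs must be a 3-d array (epoch, channel, sample)")
  else {
    if (d[1L] < 1L) msgs <- c(msgs, "at least one epoch required")
    if (d[2L] != length(object@channelNames)) msgs <- c(msgs, "channel dimension must match channelNames")
    if (abs(d[3L] - round(object@epochLength * object@sampleRate)) > 0.5) {
      msgs <- c(msgs, "sample dimension must equal epochLength * sampleRate")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Inter-trial coherence spectrum
#'
#' Per-channel inter-trial coherence (ITC) over the FFT frequency grid
#' restricted to 0.6-10 Hz, with the channel average alongside. The bin
#' width is the reciprocal of the epoch length (0.111... Hz for 9-s SL
#' epochs, 0.125 Hz for 8-s RA epochs). Per-epoch phases are retained so
#' sequential analyses can be reconstructed.
#'
#' @slot frequencies numeric, bin centres in Hz.
#' @slot itc numeric matrix, channels x frequencies, each value in `[0, 1]`.
#' @slot itcAvg numeric, channel-mean ITC per frequency.
#' @slot binWidth numeric, Hz.
#' @slot nEpochs integer, number of epochs entering the statistic.
#' @slot phases numeric array, epochs x channels x frequencies (radians).
#' @slot channelNames character.
#' @slot condition character.
#' @name ITCSpectrum-class
#' @aliases ITCSpectrum-class
#' @exportClass ITCSpectrum
setClass("ITCSpectrum",
  representation(
    frequencies = "numeric",
    itc = "matrix",
    itcAvg = "numeric",
    binWidth = "numeric",
    nEpochs = "integer",
    phases = "array",
    channelNames = "character",
    condition = "character"
  )
)

setValidity("ITCSpectrum", function(object) {
  msgs <- character()
  if (any(object@itc < -1e-12) || any(object@itc > 1 + 1e-12)) {
    msgs <- c(msgs, "ITC values must lie in [0, 1]")
  }
  if (ncol(object@itc) != length(object@frequencies)) {
    msgs <- c(msgs, "itc columns must match the frequency grid")
  }
  if (length(object@itcAvg) != length(object@frequencies)) {
    msgs <- c(msgs, "itcAvg must match the frequency grid")
  }
  if (object@binWidth <= 0) msgs <- c(msgs, "binWidth must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Stretched beta prior on a correlation
#'
#' The prior used for Bayesian rank-correlation tests: a beta(1/kappa,
#' 1/kappa) distribution stretched from (0, 1) to (-1, 1) and placed on
#' Pearson's rho; the default width kappa = 0.5 gives a beta(2, 2) shape.
#' One-sided variants truncate at zero and renormalize. The prior is
#' transported to Kendall's tau through Greiner's relation
#' tau = (2/pi) * asin(rho).
#'
#' @slot kappa numeric, prior width > 0.
#' @slot side character, "two_sided", "positive" or "negative".
#' @name StretchedBetaPrior-class
#' @aliases StretchedBetaPrior-class
#' @exportClass StretchedBetaPrior
setClass("StretchedBetaPrior",
  representation(kappa = "numeric", side = "character")
)

setValidity("StretchedBetaPrior", function(object) {
  msgs <- character()
  if (length(object@kappa) != 1L || !is.finite(object@kappa) || object@kappa <= 0) {
    msgs <- c(msgs, "kappa must be a single positive number")
  }
  if (!object@side %in% c("two_sided", "positive", "negative")) {
    msgs <- c(msgs, "side must be two_sided, positive or negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a one-sided Kendall tau-b Bayes factor test
#'
#' @slot tauB numeric, observed tau-b.
#' @slot n integer, number of complete pairs.
#' @slot bf10 numeric, Bayes factor for the (one-sided) alternative.
#' @slot ci95 numeric(2), central 95% credible interval for tau.
#' @slot prior a [StretchedBetaPrior-class] object.
#' @slot robust logical, TRUE when the evidence criterion (BF10 > 3) holds
#'   across the robustness grid of prior widths.
#' @slot robustnessCurve data.frame with columns `kappa`, `bf10`.
#' @name KendallBFResult-class
#' @aliases KendallBFResult-class
#' @exportClass KendallBFResult
setClass("KendallBFResult",
  representation(
    tauB = "numeric",
    n = "integer",
    bf10 = "numeric",
    ci95 = "numeric",
    prior = "StretchedBetaPrior",
    robust = "logical",
    robustnessCurve = "data.frame"
  )
)

setValidity("KendallBFResult", function(object) {
  msgs <- character()
  if (object@bf10 <= 0 || !is.finite(object@bf10)) msgs <- c(msgs, "bf10 must be positive and finite")
  if (abs(object@tauB) > 1 + 1e-12) msgs <- c(msgs, "tauB must lie in [-1, 1]")
  if (length(object@ci95) != 2L || object@ci95[1L] > object@ci95[2L]) {
    msgs <- c(msgs, "ci95 must be an ordered pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of Bayesian model averaging over predictor subsets
#'
#' @slot models data.frame, one row per model: `model`, `k`, `r2`,
#'   `bf_vs_null`, `prior_prob`, `post_prob`.
#' @slot predictors data.frame, one row per predictor (plus intercept):
#'   `predictor`, `p_incl`, `p_incl_data`, `bf_inclusion`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`.
#' @slot bestModel character, identifier of the highest-posterior model.
#' @slot config list, the configuration used (JZS scale, model prior,
#'   outcome transform, n).
#' @name BMAResult-class
#' @aliases BMAResult-class
#' @exportClass BMAResult
setClass("BMAResult",
  representation(
    models = "data.frame",
    predictors = "data.frame",
    bestModel = "character",
    config = "list"
  )
)

setValidity("BMAResult", function(object) {
  msgs <- character()
  if (nrow(object@models) > 0L &&
      abs(sum(object@models$post_prob) - 1) > 1e-6) {
    msgs <- c(msgs, "posterior model probabilities must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})
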