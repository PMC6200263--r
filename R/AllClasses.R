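#' @import methods
NULL

.LANGUAGES <- c("EN", "RU")
.DIRECTIONS <- c("L1toL2", "L2toL1")
.ROLES <- c("source", "target")
.METHODS <- c("CW", "CL", "SYL")

#' Time-coded transcript of one speech stream
#'
#' A `Transcript` holds the time-coded word stream of either the source
#' speech or the interpreter's overt translation for one session and one
#' direction of interpretation.  Words live in a data.frame with columns
#' `surface`, `lemma`, `onset`, `offset` (seconds), `word_class`
#' (`"content"`/`"function"`) and `align_id` (integer linking a source word
#' to its translation chunk; `NA` allowed for target-only fillers).
#'
#' @slot role `"source"` or `"target"`.
#' @slot direction `"L1toL2"` (Russian to English) or `"L2toL1"`.
#' @slot language `"EN"` or `"RU"`; all words share it.
#' @slot words data.frame of time-coded words, sorted by onset.
#'
#' @export
setClass("Transcript",
  representation(
    role = "character",
    direction = "character",
    language = "character",
    words = "data.frame"
  )
)

setValidity("Transcript", function(object) {
  msg <- character()
  w <- object@words
  need <- c("surface", "lemma", "onset", "offset", "word_class", "align_id")
  if (!all(need %in% names(w)))
    msg <- c(msg, paste("words must have columns:", paste(need, collapse = ", ")))
  if (!object@role %in% .ROLES) msg <- c(msg, "role must be 'source' or 'target'")
  if (!object@direction %in% .DIRECTIONS)
    msg <- c(msg, "direction must be 'L1toL2' or 'L2toL1'")
  if (!object@language %in% .LANGUAGES) msg <- c(msg, "language must be EN or RU")
  if (nrow(w) > 0L && all(need %in% names(w))) {
    if (any(w$offset <= w$onset)) msg <- c(msg, "every offset must exceed its onset")
    if (any(w$onset < 0)) msg <- c(msg, "onsets must be >= 0")
    if (is.unsorted(w$onset)) msg <- c(msg, "words must be sorted by onset")
    if (!all(w$word_class %in% c("content", "function")))
      msg <- c(msg, "word_class must be 'content' or 'function'")
  }
  if (length(msg)) msg else TRUE
})

#' Lemma frequency table
#'
#' Absolute corpus frequencies per lemma, standing in for live corpus
#' lookups.  `Fmin`/`Fmax` are the smallest and largest frequency in the
#' table and anchor min-max normalization of log frequencies.
#'
#' @slot entries named numeric vector, lemma -> absolute frequency (>= 1).
#' @slot Fmin,Fmax numeric scalars with `Fmin < Fmax`.
#'
#' @export
setClass("FrequencyTable",
  representation(entries = "numeric", Fmin = "numeric", Fmax = "numeric")
)

setValidity("FrequencyTable", function(object) {
  msg <- character()
  e <- object@entries
  if (is.null(names(e)) || any(!nzchar(names(e))))
    msg <- c(msg, "entries must be named by lemma")
  if (any(e < 1)) msg <- c(msg, "frequencies must be >= 1")
  if (length(e)) {
    if (object@Fmin != min(e) || object@Fmax != max(e))
      msg <- c(msg, "Fmin/Fmax must equal the table's min/max frequency")
    if (object@Fmin >= object@Fmax)
      msg <- c(msg, "degenerate table: Fmin must be < Fmax")
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-linear working-memory load series
#'
#' Load is defined at event-time breakpoints (word entries into and
#' clearances from the working-memory buffer, both at word offsets) and is
#' linearly interpolated between breakpoints; outside the breakpoint range
#' it is clamped to the nearest endpoint.
#'
#' @slot method one of `"CW"`, `"CL"`, `"SYL"`.
#' @slot time numeric, strictly increasing breakpoint times in seconds.
#' @slot load numeric, non-negative load at each breakpoint; first value 0.
#' @slot direction,subject metadata labels.
#'
#' @export
setClass("LoadSeries",
  representation(
    method = "character",
    time = "numeric",
    load = "numeric",
    direction = "character",
    subject = "character"
  )
)

setValidity("LoadSeries", function(object) {
  msg <- character()
  if (!object@method %in% .METHODS) msg <- c(msg, "method must be CW, CL or SYL")
  if (length(object@time) != length(object@load))
    msg <- c(msg, "time and load must have equal length")
  if (length(object@time) == 0L) msg <- c(msg, "series needs at least one breakpoint")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "breakpoint times must be strictly increasing")
  if (length(object@load) && any(object@load < -1e-9))
    msg <- c(msg, "load must be non-negative")
  if (length(object@load) && abs(object@load[1L]) > 1e-9)
    msg <- c(msg, "first breakpoint load must be 0 (session starts empty)")
  if (length(msg)) msg else TRUE
})

#' Probe-tone onset train
#'
#' Onsets of the task-irrelevant pure-tone probes embedded in the source
#' speech (440 Hz, 52 ms in the experimental design emulated here).
#'
#' @slot onsets strictly increasing onset times in seconds.
#' @slot toneFreq tone frequency, Hz (metadata).
#' @slot toneDur tone duration, seconds (metadata).
#'
#' @export
setClass("ProbeTrain",
  representation(onsets = "numeric", toneFreq = "numeric", toneDur = "numeric")
)

setValidity("ProbeTrain", function(object) {
  msg <- character()
  if (length(object@onsets) > 1L && any(diff(object@onsets) <= 0))
    msg <- c(msg, "onsets must be strictly increasing")
  if (length(object@onsets) && any(object@onsets < 0))
    msg <- c(msg, "onsets must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel EEG
#'
#' @slot data numeric matrix, samples x channels, microvolts.
#' @slot channels channel labels (10-20 names, e.g. `"Cz"`, `"TP9"`).
#' @slot srate sampling rate, Hz.
#' @slot events data.frame with columns `sample` (1-based index) and `code`.
#'
#' @export
setClass("ContinuousEEG",
  representation(
    data = "matrix",
    channels = "character",
    srate = "numeric",
    events = "data.frame"
  )
)

setValidity("ContinuousEEG", function(object) {
  msg <- character()
  if (ncol(object@data) != length(object@channels))
    msg <- c(msg, "one label per data column required")
  if (anyDuplicated(object@channels)) msg <- c(msg, "duplicate channel labels")
  if (length(object@srate) != 1L || object@srate <= 0)
    msg <- c(msg, "srate must be a positive scalar")
  if (nrow(object@events)) {
    if (!all(c("sample", "code") %in% names(object@events)))
      msg <- c(msg, "events needs columns sample, code")
    else if (any(object@events$sample < 1 | object@events$sample > nrow(object@data)))
      msg <- c(msg, "event sample indices out of signal bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Probe-locked EEG epochs
#'
#' Epochs cover the half-open window [-0.100, 0.400) s around probe onset
#' (125 samples at 250 Hz) and are baseline-corrected over [-0.100, 0) s.
#' Per-epoch metadata (load value, condition label, subject, direction) live
#' in `info`.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot channels channel labels.
#' @slot srate sampling rate, Hz.
#' @slot times sample times relative to probe onset, seconds.
#' @slot info data.frame with one row per epoch.
#'
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    channels = "character",
    srate = "numeric",
    times = "numeric",
    info = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x samples")
  else {
    if (d[2L] != length(object@channels)) msg <- c(msg, "channel count mismatch")
    if (d[3L] != length(object@times)) msg <- c(msg, "sample count mismatch")
    if (nrow(object@info) != d[1L]) msg <- c(msg, "one info row per epoch required")
  }
  if (length(msg)) msg else TRUE
})
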