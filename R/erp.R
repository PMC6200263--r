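#' Design the band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass.  Cutoffs are placed
#' half a transition band outside the pass-band edges; the transition
#' bandwidths default to the narrow-edge convention (lower: equal to the
#' low edge; upper: a quarter of the high edge, floored at 2 Hz), and the
#' filter length is `3.3 / min(transition) * fs`, rounded up to odd.
#'
#' @param srate sampling rate, Hz.
#' @param band pass band `c(low, high)` in Hz (default 0.1-30).
#' @param transLow,transUpper transition bandwidths in Hz; `NULL` = defaults.
#' @return numeric vector of FIR coefficients (odd length, symmetric).
#' @export
firBandpass <- function(srate, band = c(0.1, 30),
                        transLow = NULL, transUpper = NULL) {
  nyq <- srate / 2
  stopifnot(band[1] > 0, band[2] < nyq, band[1] < band[2])
  if (is.null(transLow)) transLow <- min(max(band[1] * 0.25, 2), band[1])
  if (is.null(transUpper)) transUpper <- min(max(band[2] * 0.25, 2), nyq - band[2])
  ntaps <- ceiling(3.3 / min(transLow, transUpper) * srate)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  edges <- c(band[1] - transLow / 2, band[2] + transUpper / 2) / nyq
  as.numeric(signal::fir1(ntaps - 1, edges, type = "pass"))
}

#' FIR frequency response magnitude
#'
#' @param b FIR coefficients.
#' @param freq frequencies of interest, Hz.
#' @param srate sampling rate, Hz.
#' @return magnitude of the frequency response at `freq`.
#' @export
firResponse <- function(b, freq, srate) {
  k <- seq_along(b) - 1
  vapply(freq, function(f)
    Mod(sum(b * exp(-2i * pi * f * k / srate))), numeric(1))
}

# zero-phase application of a symmetric FIR: reflection padding, single
# forward pass, group-delay compensation
.filter_zero_phase <- function(x, b) {
  n <- nrow(x)
  nb <- length(b)
  delay <- (nb - 1) / 2
  npad <- min(n - 1L, nb)
  apply(x, 2, function(col) {
    padded <- c(2 * col[1] - col[(npad + 1):2],        # reflected, anchored
                col,
                2 * col[n] - col[(n - 1):(n - npad)])
    y <- signal::fftfilt(b, c(padded, numeric(nb)))
    y[(npad + delay + 1):(npad + delay + n)]
  })
}

#' Preprocess continuous EEG
#'
#' Resamples to the target rate, re-references to linked mastoids (the
#' average of TP9 and TP10 subtracted from every channel), removes the DC
#' offset per channel, and applies a zero-phase windowed-sinc FIR
#' band-pass (default 0.1-30 Hz).  Event sample indices are remapped to
#' the new sampling rate.
#'
#' @param raw a [ContinuousEEG-class].
#' @param targetRate output sampling rate, Hz (default 250).
#' @param band FIR pass band, Hz.
#' @param mastoids the two reference channel labels.
#' @return A preprocessed [ContinuousEEG-class].
#' @export
preprocessEEG <- function(raw, targetRate = 250, band = c(0.1, 30),
                          mastoids = c("TP9", "TP10")) {
  stopifnot(is(raw, "ContinuousEEG"))
  if (!all(mastoids %in% raw@channels))
    stop("mastoid channels required for linked-mastoid re-reference: ",
         paste(setdiff(mastoids, raw@channels), collapse = ", "))
  x <- raw@data
  ev <- raw@events
  if (raw@srate != targetRate) {
    ratio <- targetRate / raw@srate
    pq <- .as_ratio(ratio)
    x <- apply(x, 2, function(col)
      as.numeric(signal::resample(col, pq[1], pq[2])))
    if (nrow(ev))
      ev$sample <- pmax(1L, pmin(nrow(x),
                                 as.integer(round((ev$sample - 1L) * ratio) + 1L)))
  }
  ref <- rowMeans(x[, mastoids, drop = FALSE])
  x <- x - ref
  x <- sweep(x, 2, colMeans(x))            # remove DC before the FIR
  b <- firBandpass(targetRate, band)
  x <- .filter_zero_phase(x, b)
  colnames(x) <- raw@channels
  new("ContinuousEEG", data = x, channels = raw@channels,
      srate = targetRate, events = ev)
}

.as_ratio <- function(r, maxden = 64) {
  for (q in seq_len(maxden)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resampling ratio not rational within denominator ", maxden)
}

#' Extract probe-locked epochs
#'
#' Cuts one epoch per probe over the half-open window `[tmin, tmax)`
#' seconds around probe onset (125 samples at 250 Hz for the default
#' \[-0.100, 0.400)) and subtracts the per-channel mean over the baseline
#' `[-0.100, 0)` s.  Probes too close to the recording edge are skipped
#' with a warning; epochs whose peak-to-peak amplitude on any channel
#' exceeds `rejectPtP` microvolts are dropped and counted in the
#' `dropped` attribute.
#'
#' @param eeg a [ContinuousEEG-class].
#' @param probes a [ProbeTrain-class] (onsets in seconds).
#' @param loads optional per-probe load values (same length as probes).
#' @param labels optional per-probe condition labels.
#' @param tmin,tmax epoch window, seconds.
#' @param baseline baseline window, seconds (within the epoch).
#' @param rejectPtP peak-to-peak rejection threshold in microvolts, or
#'   `NULL` to keep all epochs.
#' @param subject,direction metadata carried into the epoch info.
#' @return An [EpochSet-class].
#' @export
epochEEG <- function(eeg, probes, loads = NULL, labels = NULL,
                     tmin = -0.1, tmax = 0.4, baseline = c(-0.1, 0),
                     rejectPtP = NULL, subject = "s01", direction = "L1toL2") {
  stopifnot(is(eeg, "ContinuousEEG"), is(probes, "ProbeTrain"))
  onsets <- probeOnsets(probes)
  n_probe <- length(onsets)
  if (!is.null(loads)) stopifnot(length(loads) == n_probe)
  if (!is.null(labels)) stopifnot(length(labels) == n_probe)
  fs <- eeg@srate
  rel <- seq.int(round(tmin * fs), round(tmax * fs) - 1L)
  times <- rel / fs
  onset_sample <- as.integer(round(onsets * fs)) + 1L
  ok <- onset_sample + rel[1L] >= 1L & onset_sample + rel[length(rel)] <= nrow(eeg@data)
  if (any(!ok))
    warning(sum(!ok), " probe(s) too close to the recording edge; skipped")
  keep <- which(ok)
  nch <- ncol(eeg@data)
  arr <- array(NA_real_, c(length(keep), nch, length(rel)))
  b_idx <- which(times >= baseline[1] & times < baseline[2])
  for (i in seq_along(keep)) {
    seg <- eeg@data[onset_sample[keep[i]] + rel, , drop = FALSE]   # time x ch
    seg <- sweep(seg, 2, colMeans(seg[b_idx, , drop = FALSE]))
    arr[i, , ] <- t(seg)
  }
  dropped <- 0L
  if (!is.null(rejectPtP) && length(keep)) {
    ptp <- apply(arr, 1, function(e) max(apply(e, 1, function(ch) diff(range(ch)))))
    bad <- ptp > rejectPtP
    dropped <- sum(bad)
    arr <- arr[!bad, , , drop = FALSE]
    keep <- keep[!bad]
  }
  info <- data.frame(
    probe_onset = onsets[keep],
    load = if (is.null(loads)) NA_real_ else loads[keep],
    label = if (is.null(labels)) NA_character_ else as.character(labels[keep]),
    subject = subject, direction = direction)
  out <- new("EpochSet", data = arr, channels = eeg@channels, srate = fs,
             times = times, info = info)
  attr(out, "dropped") <- dropped
  out
}

#' Average epochs within conditions
#'
#' Arithmetic mean over trials within each level of a grouping column of
#' the epoch info (default the condition `label`).  Empty cells are
#' flagged by a warning and omitted.
#'
#' @param epochs an [EpochSet-class].
#' @param by grouping column in `epochInfo(epochs)`.
#' @param levels optional level order; defaults to the factor/unique levels.
#' @return named list of channel x time matrices, one per condition.
#' @export
averageByCondition <- function(epochs, by = "label", levels = NULL) {
  stopifnot(is(epochs, "EpochSet"), by %in% names(epochs@info))
  g <- epochs@info[[by]]
  if (is.null(levels)) levels <- if (is.factor(g)) base::levels(g) else unique(g)
  out <- list()
  for (lv in levels) {
    idx <- which(g == lv)
    if (!length(idx)) {
      warning("no epochs in condition ", sQuote(lv), "; cell flagged missing")
      next
    }
    m <- colMeans(epochs@data[idx, , , drop = FALSE], dims = 1)
    dimnames(m) <- list(epochs@channels, NULL)
    out[[lv]] <- m
  }
  attr(out, "times") <- epochs@times
  out
}

#' Grand average with equal subject weighting
#'
#' @param waveforms list of channel x time matrices (one per subject),
#'   identical dimensions.
#' @return channel x time matrix, the mean of the subject means.
#' @export
grandAverage <- function(waveforms) {
  stopifnot(length(waveforms) >= 1)
  Reduce(`+`, waveforms) / length(waveforms)
}

#' ERP component measurement window
#'
#' @param name `"P1"` (positive, 0.040-0.080 s) or `"N1"` (negative,
#'   0.120-0.160 s), or any label if `window`/`polarity` are given.
#' @param window `c(start, end)` seconds post-stimulus.
#' @param polarity `"positive"` or `"negative"` (peak direction).
#' @return list with `name`, `window`, `polarity`.
#' @export
componentWindow <- function(name = c("P1", "N1"), window = NULL,
                            polarity = NULL) {
  if (is.null(window) || is.null(polarity)) {
    name <- match.arg(name)
    defaults <- list(P1 = list(window = c(0.040, 0.080), polarity = "positive"),
                     N1 = list(window = c(0.120, 0.160), polarity = "negative"))
    window <- if (is.null(window)) defaults[[name]]$window else window
    polarity <- if (is.null(polarity)) defaults[[name]]$polarity else polarity
  }
  stopifnot(window[1] < window[2], polarity %in% c("positive", "negative"))
  list(name = name, window = window, polarity = polarity)
}

.window_idx <- function(times, win) {
  idx <- which(times >= win$window[1] - 1e-9 & times <= win$window[2] + 1e-9)
  if (!length(idx)) stop("component window outside the epoch")
  idx
}

#' Window-mean amplitude
#'
#' Mean voltage over the samples whose times fall inside the component
#' window (inclusive at both ends).
#'
#' @param erp channel x time matrix (or a single waveform vector).
#' @param times sample times, seconds.
#' @param win a [componentWindow()].
#' @return named numeric vector, one mean amplitude (microvolts) per channel.
#' @export
windowMeanAmplitude <- function(erp, times, win) {
  if (is.null(dim(erp))) erp <- matrix(erp, nrow = 1)
  idx <- .window_idx(times, win)
  rowMeans(erp[, idx, drop = FALSE])
}

#' Peak latency within a component window
#'
#' Latency of the maximum (positive components) or minimum (negative
#' components) sample inside the window; ties resolve to the earliest
#' sample, and a perfectly flat window returns the earliest sample with a
#' warning.
#'
#' @inheritParams windowMeanAmplitude
#' @return named numeric vector of latencies in milliseconds per channel.
#' @export
peakLatency <- function(erp, times, win) {
  if (is.null(dim(erp))) erp <- matrix(erp, nrow = 1)
  idx <- .window_idx(times, win)
  seg <- erp[, idx, drop = FALSE]
  lat <- apply(seg, 1, function(v) {
    if (diff(range(v)) == 0) {
      warning("flat waveform in component window; returning earliest sample")
      return(times[idx[1L]])
    }
    k <- if (win$polarity == "positive") which.max(v) else which.min(v)
    times[idx[k]]
  })
  lat * 1000
}

#' Summarize an epoch set into per-condition component measures
#'
#' Averages epochs within each condition label, then extracts the
#' window-mean amplitude and peak latency of each component per channel.
#'
#' @param epochs an [EpochSet-class] with condition labels in its info.
#' @param components list of [componentWindow()] objects.
#' @param channels channels to report (default the 21-channel analysis
#'   subset intersected with the available channels).
#' @return data.frame: `subject`, `direction`, `condition`, `channel`,
#'   `component`, `amplitude_uv`, `latency_ms`.
#' @export
summarizeErp <- function(epochs,
                         components = list(componentWindow("P1"),
                                           componentWindow("N1")),
                         channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(channels))
    channels <- intersect(analysisChannels(), epochs@channels)
  stopifnot(length(channels) > 0, all(channels %in% epochs@channels))
  avg <- averageByCondition(epochs, by = "label")
  times <- epochs@times
  info <- epochs@info
  rows <- list()
  ch_idx <- match(channels, epochs@channels)
  for (cond in names(avg)) {
    erp <- avg[[cond]][ch_idx, , drop = FALSE]
    for (comp in components) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = info$subject[1L], direction = info$direction[1L],
        condition = cond, channel = channels, component = comp$name,
        amplitude_uv = unname(windowMeanAmplitude(erp, times, comp)),
        latency_ms = unname(peakLatency(erp, times, comp)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach topographic factors to an ERP summary
#'
#' @param summary output of [summarizeErp()] (possibly row-bound over
#'   subjects/directions).
#' @param map a topographic map from [topoMap()].
#' @return the summary with `anteriority` and `laterality` columns added.
#' @export
addTopography <- function(summary, map = topoMap()) {
  i <- match(summary$channel, map$channel)
  if (anyNA(i)) stop("channels missing from the topographic map: ",
                     paste(unique(summary$channel[is.na(i)]), collapse = ", "))
  summary$anteriority <- map$anteriority[i]
  summary$laterality <- map$laterality[i]
  summary
}
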