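#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-session generator.  Defaults
#' emulate the emulated study's conditions: a 105 words-per-minute source
#' stream, uniform 450-750 ms probe ISIs, 250 Hz EEG, a P1 (positive,
#' ~60 ms) and N1 (negative, ~140 ms) evoked by each probe with amplitudes
#' and latencies linearly modulated by z-scored working-memory load, in
#' 1/f-plus-alpha background noise.  The source-target lag follows a
#' right-skewed, mean-reverting process (mean-centred lognormal steps,
#' reflected at 0) whose level is shifted by `lagDelta` words in the
#' L1->L2 direction.
#'
#' @param seed integer master seed; every derived random stream is a pure
#'   function of it.
#' @param nSubjects simulated cohort size.
#' @param duration session length, seconds.
#' @param wordRate source speech rate, words per minute.
#' @param contentFraction fraction of source words that are content words.
#' @param zipfExponent exponent of the Zipf law assigning lemma frequencies.
#' @param vocabSize content-word vocabulary size per language.
#' @param lagBase baseline source-target lag, words.
#' @param lagStepSd sdlog of the lognormal lag-step distribution.
#' @param lagRho mean-reversion coefficient of the lag process in (0, 1);
#'   values near 1 give slower, wider lag excursions.  Reversion keeps the
#'   process stationary (bounded in distribution), emulating the comfort
#'   zone interpreters keep their lag within.
#' @param lagDelta direction offset, words, added to the lag in L1->L2.
#' @param isiBounds probe inter-stimulus-interval bounds, seconds.
#' @param srate EEG sampling rate, Hz (>= 100).
#' @param channels channel labels; mastoids TP9/TP10 carry noise only.
#' @param p1,n1 component template parameters: `peak` (s), `sd` (s, Gaussian
#'   width), `base` (microvolts), `slope` (microvolts per load z-unit),
#'   `shift` (s of latency per load z-unit).
#' @param noise list: `gamma` (1/f exponent), `rms` (broadband microvolts
#'   RMS), `alphaRms` (10 Hz component RMS), `alphaFreq` (Hz).
#' @param toneFreq,toneDur probe tone metadata (Hz, s).
#' @return list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1L, nSubjects = 9L, duration = 600,
                      wordRate = 105, contentFraction = 0.60,
                      zipfExponent = 1.1, vocabSize = 400,
                      lagBase = 3, lagStepSd = 0.6, lagRho = 0.9,
                      lagDelta = 1.5,
                      isiBounds = c(0.450, 0.750), srate = 250,
                      channels = c(analysisChannels(), "TP9", "TP10"),
                      p1 = list(peak = 0.060, sd = 0.012, base = 2,
                                slope = 0.3, shift = 0.004),
                      n1 = list(peak = 0.140, sd = 0.018, base = -3,
                                slope = -0.5, shift = 0.004),
                      noise = list(gamma = 1, rms = 4, alphaRms = 2,
                                   alphaFreq = 10),
                      toneFreq = 440, toneDur = 0.052) {
  stopifnot(isiBounds[1] > 0, isiBounds[1] < isiBounds[2],
            duration > 10, duration > isiBounds[2],
            srate >= 100, wordRate > 0,
            contentFraction > 0, contentFraction < 1,
            is.finite(p1$slope), is.finite(n1$slope), lagBase > 0,
            lagRho > 0, lagRho < 1)
  structure(as.list(environment()), class = "simConfig")
}

.derive_seed <- function(seed, i = 0L, j = 0L) {
  as.integer((as.numeric(seed) * 1009 + i * 131071 + j * 8191) %% 2147483629)
}

.cv_word <- function(nsyl, language) {
  syl <- if (language == "RU") "ба" else "ba"
  strrep(syl, nsyl)
}

.zipf_freqs <- function(vocabSize, a, Fmax = 1e6) {
  pmax(1, round(Fmax * seq_len(vocabSize)^(-a)))
}

.lemma_name <- function(language, rank) {
  paste0("lex", tolower(language),
         chartr("0123456789", "abcdefghij", sprintf("%04d", rank)))
}

#' Generate an aligned synthetic transcript pair
#'
#' Source words arrive on a fixed grid at `wordRate` words/min (so a
#' 10-minute session has exactly 1050 source words at the default rate).
#' Each source word's translation chunk (one target word, sharing its
#' `align_id`) is emitted after the current lag of the reflected-walk lag
#' process, so target offsets are the observable clear times.  Content
#' lemmas are drawn from a Zipf-distributed vocabulary; surfaces are
#' consonant-vowel pseudo-words whose spelled syllable count is exact by
#' construction, and function words are drawn from the shipped lists.
#'
#' @param cfg a [simConfig()].
#' @param direction `"L1toL2"` (Russian source) or `"L2toL1"` (English
#'   source).
#' @param seed optional integer; `NULL` continues the current RNG stream.
#' @return list: `source` and `target` [Transcript-class] objects, `ftable`
#'   (source-language [FrequencyTable-class]), and `lag_words` (the
#'   realized per-word lag).
#' @export
generateTranscriptPair <- function(cfg, direction = c("L1toL2", "L2toL1"),
                                   seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  src_lang <- if (direction == "L1toL2") "RU" else "EN"
  tgt_lang <- if (direction == "L1toL2") "EN" else "RU"
  n <- round(cfg$wordRate / 60 * cfg$duration)
  slot <- 60 / cfg$wordRate
  onset <- (seq_len(n) - 1) * slot
  offset <- onset + slot

  is_content <- stats::runif(n) < cfg$contentFraction
  freqs <- .zipf_freqs(cfg$vocabSize, cfg$zipfExponent)
  rank <- sample.int(cfg$vocabSize, n, replace = TRUE,
                     prob = seq_len(cfg$vocabSize)^(-cfg$zipfExponent))
  nsyl <- pmin(6L, 1L + stats::rpois(n, 1.1))
  fw <- functionWords(src_lang)
  surface <- ifelse(is_content, .cv_word(nsyl, src_lang),
                    sample(fw, n, replace = TRUE))
  lemma <- ifelse(is_content, .lemma_name(src_lang, rank), surface)

  # mean-reverting process with mean-centred lognormal steps, reflected at
  # 0: stationary (bounded in distribution) and right-skewed
  step <- stats::rlnorm(n, 0, cfg$lagStepSd) - exp(cfg$lagStepSd^2 / 2)
  walk <- Reduce(function(acc, s) abs(cfg$lagRho * acc + s), step,
                 accumulate = TRUE)
  lag_words <- cfg$lagBase + if (direction == "L1toL2") cfg$lagDelta else 0
  lag_words <- lag_words + walk
  clear <- offset + lag_words * slot

  src <- Transcript(
    data.frame(surface = surface, lemma = lemma, onset = onset,
               offset = offset,
               word_class = ifelse(is_content, "content", "function"),
               align_id = seq_len(n), stringsAsFactors = FALSE),
    role = "source", direction = direction, language = src_lang)

  fw_t <- functionWords(tgt_lang)
  t_surface <- ifelse(is_content, .cv_word(nsyl, tgt_lang),
                      sample(fw_t, n, replace = TRUE))
  t_lemma <- ifelse(is_content, paste0("t", .lemma_name(tgt_lang, rank)),
                    t_surface)
  tw <- data.frame(surface = t_surface, lemma = t_lemma,
                   onset = clear - slot, offset = clear,
                   word_class = ifelse(is_content, "content", "function"),
                   align_id = seq_len(n), stringsAsFactors = FALSE)
  tw <- tw[order(tw$onset), ]
  tgt <- Transcript(tw, role = "target", direction = direction,
                    language = tgt_lang)

  fw_f <- pmax(1, round(1e6 * sample(10, length(fw), TRUE)^(-cfg$zipfExponent)))
  ftable <- FrequencyTable(c(
    stats::setNames(freqs, .lemma_name(src_lang, seq_len(cfg$vocabSize))),
    stats::setNames(fw_f, fw)))
  list(source = src, target = tgt, ftable = ftable, lag_words = lag_words)
}

#' Generate a probe-tone train
#'
#' Probe onsets with i.i.d. inter-stimulus intervals uniform on
#' `isiBounds` (default 450-750 ms, mean 600 ms), truncated at session
#' end.
#'
#' @param cfg a [simConfig()].
#' @param seed optional integer; `NULL` continues the current RNG stream.
#' @return A [ProbeTrain-class].
#' @export
generateProbeTrain <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(cfg$duration > cfg$isiBounds[2])
  n_max <- ceiling(cfg$duration / cfg$isiBounds[1]) + 1L
  isi <- stats::runif(n_max, cfg$isiBounds[1], cfg$isiBounds[2])
  onsets <- cumsum(isi)
  onsets <- onsets[onsets < cfg$duration - cfg$isiBounds[1]]
  new("ProbeTrain", onsets = onsets, toneFreq = cfg$toneFreq,
      toneDur = cfg$toneDur)
}

# default fronto-central spatial gain profile (P1/N1 peak near Fz/Cz)
.spatial_profile <- function(channels) {
  g <- c(Fz = 1, Cz = 1, FC1 = 0.95, FC2 = 0.95, F3 = 0.85, F4 = 0.85,
         C3 = 0.8, C4 = 0.8, FC5 = 0.7, FC6 = 0.7, CP1 = 0.7, CP2 = 0.7,
         Fp1 = 0.6, Fp2 = 0.6, F7 = 0.6, F8 = 0.6, Pz = 0.6,
         CP5 = 0.5, CP6 = 0.5, P3 = 0.5, P4 = 0.5, TP9 = 0, TP10 = 0)
  out <- g[channels]
  out[is.na(out)] <- 0.4
  names(out) <- channels
  out
}

# spectrally shaped Gaussian noise, independent across channels: power
# ~ 1/f^gamma plus a 10 Hz alpha bump, each component weighted so its
# share of the total power is (rms^2) : (alphaRms^2); every channel is
# rescaled to total RMS sqrt(rms^2 + alphaRms^2).  Implementation: a
# complex-Gaussian spectrum shaped over a padded highly-composite FFT
# length; without Hermitian symmetry the real and imaginary parts of one
# inverse FFT are two independent realizations, so nch/2 transforms
# suffice.
.shaped_noise <- function(n, nch, srate, gamma, rms, alphaRms, alphaFreq) {
  m <- stats::nextn(n)
  nf <- floor(m / 2)
  f <- seq_len(nf) * srate / m
  bb <- 1 / pmax(f, 0.5)^(gamma / 2)
  al <- exp(-(f - alphaFreq)^2 / 2)
  shape <- sqrt(rms^2 * bb^2 / sum(bb^2) + alphaRms^2 * al^2 / sum(al^2))
  full <- c(0, shape, shape[if (m %% 2 == 0) (nf - 1):1 else nf:1])
  ncplx <- ceiling(nch / 2)
  spec <- matrix(complex(real = stats::rnorm(m * ncplx),
                         imaginary = stats::rnorm(m * ncplx)) * full,
                 m, ncplx)
  z <- stats::mvfft(spec, inverse = TRUE)[seq_len(n), , drop = FALSE]
  x <- cbind(Re(z), Im(z))[, seq_len(nch), drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd) / sqrt(rms^2 + alphaRms^2), "/")
}

#' Noiseless probe-locked template
#'
#' The deterministic part of one epoch under the forward model: the P1 and
#' N1 Gaussian bumps at their load-shifted latencies and load-scaled
#' amplitudes, multiplied by a channel gain.
#'
#' @param cfg a [simConfig()].
#' @param z z-scored load value of the probe.
#' @param times epoch sample times, seconds.
#' @param gain channel gain (1 = template channel).
#' @return numeric waveform, microvolts.
#' @export
noiselessEpoch <- function(cfg, z, times, gain = 1) {
  p1a <- cfg$p1$base + cfg$p1$slope * z
  n1a <- cfg$n1$base + cfg$n1$slope * z
  p1m <- cfg$p1$peak + cfg$p1$shift * z
  n1m <- cfg$n1$peak + cfg$n1$shift * z
  gain * (p1a * exp(-(times - p1m)^2 / (2 * cfg$p1$sd^2)) +
          n1a * exp(-(times - n1m)^2 / (2 * cfg$n1$sd^2)))
}

#' Generate continuous EEG under the forward model
#'
#' Each probe contributes a P1 and an N1 Gaussian template whose amplitude
#' is `base + slope * z(load)` and whose latency is
#' `peak + shift * z(load)`, projected across channels by a fixed
#' fronto-central gain profile; mastoid channels (TP9/TP10) carry noise
#' only.  Background noise is spectrally shaped Gaussian noise (power
#' ~1/f^gamma) plus a narrowband alpha component, independent per channel.
#'
#' @param cfg a [simConfig()].
#' @param probes a [ProbeTrain-class].
#' @param loads per-probe true load values (same length as the train).
#' @param seed optional integer; `NULL` continues the current RNG stream.
#' @return list: `eeg` (a [ContinuousEEG-class], 1 s padding after session
#'   end) and `truth` (ground-truth record: `loads`, `z`, per-probe
#'   amplitudes and latencies, slopes, channel gains).
#' @export
generateEEG <- function(cfg, probes, loads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  onsets <- probeOnsets(probes)
  stopifnot(length(loads) == length(onsets), cfg$srate >= 100)
  fs <- cfg$srate
  n <- round((cfg$duration + 1) * fs)
  z <- if (stats::sd(loads) > 0) (loads - mean(loads)) / stats::sd(loads)
       else numeric(length(loads))

  p1a <- cfg$p1$base + cfg$p1$slope * z
  n1a <- cfg$n1$base + cfg$n1$slope * z
  p1m <- cfg$p1$peak + cfg$p1$shift * z
  n1m <- cfg$n1$peak + cfg$n1$shift * z

  sig <- numeric(n)
  w <- seq(0, round(0.3 * fs)) / fs        # template support, 0-300 ms
  on_samp <- round(onsets * fs) + 1L
  for (k in seq_along(onsets)) {
    idx <- on_samp[k] + seq_along(w) - 1L
    ok <- idx <= n
    sig[idx[ok]] <- sig[idx[ok]] +
      p1a[k] * exp(-(w[ok] - p1m[k])^2 / (2 * cfg$p1$sd^2)) +
      n1a[k] * exp(-(w[ok] - n1m[k])^2 / (2 * cfg$n1$sd^2))
  }
  gains <- .spatial_profile(cfg$channels)
  data <- outer(sig, gains)
  if (cfg$noise$rms > 0 || cfg$noise$alphaRms > 0)
    data <- data + .shaped_noise(n, length(cfg$channels), fs,
                                 cfg$noise$gamma, cfg$noise$rms,
                                 cfg$noise$alphaRms, cfg$noise$alphaFreq)
  colnames(data) <- cfg$channels
  eeg <- new("ContinuousEEG", data = data, channels = cfg$channels,
             srate = fs,
             events = data.frame(sample = as.integer(on_samp), code = "probe"))
  truth <- list(loads = loads, z = z, p1_amp = p1a, n1_amp = n1a,
                p1_lat = p1m, n1_lat = n1m,
                p1_slope = cfg$p1$slope, n1_slope = cfg$n1$slope,
                gains = gains)
  list(eeg = eeg, truth = truth)
}

#' Simulate one interpreting session end to end
#'
#' Transcript pair, frequency table, probe train, the three load series,
#' per-probe interpolated loads (the forward model is driven by the CW
#' series) and, optionally, continuous EEG.
#'
#' @param cfg a [simConfig()].
#' @param subject subject label.
#' @param direction `"L1toL2"` or `"L2toL1"`.
#' @param seed integer seed for this session (derive one per session for
#'   cohorts); defaults to `cfg$seed`.
#' @param eeg generate EEG too (set FALSE for behavioral-only use).
#' @return list with elements `source`, `target`, `ftable`, `probes`,
#'   `series` (named list CW/CL/SYL of [LoadSeries-class]), `loads`
#'   (per-probe CW load), `eeg`, `truth`.
#' @export
simulateSession <- function(cfg, subject = "s01",
                            direction = c("L1toL2", "L2toL1"),
                            seed = cfg$seed, eeg = TRUE) {
  direction <- match.arg(direction)
  set.seed(seed)
  tp <- generateTranscriptPair(cfg, direction)
  probes <- generateProbeTrain(cfg)
  series <- lapply(stats::setNames(.METHODS, .METHODS), function(m)
    computeLoadSeries(tp$source, tp$target, method = m,
                      ftable = tp$ftable, subject = subject, warn = FALSE))
  loads <- interpolateLoad(series$CW, probeOnsets(probes))
  rec <- if (eeg) generateEEG(cfg, probes, loads) else NULL
  list(source = tp$source, target = tp$target, ftable = tp$ftable,
       probes = probes, series = series, loads = loads,
       eeg = rec$eeg, truth = rec$truth, subject = subject,
       direction = direction, seed = seed)
}

#' Simulate a cohort (behavioral level)
#'
#' One session per subject and direction, without EEG (sessions are
#' generated EEG-free so cohort-level behavioral analyses stay light;
#' regenerate single sessions with [simulateSession()] for EEG).
#'
#' @param cfg a [simConfig()].
#' @return list of session records (see [simulateSession()]).
#' @export
simulateCohort <- function(cfg) {
  out <- list()
  for (i in seq_len(cfg$nSubjects)) {
    for (d in c("L1toL2", "L2toL1")) {
      s <- simulateSession(cfg, subject = sprintf("s%02d", i), direction = d,
                           seed = .derive_seed(cfg$seed, i,
                                               match(d, .DIRECTIONS)),
                           eeg = FALSE)
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
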