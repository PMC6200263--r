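make_eeg <- function(data, srate = 250,
                     channels = colnames(data),
                     events = data.frame(sample = integer(),
                                         code = character())) {
  new("ContinuousEEG", data = data, channels = channels, srate = srate,
      events = events)
}

sine_eeg <- function(freq, dur = 60, srate = 250, amp = 10,
                     channels = c("Cz", "TP9", "TP10")) {
  t <- seq(0, dur - 1 / srate, by = 1 / srate)
  x <- matrix(amp * sin(2 * pi * freq * t), ncol = length(channels),
              nrow = length(t))
  colnames(x) <- channels
  # keep mastoids quiet so re-referencing leaves the test channel intact
  x[, channels %in% c("TP9", "TP10")] <- 0
  make_eeg(x, srate = srate)
}

test_that("the band-pass FIR attenuates 50 Hz by at least 20 dB and passes
           10 Hz", {
  b <- firBandpass(250)
  # response oracle straight from the designed coefficients
  expect_lt(firResponse(b, 50, 250), 10^(-20 / 20))
  expect_equal(firResponse(b, 10, 250), 1, tolerance = 0.01)
  expect_lt(firResponse(b, 0, 250), 0.05)
  # end to end: a 50 Hz sinusoid shrinks by >= 20 dB (the interior window
  # keeps clear of the FIR settling span, ~16.5 s at 250 Hz)
  eeg <- sine_eeg(50)
  out <- preprocessEEG(eeg)
  mid <- 4500:10500
  ratio <- sd(signalData(out)[mid, "Cz"]) / sd(signalData(eeg)[mid, "Cz"])
  expect_lt(ratio, 0.1)
  # and a 10 Hz sinusoid passes essentially unchanged
  eeg10 <- sine_eeg(10)
  out10 <- preprocessEEG(eeg10)
  ratio10 <- sd(signalData(out10)[mid, "Cz"]) /
    sd(signalData(eeg10)[mid, "Cz"])
  expect_equal(ratio10, 1, tolerance = 0.02)
})

test_that("a 100 uV DC offset is removed by preprocessing", {
  x <- matrix(100, nrow = 15000, ncol = 3)
  colnames(x) <- c("Cz", "TP9", "TP10")
  x[, 2:3] <- 0
  out <- preprocessEEG(make_eeg(x))
  expect_lt(max(abs(signalData(out)[4500:10500, "Cz"])), 1)
})

test_that("identical signal on all channels is nulled by the linked-mastoid
           reference", {
  set.seed(5)
  common <- rnorm(5000)
  x <- matrix(common, nrow = 5000, ncol = 4)
  colnames(x) <- c("Cz", "Fz", "TP9", "TP10")
  out <- preprocessEEG(make_eeg(x))
  expect_lt(max(abs(signalData(out))), 1e-8)
})

test_that("preprocessing requires the mastoid channels", {
  x <- matrix(0, 100, 1); colnames(x) <- "Cz"
  expect_error(preprocessEEG(make_eeg(x)), "mastoid")
})

test_that("resampling halves the rate and remaps event indices", {
  srate <- 500
  t <- seq(0, 10 - 1 / srate, by = 1 / srate)
  x <- matrix(sin(2 * pi * 5 * t), ncol = 3, nrow = length(t))
  colnames(x) <- c("Cz", "TP9", "TP10")
  x[, 2:3] <- 0
  eeg <- make_eeg(x, srate = srate,
                  events = data.frame(sample = 2001L, code = "probe"))
  out <- preprocessEEG(eeg, targetRate = 250)
  expect_equal(samplingRate(out), 250)
  expect_equal(nrow(signalData(out)), 2500)
  expect_equal(eegEvents(out)$sample, 1001L)   # t = 4 s at the new rate
})

test_that("epochs are 125 samples at 250 Hz over [-0.1, 0.4) with edge
           probes skipped", {
  set.seed(9)
  x <- matrix(rnorm(15000 * 2), ncol = 2)
  colnames(x) <- c("Cz", "Fz")
  eeg <- make_eeg(x)                      # 60 s at 250 Hz
  onsets <- sort(runif(95, 0, 59.9))
  pr <- new("ProbeTrain", onsets = onsets, toneFreq = 440, toneDur = 0.052)
  ep <- suppressWarnings(epochEEG(eeg, pr))
  expect_lte(dim(signalData(ep))[1], 95L)
  expect_equal(dim(signalData(ep))[3], 125L)
  expect_equal(length(epochTimes(ep)), 125L)
  expect_equal(min(epochTimes(ep)), -0.1)
  expect_equal(max(epochTimes(ep)), 0.396)
  # a probe at the very edge is skipped with a warning, not an error
  pr_edge <- new("ProbeTrain", onsets = c(0.01, 30), toneFreq = 440,
                 toneDur = 0.052)
  expect_warning(ep2 <- epochEEG(eeg, pr_edge), "edge")
  expect_equal(dim(signalData(ep2))[1], 1L)
})

test_that("baseline correction zeroes constant signals and is idempotent", {
  x <- matrix(5, nrow = 2500, ncol = 2)
  colnames(x) <- c("Cz", "Fz")
  pr <- new("ProbeTrain", onsets = c(2, 4, 6), toneFreq = 440,
            toneDur = 0.052)
  ep <- epochEEG(make_eeg(x), pr)
  expect_equal(max(abs(signalData(ep))), 0)
  # idempotence: re-subtracting the baseline mean changes nothing
  arr <- signalData(ep)
  b_idx <- which(epochTimes(ep) >= -0.1 & epochTimes(ep) < 0)
  again <- arr
  for (i in seq_len(dim(arr)[1]))
    again[i, , ] <- arr[i, , ] - rowMeans(arr[i, , b_idx, drop = FALSE])
  expect_equal(again, arr)
})

test_that("peak-to-peak rejection drops extreme epochs", {
  set.seed(2)
  x <- matrix(rnorm(5000 * 2, sd = 5), ncol = 2)
  colnames(x) <- c("Cz", "Fz")
  x[1000:1005, 1] <- 400                       # gross artifact at ~4 s
  pr <- new("ProbeTrain", onsets = c(2, 4, 8, 12), toneFreq = 440,
            toneDur = 0.052)
  ep <- epochEEG(make_eeg(x), pr, rejectPtP = 150)
  expect_equal(attr(ep, "dropped"), 1L)
  expect_equal(dim(signalData(ep))[1], 3L)
})

test_that("condition averages equal the trivial cases and commute with
           channel selection", {
  set.seed(3)
  arr <- array(rnorm(6 * 3 * 125), c(6, 3, 125))
  arr[2, , ] <- arr[1, , ]                    # two identical epochs
  info <- data.frame(probe_onset = 1:6, load = 1:6,
                     label = c("low", "low", "high", "medium", "medium",
                               "medium"),
                     subject = "s01", direction = "L1toL2")
  ep <- new("EpochSet", data = arr, channels = c("Cz", "Fz", "Pz"),
            srate = 250, times = seq(-0.1, 0.396, by = 0.004), info = info)
  avg <- averageByCondition(ep)
  expect_equal(avg$low, arr[1, , ], ignore_attr = TRUE)
  expect_equal(avg$high, arr[3, , ], ignore_attr = TRUE)   # single epoch
  # channel selection before or after averaging gives the same answer
  sel <- averageByCondition(ep)$medium[c("Cz", "Pz"), ]
  ep_sel <- new("EpochSet", data = arr[, c(1, 3), ],
                channels = c("Cz", "Pz"), srate = 250,
                times = ep@times, info = info)
  expect_equal(averageByCondition(ep_sel)$medium, sel)
  # empty cell flagged with a warning
  info2 <- info; info2$label[3] <- "medium"
  ep2 <- new("EpochSet", data = arr, channels = ep@channels, srate = 250,
             times = ep@times, info = info2)
  expect_warning(averageByCondition(ep2, levels = c("low", "medium", "high")),
                 "no epochs")
})

test_that("grand averages weight subjects equally", {
  a <- matrix(1, 2, 10); b <- matrix(3, 2, 10)
  expect_equal(grandAverage(list(a, b)), matrix(2, 2, 10))
})

test_that("window-mean amplitude averages the samples inside the window", {
  times <- seq(-0.1, 0.396, by = 0.004)
  flat <- rep(5, length(times))
  expect_equal(unname(windowMeanAmplitude(flat, times,
                                          componentWindow("P1"))), 5)
  # linear ramp: the window mean is the value at the window midpoint
  ramp <- 100 * (times - 0.04) / 0.04          # 0 at 40 ms, 100 at 80 ms
  expect_equal(unname(windowMeanAmplitude(ramp, times,
                                          componentWindow("P1"))),
               50, tolerance = 1e-9)
  # Gaussian template: matches the sampled closed form exactly and the
  # continuous integral up to discretization
  g <- 2 * exp(-(times - 0.060)^2 / (2 * 0.012^2))
  idx <- which(times >= 0.040 & times <= 0.080)
  expect_equal(unname(windowMeanAmplitude(g, times, componentWindow("P1"))),
               mean(2 * exp(-(times[idx] - 0.06)^2 / (2 * 0.012^2))),
               tolerance = 1e-12)
  cont <- integrate(function(t) 2 * exp(-(t - 0.06)^2 / (2 * 0.012^2)),
                    0.040 - 0.002, 0.080 + 0.002)$value / 0.044
  expect_equal(unname(windowMeanAmplitude(g, times, componentWindow("P1"))),
               cont, tolerance = 5e-3)
  expect_error(windowMeanAmplitude(g, times,
                                   componentWindow("X", c(2, 3), "positive")),
               "outside")
})

test_that("peak latency finds the extremum with earliest-tie and flat-window
           handling", {
  times <- seq(-0.1, 0.396, by = 0.004)
  bump <- exp(-(times - 0.060)^2 / (2 * 0.012^2))
  expect_equal(unname(peakLatency(bump, times, componentWindow("P1"))), 60,
               tolerance = 4)
  dip <- -exp(-(times - 0.140)^2 / (2 * 0.018^2))
  expect_equal(unname(peakLatency(dip, times, componentWindow("N1"))), 140,
               tolerance = 4)
  # monotone rising segment: the maximum sits at the window end
  expect_equal(unname(peakLatency(times, times, componentWindow("P1"))), 80)
  expect_warning(
    lat <- peakLatency(rep(1, length(times)), times, componentWindow("P1")),
    "flat")
  expect_equal(unname(lat), 40)
  # ties resolve to the earliest sample
  two <- rep(0, length(times))
  two[c(which.min(abs(times - 0.048)), which.min(abs(times - 0.072)))] <- 7
  expect_equal(unname(peakLatency(two, times, componentWindow("P1"))), 48)
})

test_that("the ERP summary covers each condition, channel and component", {
  cfg <- simConfig(seed = 8, duration = 40)
  s <- simulateSession(cfg, direction = "L2toL1", seed = 31)
  ep <- epochEEG(s$eeg, s$probes, loads = s$loads)
  ep@info$label <- as.character(labelByQuantile(epochInfo(ep)$load))
  sm <- summarizeErp(ep)
  expect_setequal(unique(sm$channel), analysisChannels())
  expect_setequal(unique(sm$component), c("P1", "N1"))
  expect_equal(nrow(sm), 3 * 21 * 2)
  top <- addTopography(sm)
  expect_equal(sum(top$anteriority == "Front") / 6, 7)   # 7 frontal sites
  expect_setequal(unique(top$laterality), c("Left", "Middle", "Right"))
})

test_that("the topographic map partitions the 21 channels 3 x 3", {
  m <- topoMap()
  expect_setequal(m$channel, analysisChannels())
  expect_equal(as.vector(table(m$anteriority)), c(7L, 7L, 7L))
  expect_equal(sort(as.vector(table(m$laterality))), c(3L, 9L, 9L))
})
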