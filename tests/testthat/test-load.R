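test_that("empty transcripts give a single zero breakpoint", {
  s <- computeLoadSeries(empty_transcript("source"),
                         empty_transcript("target", language = "EN"), "CW")
  bp <- breakpoints(s)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$time, 0)
  expect_equal(bp$load, 0)
})

test_that("a single buffered content word enters at its offset and clears at
           the translation offset", {
  src <- Transcript(make_words("мир", 0.5, 1.0, word_class = "content",
                               align_id = 1L),
                    "source", "L1toL2", "RU")
  tgt <- Transcript(make_words("ba", 1.5, 2.0, word_class = "content",
                               align_id = 1L),
                    "target", "L1toL2", "EN")
  s <- computeLoadSeries(src, tgt, "CW")
  expect_equal(breakpoints(s), data.frame(time = c(0, 1, 2),
                                          load = c(0, 1, 0)))
  # the load is 1 exactly at entry and returns to 0 at the clear event
  expect_equal(interpolateLoad(s, c(1.0, 2.0, 3.0)), c(1, 0, 0))
})

test_that("load series equals the independent event-sweep oracle", {
  tp <- toy_pair()
  sw <- transcriptWords(tp$src)
  twd <- transcriptWords(tp$tgt)
  clear <- vapply(sw$align_id, function(id)
    if (is.na(id) || !id %in% twd$align_id) NA_real_
    else max(twd$offset[twd$align_id == id]), numeric(1))
  # CW: content words, weight 1
  w_cw <- as.numeric(sw$word_class == "content")
  got <- breakpoints(computeLoadSeries(tp$src, tp$tgt, "CW"))
  expect_equal(got, sweep_oracle(sw$offset, clear, w_cw),
               ignore_attr = TRUE)
  # SYL: all words, syllable weight
  w_syl <- vapply(sw$surface, countSyllables, integer(1), language = "RU")
  got_syl <- breakpoints(computeLoadSeries(tp$src, tp$tgt, "SYL"))
  expect_equal(got_syl, sweep_oracle(sw$offset, clear, as.numeric(w_syl)),
               ignore_attr = TRUE)
  # omitted word (no aligned target) is excluded and reported
  cov <- attr(computeLoadSeries(tp$src, tp$tgt, "CW"), "coverage")
  expect_equal(cov$omitted, 1L)
})

test_that("load series matches the sweep oracle on random sessions", {
  cfg <- simConfig(seed = 11, duration = 45)
  for (k in 1:10) {
    tp <- generateTranscriptPair(cfg, "L2toL1", seed = 100 + k)
    sw <- transcriptWords(tp$source)
    twd <- transcriptWords(tp$target)
    clear <- vapply(sw$align_id, function(id)
      max(twd$offset[twd$align_id == id]), numeric(1))
    s <- computeLoadSeries(tp$source, tp$target, "CW", subject = "sX")
    expect_equal(breakpoints(s),
                 sweep_oracle(sw$offset, clear,
                              as.numeric(sw$word_class == "content")),
                 ignore_attr = TRUE)
    # CL is bounded above by CW pointwise because fhat is in [0, 1]
    scl <- computeLoadSeries(tp$source, tp$target, "CL",
                             ftable = tp$ftable, warn = FALSE)
    grid <- seq(0, cfg$duration, by = 0.25)
    expect_true(all(interpolateLoad(scl, grid) <=
                      interpolateLoad(s, grid) + 1e-9))
  }
})

test_that("adding one buffered content word raises CW load by exactly 1
           inside its interval and nowhere else", {
  tp <- toy_pair()
  base <- computeLoadSeries(tp$src, tp$tgt, "CW")
  sw <- transcriptWords(tp$src)
  extra_src <- rbind(sw, make_words("бабаба", 3.6, 4.1,
                                    word_class = "content", align_id = 9L))
  tw <- transcriptWords(tp$tgt)
  extra_tgt <- rbind(tw, make_words("baba", 5.5, 6.0,
                                    word_class = "content", align_id = 9L))
  src2 <- Transcript(extra_src, "source", "L1toL2", "RU")
  tgt2 <- Transcript(extra_tgt, "target", "L1toL2", "EN")
  more <- computeLoadSeries(src2, tgt2, "CW")
  # the event process gains exactly 1 while the word is buffered
  # ([4.1, 6.0)) and is untouched elsewhere
  inside <- c(4.1, 5.0, 5.999)
  outside <- c(0, 2.0, 4.05, 6.0, 7.0)
  expect_equal(step_at(more, inside), step_at(base, inside) + 1)
  expect_equal(step_at(more, outside), step_at(base, outside))
  # the new breakpoints are the old ones plus the entry/clear events
  expect_equal(breakpoints(more),
               data.frame(time = c(0, 1, 2, 2.5, 2.8, 4.1, 4.4, 5.1, 6.0),
                          load = c(0, 1, 2, 3, 2, 3, 2, 1, 0)))
})

test_that("fully aligned sessions conserve: the final CW load returns to 0", {
  cfg <- simConfig(seed = 3, duration = 30)
  tp <- generateTranscriptPair(cfg, "L1toL2", seed = 21)
  s <- computeLoadSeries(tp$source, tp$target, "CW")
  bp <- breakpoints(s)
  expect_equal(bp$load[nrow(bp)], 0)
  expect_true(all(bp$load >= 0))
})

test_that("CL requires a frequency table and alignment must be consistent", {
  tp <- toy_pair()
  expect_error(computeLoadSeries(tp$src, tp$tgt, "CL"), "frequency table")
  tw <- transcriptWords(tp$tgt)
  tw$align_id[1] <- 99L
  bad_tgt <- Transcript(tw, "target", "L1toL2", "EN")
  expect_error(computeLoadSeries(tp$src, bad_tgt, "CW"), "absent in source")
})

test_that("word scope switch swaps CL and SYL scopes", {
  tp <- toy_pair()
  ft <- FrequencyTable(c(мир = 1000, бабаба = 10,
                         организация = 100, ба = 50))
  # alternate scope: SYL counts content words only -> lighter series
  syl_all <- computeLoadSeries(tp$src, tp$tgt, "SYL", warn = FALSE)
  syl_content <- computeLoadSeries(tp$src, tp$tgt, "SYL",
                                   wordScope = "alternate", warn = FALSE)
  grid <- seq(0, 6, by = 0.1)
  expect_true(all(step_at(syl_content, grid) <=
                    step_at(syl_all, grid) + 1e-9))
  # inverted CL weight: 1 - fhat
  cl <- computeLoadSeries(tp$src, tp$tgt, "CL", ftable = ft, warn = FALSE)
  cli <- computeLoadSeries(tp$src, tp$tgt, "CL", ftable = ft,
                           invertClWeight = TRUE, warn = FALSE)
  expect_false(isTRUE(all.equal(breakpoints(cl), breakpoints(cli))))
})

test_that("interpolation is linear between breakpoints and clamped outside", {
  s <- new("LoadSeries", method = "CW", time = c(0, 1, 2),
           load = c(0, 2, 4), direction = "L1toL2", subject = "s01")
  expect_equal(interpolateLoad(s, 1.5), 3.0)
  expect_equal(interpolateLoad(s, 0.5), 1.0)
  expect_equal(interpolateLoad(s, -1), 0)      # clamp before the range
  expect_equal(interpolateLoad(s, 99), 4)      # clamp after the range
  expect_error(interpolateLoad(s, c(2, 1)), "sorted")
})

test_that("interpolation agrees with a dense-grid resampling oracle", {
  set.seed(7)
  tt <- cumsum(runif(40, 0.1, 2))
  ld <- c(0, abs(cumsum(rnorm(39))))
  s <- new("LoadSeries", method = "CW", time = tt, load = ld,
           direction = "L1toL2", subject = "s01")
  dense_t <- seq(min(tt), max(tt), length.out = 200001)
  dense <- interpolateLoad(s, dense_t)
  q <- sort(runif(1000, min(tt), max(tt)))
  # snap queries onto the dense grid, then compare
  qi <- round((q - min(tt)) / (max(tt) - min(tt)) * 200000) + 1
  expect_lt(max(abs(interpolateLoad(s, dense_t[qi]) - dense[qi])), 1e-9)
})

test_that("quantile labels match the linear-interpolation quantile rule", {
  lab <- labelByQuantile(1:10)
  expect_equal(as.character(lab[1]), "low")     # 1 < Q(0.10) = 1.9
  expect_equal(as.character(lab[10]), "high")   # 10 > Q(0.90) = 9.1
  expect_equal(sum(lab == "low"), 1L)
  expect_equal(sum(lab == "high"), 1L)
  # degenerate distribution: strict inequalities fail, everything medium
  expect_true(all(labelByQuantile(rep(3, 50)) == "medium"))
  expect_warning(labelByQuantile(1:5), "fewer than 10")
  expect_error(labelByQuantile(1:20, qLow = 0.9, qHigh = 0.1))
})

test_that("label proportions approach 10/80/10 and are invariant under
           monotone transforms", {
  set.seed(123)
  loads <- rlnorm(10000, 0, 0.6)
  lab <- labelByQuantile(loads)
  prop <- as.numeric(table(lab)) / length(loads)
  expect_true(all(abs(prop - c(0.10, 0.80, 0.10)) <= 0.01))
  expect_equal(labelByQuantile(exp(loads)), lab)
  expect_equal(labelByQuantile(rank(loads, ties.method = "first")), lab)
})

test_that("load series export one aligned CSV column per method", {
  tp <- toy_pair()
  ft <- FrequencyTable(c(мир = 1000, бабаба = 10,
                         организация = 100, ба = 50))
  sl <- list(CW = computeLoadSeries(tp$src, tp$tgt, "CW"),
             CL = computeLoadSeries(tp$src, tp$tgt, "CL", ftable = ft,
                                    warn = FALSE),
             SYL = computeLoadSeries(tp$src, tp$tgt, "SYL"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLoadSeriesCsv(sl, f)
  d <- read.csv(f)
  expect_named(d, c("time_s", "load_cw", "load_cl", "load_syl"))
  expect_equal(d$load_cw, interpolateLoad(sl$CW, d$time_s))
  expect_true(all(diff(d$time_s) > 0))
})

test_that("median loads summarize probe-onset loads per session", {
  s <- new("LoadSeries", method = "CW", time = c(0, 1, 2, 3, 4),
           load = c(0, 1, 2, 3, 0), direction = "L1toL2", subject = "s01")
  pr <- new("ProbeTrain", onsets = c(1, 2, 3), toneFreq = 440,
            toneDur = 0.052)
  s2 <- new("LoadSeries", method = "CW", time = s@time, load = s@load,
            direction = "L2toL1", subject = "s01")
  med <- medianLoads(list(list(series = s, probes = pr),
                          list(series = s2, probes = pr)))
  expect_equal(med$median_load, c(2, 2))      # median of {1,2,3}
  # single-probe session: median equals that probe's load
  pr1 <- new("ProbeTrain", onsets = 2.5, toneFreq = 440, toneDur = 0.052)
  med1 <- medianLoads(list(list(series = s, probes = pr1),
                           list(series = s2, probes = pr1)))
  expect_equal(med1$median_load[1], 2.5)
  # a subject missing one direction is dropped with a warning
  expect_warning(
    med2 <- medianLoads(list(list(series = s, probes = pr))), "missing")
  expect_equal(nrow(med2), 0L)
})
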