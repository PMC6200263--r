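# fixtures and independent oracles, built in code

make_words <- function(surface, onset, offset, lemma = surface,
                       word_class = NULL, align_id = NA_integer_) {
  data.frame(surface = surface, lemma = lemma, onset = onset,
             offset = offset,
             word_class = if (is.null(word_class)) "content" else word_class,
             align_id = align_id, stringsAsFactors = FALSE)
}

empty_transcript <- function(role = "source", direction = "L1toL2",
                             language = "RU") {
  w <- data.frame(surface = character(), lemma = character(),
                  onset = numeric(), offset = numeric(),
                  word_class = character(), align_id = integer())
  Transcript(w, role = role, direction = direction, language = language)
}

# read a load series as the underlying step process: the value at t is the
# load after the last event at or before t
step_at <- function(series, times) {
  bp <- breakpoints(series)
  if (nrow(bp) == 1L) return(rep(bp$load, length(times)))
  stats::approx(bp$time, bp$load, xout = times, method = "constant",
                rule = 2)$y
}

# 6-word toy pair with interleaved clears: source words cleared out of
# order, two function words, one omitted (never translated) word
toy_pair <- function() {
  src <- Transcript(make_words(
    surface = c("мир", "и", "бабаба", "ба", "в", "организация"),
    onset  = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0),
    offset = c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5),
    word_class = c("content", "function", "content", "content",
                   "function", "content"),
    align_id = c(1L, 2L, 3L, 4L, NA, 6L)),
    role = "source", direction = "L1toL2", language = "RU")
  tgt <- Transcript(make_words(
    surface = c("ba", "and", "bababa", "baba"),
    onset  = c(2.2, 2.8, 3.4, 4.5),
    offset = c(2.8, 3.4, 4.4, 5.1),
    word_class = c("content", "function", "content", "content"),
    align_id = c(3L, 2L, 1L, 4L)),          # clears out of source order
    role = "target", direction = "L1toL2", language = "EN")
  list(src = src, tgt = tgt)
}

# independent event-sweep oracle: replays entry/clear events in time order
# and returns the load after the events at each unique event time
sweep_oracle <- function(entry, clear, w) {
  keep <- !is.na(clear) & clear > entry & w > 0
  ev <- data.frame(t = c(entry[keep], clear[keep]), d = c(w[keep], -w[keep]))
  if (!nrow(ev)) return(data.frame(time = 0, load = 0))
  ev <- ev[order(ev$t), ]
  tt <- unique(ev$t)
  load <- vapply(tt, function(t0) sum(ev$d[ev$t <= t0]), numeric(1))
  load[abs(load) < 1e-9] <- 0
  if (tt[1] > 0) { tt <- c(0, tt); load <- c(0, load) }
  data.frame(time = tt, load = load)
}

# brute-force exact Wilcoxon: literal enumeration of all 2^n sign patterns
brute_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  list(V = V, p = p)
}

# independent sums-of-squares oracle for the fully balanced within-subject
# ANOVA: marginal totals + inclusion-exclusion, error term per effect
ss_oracle <- function(data, dv, within, subject = "subject") {
  data <- as.data.frame(data)
  for (v in c(within, subject)) data[[v]] <- factor(data[[v]])
  agg <- stats::aggregate(data[[dv]],
                          by = c(data[subject], data[within]), FUN = mean)
  names(agg)[ncol(agg)] <- ".y"
  N <- nrow(agg)
  grand <- sum(agg$.y)
  U <- function(facs) {               # sum over margin cells of total^2/size
    if (!length(facs)) return(grand^2 / N)
    tot <- stats::aggregate(agg$.y, by = agg[facs], FUN = sum)
    cnt <- stats::aggregate(agg$.y, by = agg[facs], FUN = length)
    sum(tot$x^2 / cnt$x)
  }
  SS <- function(facs) {              # inclusion-exclusion over subsets
    s <- 0
    for (k in 0:length(facs)) {
      subs <- utils::combn(facs, k, simplify = FALSE)
      for (t in subs) s <- s + (-1)^(length(facs) - k) * U(t)
    }
    s
  }
  dfs <- vapply(c(within, subject), function(f) nlevels(agg[[f]]) - 1L,
                integer(1))
  names(dfs) <- c(within, subject)
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(e) {
    ss_e <- SS(e)
    ss_err <- SS(c(e, subject))
    df_e <- prod(dfs[e])
    df_err <- df_e * dfs[subject]
    Fv <- (ss_e / df_e) / (ss_err / df_err)
    data.frame(effect = paste(e, collapse = ":"), df_num = df_e,
               df_den = df_err, F = Fv,
               p = stats::pf(Fv, df_e, df_err, lower.tail = FALSE),
               pes = ss_e / (ss_e + ss_err))
  })
  do.call(rbind, out)
}

random_anova_table <- function(n_subj = 9, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("s%02d", seq_len(n_subj)),
                   direction = c("L1toL2", "L2toL1"),
                   load = c("low", "medium", "high"),
                   anteriority = c("Front", "Center", "Back"),
                   laterality = c("Left", "Middle", "Right"))
  d$amplitude <- stats::rnorm(nrow(d))
  d
}
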