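#' Compute a working-memory load series from an aligned transcript pair
#'
#' Each counted source word enters the working-memory buffer at its own
#' offset and leaves it at the offset of the last target word sharing its
#' `align_id` (the overt translation of its chunk).  Its contribution while
#' buffered is
#' \describe{
#'   \item{CW}{1 for content words (function words contribute 0),}
#'   \item{CL}{the min-max normalized log corpus frequency of its lemma
#'     (content words only by default),}
#'   \item{SYL}{its syllable count (all words by default).}
#' }
#' Breakpoints are emitted at every entry/clear event (simultaneous events
#' coalesced to the net load) and the series is linear between breakpoints.
#' Source words that were never translated (no matching target chunk) have
#' no observable clear time and are excluded; they are reported in the
#' `coverage` attribute of the result.
#'
#' @param source,target aligned source/target [Transcript-class] objects.
#' @param method `"CW"`, `"CL"` or `"SYL"`.
#' @param ftable [FrequencyTable-class]; required for CL.
#' @param wordScope `"methods"` (default: CL counts content words, SYL all
#'   words) or `"alternate"` (the swapped reading: CL all words, SYL content
#'   words only).
#' @param invertClWeight if TRUE, CL uses `1 - fhat` so rarer words weigh
#'   more; default FALSE applies the normalization as printed, where more
#'   frequent words weigh more.
#' @param subject subject label carried into the result.
#' @param warn warn about out-of-vocabulary lemmas.
#' @return A [LoadSeries-class] with a `coverage` attribute
#'   (list: `counted`, `omitted`, `anticipated`).
#' @export
computeLoadSeries <- function(source, target, method = c("CW", "CL", "SYL"),
                              ftable = NULL,
                              wordScope = c("methods", "alternate"),
                              invertClWeight = FALSE,
                              subject = "s01", warn = TRUE) {
  method <- match.arg(method)
  wordScope <- match.arg(wordScope)
  stopifnot(is(source, "Transcript"), is(target, "Transcript"))
  if (method == "CL" && is.null(ftable))
    stop("CL weighting requires a frequency table")

  sw <- source@words
  tw <- target@words
  t_ids <- tw$align_id[!is.na(tw$align_id)]
  if (length(setdiff(t_ids, sw$align_id)))
    stop("align_id present in target but absent in source: ",
         paste(utils::head(setdiff(t_ids, sw$align_id), 5), collapse = ", "))

  # observable clear time: offset of the last target word of the chunk
  clear_by_id <- if (length(t_ids))
    tapply(tw$offset[!is.na(tw$align_id)], t_ids, max) else numeric()
  clear <- unname(clear_by_id[as.character(sw$align_id)])

  scope_content <- switch(method,
    CW = TRUE,
    CL = wordScope == "methods",
    SYL = wordScope == "alternate")
  in_scope <- if (scope_content) sw$word_class == "content" else rep(TRUE, nrow(sw))

  w <- numeric(nrow(sw))
  if (method == "CW") {
    w[in_scope] <- 1
  } else if (method == "CL") {
    fhat <- lemmaWeight(.norm_token(sw$lemma[in_scope]), ftable, warn = warn)
    w[in_scope] <- if (invertClWeight) 1 - fhat else fhat
  } else {
    w[in_scope] <- vapply(sw$surface[in_scope], countSyllables,
                          integer(1), language = source@language)
  }

  counted <- in_scope & !is.na(clear) & w > 0
  omitted <- in_scope & is.na(clear)
  anticipated <- counted & clear <= sw$offset
  use <- counted & !anticipated

  if (!any(use)) {
    out <- new("LoadSeries", method = method, time = 0, load = 0,
               direction = source@direction, subject = subject)
  } else {
    ev_t <- c(sw$offset[use], clear[use])
    ev_d <- c(w[use], -w[use])
    agg <- tapply(ev_d, ev_t, sum)                    # coalesce simultaneous events
    tt <- as.numeric(names(agg))
    o <- order(tt)
    load <- cumsum(as.numeric(agg)[o])
    load[abs(load) < 1e-12] <- 0                      # float dust at full clears
    tt <- tt[o]
    if (tt[1L] > 0) { tt <- c(0, tt); load <- c(0, load) }
    out <- new("LoadSeries", method = method, time = tt, load = load,
               direction = source@direction, subject = subject)
  }
  attr(out, "coverage") <- list(counted = sum(use), omitted = sum(omitted),
                                anticipated = sum(anticipated))
  out
}

#' Interpolate a load series at arbitrary times
#'
#' Linear interpolation between bracketing breakpoints; outside the
#' breakpoint range the series is clamped to the nearest endpoint value.
#'
#' @param series a [LoadSeries-class].
#' @param times numeric vector of query times (seconds), sorted.
#' @return numeric vector of load values, same length as `times`.
#' @export
interpolateLoad <- function(series, times) {
  stopifnot(is(series, "LoadSeries"))
  if (is.unsorted(times)) stop("query times must be sorted")
  if (length(series@time) == 1L)
    return(rep(series@load, length(times)))
  stats::approx(series@time, series@load, xout = times, rule = 2)$y
}

#' Label load values by within-scope quantiles
#'
#' An observation is `low` if its load is strictly below the `qLow` sample
#' quantile, `high` if strictly above the `qHigh` quantile, else `medium`.
#' Quantiles use the linear-interpolation estimator
#' (`stats::quantile(type = 7)`) and are meant to be computed within one
#' subject and one direction of interpretation; callers provide loads
#' already restricted to that scope.
#'
#' @param loads numeric vector of load values.
#' @param qLow,qHigh boundary quantile probabilities, `0 < qLow < qHigh < 1`
#'   (defaults 0.10 and 0.90).
#' @return factor with levels `low`, `medium`, `high`.
#' @export
labelByQuantile <- function(loads, qLow = 0.10, qHigh = 0.90) {
  stopifnot(is.numeric(loads), qLow > 0, qHigh < 1, qLow < qHigh)
  if (length(loads) < 10L)
    warning("fewer than 10 load values; quantile boundaries will be unstable")
  q <- stats::quantile(loads, c(qLow, qHigh), names = FALSE, type = 7)
  factor(ifelse(loads < q[1L], "low", ifelse(loads > q[2L], "high", "medium")),
         levels = c("low", "medium", "high"))
}

#' Median load at probe onsets per subject, direction and method
#'
#' Interpolates each session's load series at its probe onsets and takes
#' the median — the behavioral summary feeding the direction contrast
#' (Wilcoxon signed-rank test).  Subjects missing either direction are
#' dropped with a warning.
#'
#' @param sessions list of records, each a list with elements `series`
#'   (a [LoadSeries-class]) and `probes` (a [ProbeTrain-class]).
#' @return data.frame: `subject`, `direction`, `method`, `median_load`.
#' @export
medianLoads <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    stopifnot(is(s$series, "LoadSeries"), is(s$probes, "ProbeTrain"))
    data.frame(subject = s$series@subject, direction = s$series@direction,
               method = s$series@method,
               median_load = stats::median(
                 interpolateLoad(s$series, probeOnsets(s$probes))))
  })
  tab <- do.call(rbind, rows)
  have <- table(unique(tab[c("subject", "direction")])$subject)
  incomplete <- names(have)[have < 2L]
  if (length(incomplete)) {
    warning("dropping subject(s) missing a direction: ",
            paste(incomplete, collapse = ", "))
    tab <- tab[!tab$subject %in% incomplete, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Paired direction contrast of median loads
#'
#' Runs the exact Wilcoxon signed-rank test on per-subject median loads,
#' pairing L1->L2 against L2->L1 within one estimation method.
#'
#' @param medians output of [medianLoads()].
#' @param method `"CW"`, `"CL"` or `"SYL"`.
#' @return A `wilcoxonExact` result (class `htest`).
#' @export
directionContrast <- function(medians, method = c("CW", "CL", "SYL")) {
  method <- match.arg(method)
  m <- medians[medians$method == method, ]
  wide <- stats::reshape(m[c("subject", "direction", "median_load")],
                         idvar = "subject", timevar = "direction",
                         direction = "wide")
  x <- wide$median_load.L1toL2
  y <- wide$median_load.L2toL1
  if (anyNA(x) || anyNA(y)) stop("both directions required for every subject")
  wilcoxonExact(x, y)
}
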