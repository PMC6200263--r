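#' Null distribution of the signed-rank statistic
#'
#' Counts, for ranks `1..n`, how many of the `2^n` sign assignments yield
#' each possible positive-rank sum `V = 0 .. n(n+1)/2`, by polynomial
#' convolution (equivalent to full enumeration).
#'
#' @param n number of non-zero paired differences.
#' @return numeric vector of counts, index `v + 1` holding the count for
#'   sum `v`; sums to `2^n`.
#' @export
wilcoxonNullDistribution <- function(n) {
  stopifnot(n >= 1, n <= 30)
  maxv <- n * (n + 1) / 2
  f <- c(1, numeric(maxv))
  for (r in seq_len(n)) {
    g <- f
    g[(r + 1):(maxv + 1)] <- g[(r + 1):(maxv + 1)] + f[1:(maxv + 1 - r)]
    f <- g
  }
  f
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test.  Zero differences are dropped; with
#' no ties and at most 25 effective pairs, the two-sided p-value is exact,
#' computed from the full null distribution of `V` over all `2^n` sign
#' assignments.  With ties among the absolute differences, or more than 25
#' pairs, mid-ranks and a tie-corrected normal approximation with
#' continuity correction are used instead, with a warning.
#'
#' @param x,y paired numeric vectors; `y` may be omitted to test the
#'   differences in `x` against zero.
#' @return An object of class `c("wilcoxonExact", "htest")` with `statistic`
#'   (`V`, the sum of ranks of positive differences), `p.value`,
#'   `parameter` (`n_effective`) and `method` (`"exact"` or
#'   `"normal-approx"`).
#' @examples
#' wilcoxonExact(1:9, rep(0, 9))  # V = 45, p = 0.003906
#' @export
wilcoxonExact <- function(x, y = NULL) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    d <- x - y
  } else d <- x
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    counts <- wilcoxonNullDistribution(n)
    total <- sum(counts)
    lo <- sum(counts[seq_len(V + 1)]) / total          # P(V <= v)
    hi <- sum(counts[(V + 1):length(counts)]) / total  # P(V >= v)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    warning(if (ties) "ties present; " else "n > 25; ",
            "using normal approximation")
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)            # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(
    list(statistic = c(V = V), p.value = p,
         parameter = c(n_effective = n), method = method,
         alternative = "two.sided",
         data.name = "paired differences"),
    class = c("wilcoxonExact", "htest"))
}

# orthonormalized helmert contrasts for a k-level factor
.ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon for one within-subject effect.
# Y: subjects x cells matrix (cells in expand.grid order over `levels_list`,
# first factor fastest); `in_effect`: logical, which factors span the effect.
.gg_epsilon <- function(Y, levels_list, in_effect) {
  mats <- mapply(function(lv, use) {
    k <- length(lv)
    if (use) .ortho_contrasts(k) else matrix(1 / k, k, 1)
  }, levels_list, in_effect, SIMPLIFY = FALSE)
  M <- Reduce(kronecker, rev(mats))
  d <- ncol(M)
  if (d == 1L) return(1)
  S <- stats::cov(Y %*% M)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  min(1, max(1 / d, eps))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Full-factorial within-subject ANOVA on a long table, with one error
#' term per effect (the effect-by-subject interaction).  For every effect
#' the table reports the uncorrected F, dfs and p, partial eta squared,
#' the Greenhouse-Geisser epsilon estimated from the covariance of the
#' orthonormalized within-subject contrasts, and the epsilon-corrected dfs
#' and p.  Observations are first averaged to one value per subject and
#' design cell; a missing subject-by-cell value is imputed by that cell's
#' mean over the remaining subjects, with a warning.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns, e.g.
#'   `c("direction", "load", "anteriority", "laterality")`.
#' @param subject name of the subject-id column.
#' @return data.frame of class `c("anovaTable", "data.frame")`: one row per
#'   effect with `effect`, `df_num`, `df_den`, `F`, `p`, `pes`,
#'   `gg_epsilon`, `df_num_gg`, `df_den_gg`, `p_gg`.
#' @export
rmAnova <- function(data, dv, within, subject = "subject") {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  data <- as.data.frame(data)
  for (v in c(within, subject)) data[[v]] <- factor(data[[v]])
  subjects <- levels(data[[subject]])
  if (length(subjects) < 3L) stop("repeated-measures ANOVA needs >= 3 subjects")

  levels_list <- lapply(data[within], levels)
  grid <- do.call(expand.grid,
                  c(levels_list, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  cell_key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  cells <- do.call(paste, c(grid, sep = "\r"))
  key <- factor(cell_key(data), levels = cells)
  if (anyNA(key)) stop("internal: unmapped design cell")

  # subjects x cells matrix of cell means
  Y <- tapply(data[[dv]], list(data[[subject]], key), mean)
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    cell_means <- colMeans(Y, na.rm = TRUE)
    if (anyNA(cell_means[miss[, 2]]))
      stop("design cell empty for all subjects; cannot impute")
    warning(nrow(miss), " missing subject-by-cell value(s) imputed by cell mean")
    Y[miss] <- cell_means[miss[, 2]]
  }

  long <- data.frame(grid[rep(seq_len(nrow(grid)), each = length(subjects)), ,
                          drop = FALSE],
                     .subj = factor(rep(subjects, nrow(grid))),
                     .y = as.vector(Y))
  for (v in within) long[[v]] <- factor(long[[v]], levels = levels_list[[v]])
  fml <- stats::as.formula(paste(
    ".y ~", paste(within, collapse = "*"),
    "+ Error(.subj/(", paste(within, collapse = "*"), "))"))
  fit <- stats::aov(fml, data = long)
  strata <- summary(fit)

  rows <- list()
  for (snm in names(strata)) {
    tab <- strata[[snm]][[1L]]
    terms <- trimws(rownames(tab))
    eff_idx <- which(terms != "Residuals")
    if (!length(eff_idx)) next
    res_idx <- which(terms == "Residuals")
    ss_err <- tab[res_idx, "Sum Sq"]
    df_err <- tab[res_idx, "Df"]
    for (i in eff_idx) {
      eff <- terms[i]
      facs <- strsplit(eff, ":", fixed = TRUE)[[1L]]
      ss <- tab[i, "Sum Sq"]
      df1 <- tab[i, "Df"]
      if (ss <= 1e-12 * max(1, ss_err)) {
        Fv <- 0; p <- 1
      } else {
        Fv <- (ss / df1) / (ss_err / df_err)
        p <- stats::pf(Fv, df1, df_err, lower.tail = FALSE)
      }
      eps <- .gg_epsilon(Y, levels_list, within %in% facs)
      p_gg <- if (Fv == 0) 1 else
        stats::pf(Fv, df1 * eps, df_err * eps, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = paste(facs, collapse = ":"),
        df_num = df1, df_den = df_err, F = Fv, p = p,
        pes = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
        gg_epsilon = eps, df_num_gg = df1 * eps, df_den_gg = df_err * eps,
        p_gg = p_gg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anovaTable", "data.frame")
  out
}

#' Leave-one-out jackknife over subjects
#'
#' Repeats an analysis on every subset that drops one subject, to check
#' that a result is not driven by a single participant.
#'
#' @param data long-format data.frame with a subject column.
#' @param analysis function(data-subset) returning either an `htest` or an
#'   `anovaTable` from [rmAnova()].
#' @param subject name of the subject-id column.
#' @param effect for `anovaTable` results, the effect whose p-value is
#'   monitored (e.g. `"load"`); ignored for `htest` results.
#' @param alpha significance level for the consistency verdict.
#' @param useGG use the Greenhouse-Geisser corrected p (default) for
#'   `anovaTable` results.
#' @return list of class `"decalageJackknife"`: `p` (named vector of
#'   per-resample p-values, `NA` where the analysis failed), `results`
#'   (per-resample raw results), `errors`, and `consistent` (TRUE iff the
#'   effect is significant at `alpha` in every successful resample).
#' @export
jackknifeSubjects <- function(data, analysis, subject = "subject",
                              effect = NULL, alpha = 0.05, useGG = TRUE) {
  subjects <- unique(as.character(data[[subject]]))
  if (length(subjects) < 3L) stop("jackknife needs >= 3 subjects")
  res <- vector("list", length(subjects))
  errs <- vector("list", length(subjects))
  p <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  for (i in seq_along(subjects)) {
    sub <- data[data[[subject]] != subjects[i], , drop = FALSE]
    r <- tryCatch(analysis(sub), error = function(e) e)
    if (inherits(r, "error")) { errs[[i]] <- conditionMessage(r); next }
    res[[i]] <- r
    p[i] <- if (inherits(r, "htest")) r$p.value
    else if (inherits(r, "anovaTable")) {
      stopifnot(!is.null(effect))
      row <- r[r$effect == effect, ]
      if (!nrow(row)) stop("effect not found: ", effect)
      if (useGG) row$p_gg else row$p
    } else as.numeric(r)
  }
  structure(list(p = p, results = res, errors = errs,
                 alpha = alpha,
                 consistent = all(p[!is.na(p)] <= alpha) && !anyNA(p)),
            class = "decalageJackknife")
}

#' @export
print.decalageJackknife <- function(x, ...) {
  cat(sprintf("Leave-one-out jackknife over %d subjects (alpha = %g)\n",
              length(x$p), x$alpha))
  print(signif(x$p, 4))
  cat(if (isTRUE(x$consistent)) "Effect significant in every resample.\n"
      else "Effect NOT significant in every resample.\n")
  invisible(x)
}
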