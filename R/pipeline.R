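#' Run the full simulate -> load -> ERP -> stats pipeline
#'
#' Orchestrates a reproducible end-to-end run on a simulated cohort:
#' generates each subject's two sessions, estimates the working-memory
#' load series per method, interpolates loads at probe onsets, labels
#' epochs by per-subject-and-direction load quantiles, preprocesses and
#' epochs the EEG, summarizes P1/N1 window measures, and runs the
#' behavioral Wilcoxon contrast, the repeated-measures ANOVAs and the
#' leave-one-out jackknife.  All outputs are CSV/JSON files listed, with
#' content hashes, in `manifest.json`; reruns with the same config are
#' bit-identical.
#'
#' @param config a list or the path of a YAML file.  Recognized top-level
#'   fields: `seed`, `out_dir`, `methods` (subset of CW/CL/SYL), `q_low`,
#'   `q_high`, `reject_ptp` (microvolts or NULL), `word_scope`
#'   (`"methods"`/`"alternate"`), `invert_cl_weight`, `use_gg`, and `sim`
#'   (arguments for [simConfig()]).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with `medians`, `wilcoxon`, `summary`,
#'   `anova`, `jackknife`, `manifest`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      .write_manifest(cfg, outputs)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say("stage %-12s done in %.1f s", name,
        as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  sim <- do.call(simConfig, c(list(seed = cfg$seed), cfg$sim))
  sessions <- stage("simulate+erp", {
    recs <- list()
    for (i in seq_len(sim$nSubjects)) {
      for (d in .DIRECTIONS) {
        s <- simulateSession(sim, subject = sprintf("s%02d", i),
                             direction = d,
                             seed = .derive_seed(cfg$seed, i,
                                                 match(d, .DIRECTIONS)))
        clean <- preprocessEEG(s$eeg)
        ep <- epochEEG(clean, s$probes, loads = s$loads,
                       rejectPtP = cfg$reject_ptp,
                       subject = s$subject, direction = d)
        per_method <- list()
        for (m in cfg$methods) {
          series <- computeLoadSeries(s$source, s$target, method = m,
                                      ftable = s$ftable,
                                      wordScope = cfg$word_scope,
                                      invertClWeight = cfg$invert_cl_weight,
                                      subject = s$subject, warn = FALSE)
          lv <- interpolateLoad(series, ep@info$probe_onset)
          labels <- labelByQuantile(lv, cfg$q_low, cfg$q_high)
          epm <- ep
          epm@info$load <- lv
          epm@info$label <- as.character(labels)
          per_method[[m]] <- list(series = series,
                                  summary = summarizeErp(epm))
        }
        recs[[length(recs) + 1L]] <- list(
          subject = s$subject, direction = d, probes = s$probes,
          dropped = attr(ep, "dropped"), per_method = per_method)
      }
    }
    recs
  })

  medians <- stage("medians", {
    recs <- unlist(lapply(sessions, function(s)
      lapply(cfg$methods, function(m)
        list(series = s$per_method[[m]]$series, probes = s$probes))),
      recursive = FALSE)
    medianLoads(recs)
  })
  f_med <- file.path(cfg$out_dir, "median_loads.csv")
  utils::write.csv(medians, f_med, row.names = FALSE)
  outputs <- c(outputs, f_med)

  wres <- stage("wilcoxon", {
    lapply(stats::setNames(cfg$methods, cfg$methods), function(m)
      directionContrast(medians, m))
  })
  f_w <- file.path(cfg$out_dir, "wilcoxon.csv")
  utils::write.csv(data.frame(
    method = names(wres),
    V = vapply(wres, function(w) unname(w$statistic), numeric(1)),
    p = vapply(wres, function(w) w$p.value, numeric(1)),
    n = vapply(wres, function(w) unname(w$parameter), numeric(1)),
    test = vapply(wres, function(w) w$method, character(1))),
    f_w, row.names = FALSE)
  outputs <- c(outputs, f_w)

  summary_tab <- stage("summarize", {
    tab <- do.call(rbind, unlist(lapply(sessions, function(s)
      lapply(cfg$methods, function(m)
        cbind(method = m, s$per_method[[m]]$summary))),
      recursive = FALSE))
    addTopography(tab)
  })
  f_s <- file.path(cfg$out_dir, "erp_summary.csv")
  utils::write.csv(summary_tab, f_s, row.names = FALSE)
  outputs <- c(outputs, f_s)

  anovas <- stage("anova", {
    out <- list()
    for (m in cfg$methods) for (comp in c("P1", "N1"))
      for (dv in c("amplitude_uv", "latency_ms")) {
        d <- summary_tab[summary_tab$method == m &
                           summary_tab$component == comp, ]
        d$load <- d$condition
        a <- rmAnova(d, dv = dv,
                     within = c("direction", "load", "anteriority",
                                "laterality"))
        key <- sprintf("%s_%s_%s", comp, m,
                       if (dv == "amplitude_uv") "amplitude" else "latency")
        f <- file.path(cfg$out_dir, sprintf("anova_%s.csv", key))
        utils::write.csv(a, f, row.names = FALSE)
        outputs <- c(outputs, f)
        out[[key]] <- a
      }
    out
  })

  jk <- stage("jackknife", {
    m <- cfg$methods[1]
    d <- summary_tab[summary_tab$method == m & summary_tab$component == "N1", ]
    d$load <- d$condition
    jackknifeSubjects(
      d, function(sub) rmAnova(sub, "amplitude_uv",
                               within = c("direction", "load", "anteriority",
                                          "laterality")),
      effect = "load", useGG = cfg$use_gg)
  })
  f_j <- file.path(cfg$out_dir, "jackknife.csv")
  utils::write.csv(data.frame(left_out = names(jk$p), p_load = unname(jk$p),
                              consistent = jk$consistent),
                   f_j, row.names = FALSE)
  outputs <- c(outputs, f_j)

  manifest <- .write_manifest(cfg, outputs)
  say("pipeline complete: %d output files in %s", length(outputs), cfg$out_dir)
  invisible(list(medians = medians, wilcoxon = wres, summary = summary_tab,
                 anova = anovas, jackknife = jk, manifest = manifest))
}

.pipeline_config <- function(config) {
  defaults <- list(seed = 1L, out_dir = "decalage-run",
                   methods = c("CW", "CL", "SYL"),
                   q_low = 0.10, q_high = 0.90, reject_ptp = 150,
                   word_scope = "methods", invert_cl_weight = FALSE,
                   use_gg = TRUE, sim = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$methods, .METHODS)
  if (length(bad))
    stop("unknown load-estimation method(s): ", paste(bad, collapse = ", "))
  bad_sim <- setdiff(names(cfg$sim), names(formals(simConfig)))
  if (length(bad_sim))
    stop("unknown sim field(s): ", paste(bad_sim, collapse = ", "))
  stopifnot(cfg$q_low > 0, cfg$q_high < 1, cfg$q_low < cfg$q_high)
  cfg
}

.write_manifest <- function(cfg, outputs) {
  manifest <- list(
    package = "decalage",
    version = as.character(utils::packageVersion("decalage")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    files = if (length(outputs)) data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs))) else list())
  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
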