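# End-to-end orchestration: TCT -> microstate cross-validation + clustering ->
# fitting / parameter tests -> TANOVA + duration control -> t-maps -> source
# statistics -> windowed ROI Bayes factors, behind one config object with a
# single global seed expanded into fixed per-stage seeds.

#' Pipeline configuration
#'
#' Validates every setting before any computation. `n_perm` applies to all
#' randomization tests; alphas default to 0.01 for TCT/TANOVA and 0.05 for
#' the voxel test. With `dataset = NULL` the pipeline simulates a desk-scale
#' source study (`sim_effect` plants the congruency effect).
#'
#' @param dataset path to a [write_study()] directory, or `NULL` to simulate.
#' @param seed global integer seed (mandatory; expanded per stage).
#' @param n_perm randomization runs for all tests (> 0).
#' @param alpha_tct,alpha_tanova,alpha_voxel significance levels.
#' @param k number of microstate maps (`NULL`: choose by cross-validation).
#' @param k_range,cv_reps,n_init cross-validation / clustering settings.
#' @param polarity_sensitive microstate polarity convention.
#' @param fit_mode segmentation mode (see [fit_to_erp()]).
#' @param prior_scale JZS prior scale r.
#' @param sim_effect planted effect when simulating (`"longer"`,
#'   `"stronger"`, `"none"`).
#' @param stages named logical toggles (`tct`, `microstates`, `mstats`,
#'   `tanova`, `tmap`, `source`, `bayes`).
#' @param out optional output directory for TSV stage outputs.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, seed = 1L, n_perm = 500L,
                            alpha_tct = 0.01, alpha_tanova = 0.01,
                            alpha_voxel = 0.05, k = NULL, k_range = 3:8,
                            cv_reps = 20L, n_init = 6L,
                            polarity_sensitive = TRUE,
                            fit_mode = "ordered-contiguous",
                            prior_scale = sqrt(2) / 2,
                            sim_effect = "longer",
                            stages = NULL, out = NULL) {
  if (length(n_perm) != 1L || !is.finite(n_perm) || n_perm < 1L)
    stopf("configuration error: n_perm must be a positive count")
  if (is.null(seed) || !is.finite(seed))
    stopf("configuration error: a seed is mandatory")
  for (a in c(alpha_tct, alpha_tanova, alpha_voxel))
    if (a <= 0 || a >= 1) stopf("configuration error: alpha outside (0, 1)")
  if (!is.null(dataset) && !file.exists(file.path(dataset, "manifest.json")))
    stopf("configuration error: dataset path '%s' has no manifest", dataset)
  if (cv_reps < 1L || n_init < 1L)
    stopf("configuration error: counts must be positive")
  if ((n_perm + 1) * min(alpha_tct, alpha_tanova) < 1)
    warning(sprintf("with n_perm = %d the smallest attainable p is %.4g; no timepoint can reach alpha = %g",
                    as.integer(n_perm), 1 / (n_perm + 1),
                    min(alpha_tct, alpha_tanova)), call. = FALSE)
  st <- list(tct = TRUE, microstates = TRUE, mstats = TRUE, tanova = TRUE,
             tmap = TRUE, source = TRUE, bayes = TRUE)
  for (nm in names(stages)) {
    if (!nm %in% names(st)) stopf("configuration error: unknown stage '%s'", nm)
    st[[nm]] <- isTRUE(stages[[nm]])
  }
  structure(list(dataset = dataset, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), alpha_tct = alpha_tct,
                 alpha_tanova = alpha_tanova, alpha_voxel = alpha_voxel,
                 k = k, k_range = k_range, cv_reps = as.integer(cv_reps),
                 n_init = as.integer(n_init),
                 polarity_sensitive = polarity_sensitive,
                 fit_mode = fit_mode, prior_scale = prior_scale,
                 sim_effect = sim_effect, stages = st, out = out),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a loaded or simulated study
#' and assembles a run report: per-condition microstate parameter table,
#' parameter-test p values, TANOVA significant windows after duration
#' control, the post-hoc t-map of the first significant window, source-level
#' voxel statistics and window-wise ROI Bayes factors, plus the overlap of
#' TANOVA windows with microstate windows. The report payload is a pure
#' function of config + seed (stage wall times live in the separate `log`
#' element).
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log <- list()
  note <- function(stage, t0) {
    log[[stage]] <<- list(stage = stage, wall_s = as.numeric(Sys.time()) - t0)
  }
  report <- list(provenance = list(
    config = unclass(config), seed = seed,
    version = as.character(utils::packageVersion("erpmicro"))))

  headmodel <- operator <- truth <- NULL
  t0 <- as.numeric(Sys.time())
  if (is.null(config$dataset)) {
    cfg <- sim_config(seed = seed)
    headmodel <- make_toy_headmodel(cfg$n_channels, c(5L, 5L, 3L),
                                    seed = stage_seed(seed, "simulate"))
    sim <- simulate_source_study(headmodel, effect = config$sim_effect,
                                 cfg = cfg)
    ds <- sim$dataset
    truth <- sim$truth
  } else {
    ds <- read_study(config$dataset)
  }
  note("load", t0)
  n_t <- dim(ds$data)[2L]

  if (config$stages$tct) {
    t0 <- as.numeric(Sys.time())
    report$tct <- lapply(CELLS, function(cell) {
      out <- tct(ds, cell, n_perm = config$n_perm, alpha = config$alpha_tct,
                 seed = stage_seed(seed, "tct"))
      dc <- duration_control(out)
      list(cell = cell, p = out$p, significant_runs = dc$significant_runs,
           duration_threshold = dc$duration_threshold)
    })
    names(report$tct) <- CELLS
    note("tct", t0)
  }

  model <- NULL
  if (config$stages$microstates) {
    t0 <- as.numeric(Sys.time())
    if (is.null(config$k)) {
      cv <- cross_validate_k(ds, config$k_range, reps = config$cv_reps,
                             n_init = config$n_init,
                             polarity_sensitive = config$polarity_sensitive,
                             seed = stage_seed(seed, "cv"))
      report$cv <- list(k_range = cv$k_range, mean_test_gev = cv$mean,
                        chosen_k = cv$chosen_k)
      k <- cv$chosen_k
    } else k <- config$k
    Xall <- do.call(cbind, lapply(CELLS, function(cell)
      grand_mean(ds, cells = cell)$values))
    model <- cluster_kmeans(Xall, k, n_init = max(config$n_init, 10L),
                            polarity_sensitive = config$polarity_sensitive,
                            seed = stage_seed(seed, "cluster"),
                            blocks = rep(1:4, each = n_t))
    seg <- list(
      congruent = fit_to_erp(model, grand_mean(ds, cells = c("cC", "wC")),
                             mode = config$fit_mode),
      incongruent = fit_to_erp(model, grand_mean(ds, cells = c("cI", "wI")),
                               mode = config$fit_mode))
    report$model <- list(k = k, maps = model$maps,
                         gev_train = model$gev_train)
    report$segmentation <- lapply(seg, `[[`, "params")
    note("microstates", t0)
  }

  if (config$stages$mstats && !is.null(model)) {
    t0 <- as.numeric(Sys.time())
    mt <- microstate_param_test(ds, model, effect = "congruency",
                                n_perm = config$n_perm,
                                seed = stage_seed(seed, "mstats"))
    report$mstats <- list(p = mt$p, observed = mt$observed)
    note("mstats", t0)
  }

  dc <- NULL
  if (config$stages$tanova) {
    t0 <- as.numeric(Sys.time())
    tan <- tanova(ds, "congruency", n_perm = config$n_perm,
                  alpha = config$alpha_tanova,
                  seed = stage_seed(seed, "tanova"))
    dc <- duration_control(tan)
    report$tanova <- list(p = tan$p, observed = tan$observed,
                          duration_threshold = dc$duration_threshold,
                          significant_runs = dc$significant_runs,
                          significant_runs_ms = dc$significant_runs *
                            (1000 / ds$sfreq) - (1000 / ds$sfreq) + ds$t0)
    note("tanova", t0)
  }

  if (config$stages$tmap && !is.null(dc) && nrow(dc$significant_runs) > 0L) {
    t0 <- as.numeric(Sys.time())
    run1 <- dc$significant_runs[1L, ]
    sel <- run1["start"]:(run1["end"] - 1L)
    ns <- length(ds$subjects)
    wavg <- function(cells) vapply(seq_len(ns), function(si)
      rowMeans(apply(ds$data[, sel, si, cells, drop = FALSE],
                     c(1L, 2L), mean)), numeric(dim(ds$data)[1L]))
    tms <- times_ms(n_t, ds$sfreq, ds$t0)
    dt <- 1000 / ds$sfreq
    report$tmap <- tmap(wavg(c("cI", "wI")), wavg(c("cC", "wC")),
                        window = c(tms[run1["start"]],
                                   tms[run1["end"] - 1L] + dt),
                        contrast = c("incongruent", "congruent"))
    note("tmap", t0)
  }

  if (config$stages$source && !is.null(headmodel)) {
    t0 <- as.numeric(Sys.time())
    operator <- build_inverse(headmodel, alpha_reg = 0)
    if (!is.null(dc) && nrow(dc$significant_runs) > 0L) {
      run1 <- dc$significant_runs[1L, ]
      sel <- run1["start"]:(run1["end"] - 1L)
      ns <- length(ds$subjects)
      smap <- function(cells) vapply(seq_len(ns), function(si) {
        m <- apply(ds$data[, , si, cells, drop = FALSE], c(1L, 2L), mean)
        rowMeans(localize(operator, m)$standardized[, sel, drop = FALSE])
      }, numeric(ncol(headmodel$leadfield)))
      report$voxel_test <- voxel_permutation_ttest(
        smap(c("cI", "wI")), smap(c("cC", "wC")),
        n_perm = config$n_perm, alpha = config$alpha_voxel,
        seed = stage_seed(seed, "source"))
    }
    note("source", t0)
  }

  if (config$stages$bayes && !is.null(operator) && !is.null(model)) {
    t0 <- as.numeric(Sys.time())
    report$roi_bayes <- windowed_roi_bayes(
      ds, operator, headmodel$roi$ACC,
      windows = list(congruent = report$segmentation$congruent,
                     incongruent = report$segmentation$incongruent),
      r = config$prior_scale)
    note("bayes", t0)
  }

  if (!is.null(dc) && !is.null(model)) {
    report$window_overlap <- compare_windows(
      dc, report$segmentation, sfreq = ds$sfreq, t0 = ds$t0, n_times = n_t)
  }
  if (!is.null(truth)) report$truth <- truth

  if (!is.null(config$out)) .write_report(report, config$out, ds)
  structure(list(report = report, log = log), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("<run_report>\n")
  if (!is.null(r$cv)) cat(sprintf("  chosen k: %d\n", r$cv$chosen_k))
  if (!is.null(r$tanova))
    cat(sprintf("  TANOVA significant windows: %d (duration threshold %s samples)\n",
                nrow(r$tanova$significant_runs),
                format(r$tanova$duration_threshold)))
  if (!is.null(r$roi_bayes))
    cat(sprintf("  ROI BF01 range: [%.2f, %.2f]\n",
                min(r$roi_bayes$bf01), max(r$roi_bayes$bf01)))
  invisible(x)
}

#' Overlap of significant TANOVA windows with microstate windows
#'
#' For every duration-surviving TANOVA window, reports which microstate maps'
#' condition windows intersect it and by what fraction of the window.
#'
#' @param dc a [duration_control()] result (sample-index windows).
#' @param segmentation named list of per-condition segmentation parameter
#'   tables (columns map, onset, offset in ms).
#' @param sfreq,t0,n_times time axis of the tested epoch.
#' @return data frame: window, condition, map, overlap_ms, overlap_fraction.
#' @export
compare_windows <- function(dc, segmentation, sfreq, t0 = 0, n_times) {
  stopifnot(inherits(dc, "duration_control"))
  dt <- 1000 / sfreq
  runs <- dc$significant_runs
  if (nrow(runs) == 0L)
    return(data.frame(window = integer(), condition = character(),
                      map = integer(), overlap_ms = numeric(),
                      overlap_fraction = numeric()))
  out <- list()
  for (ri in seq_len(nrow(runs))) {
    w0 <- t0 + (runs[ri, "start"] - 1L) * dt
    w1 <- t0 + (runs[ri, "end"] - 1L) * dt
    for (cond in names(segmentation)) {
      par <- segmentation[[cond]]
      if (max(par$offset) < w1 - 1e-9 || min(par$onset) > w0 + 1e-9)
        stopf("segmentation time axis does not cover the TANOVA window")
      ov <- pmax(0, pmin(par$offset, w1) - pmax(par$onset, w0))
      keep <- ov > 0
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          window = ri, condition = cond, map = par$map[keep],
          overlap_ms = ov[keep], overlap_fraction = ov[keep] / (w1 - w0))
    }
  }
  do.call(rbind, out)
}

# TSV dump of the main report tables.
.write_report <- function(report, dir, ds) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(report$segmentation)) {
    write_segmentation(list(params = report$segmentation[[cond]]),
                       file.path(dir, sprintf("segmentation_%s.tsv", cond)),
                       condition = cond)
  }
  if (!is.null(report$mstats)) {
    utils::write.table(cbind(map = seq_len(nrow(report$mstats$p)),
                             as.data.frame(report$mstats$p)),
                       file.path(dir, "mstats_p.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$tanova)) {
    utils::write.table(data.frame(time_ms = times_ms(length(report$tanova$p),
                                                     ds$sfreq, ds$t0),
                                  observed = report$tanova$observed,
                                  p = report$tanova$p),
                       file.path(dir, "tanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$roi_bayes)) {
    utils::write.table(report$roi_bayes, file.path(dir, "roi_bayes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
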