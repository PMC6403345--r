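# Randomization statistics for within-subject 2x2 factorial ERP designs,
# applied point-wise over time: topographic consistency test (TCT),
# topographic analysis of variance (TANOVA), duration-based multiple-testing
# control, and randomization tests on microstate parameters.
#
# All p values use the +1 convention p = (#{perm >= obs} + 1) / (n_perm + 1)
# (ties count as exceeding; p is never exactly 0). Each randomization run
# applies one shuffle per subject consistently across all timepoints, so the
# retained run x timepoint statistics preserve the temporal structure the
# duration control needs.

# Contrast weights over the canonical cell order (cC, cI, wC, wI). The GFP
# of the effect topography is sign-invariant, so the orientation convention
# (incongruent minus congruent; word minus color) does not affect the tests.
effect_weights <- function(effect = c("congruency", "task", "interaction")) {
  effect <- match.arg(effect)
  switch(effect,
         congruency  = c(cC = -0.5, cI = 0.5, wC = -0.5, wI = 0.5),
         task        = c(cC = -0.5, cI = -0.5, wC = 0.5, wI = 0.5),
         interaction = c(cC = -1, cI = 1, wC = 1, wI = -1))
}

# One within-subject label shuffle per run. scheme "full" permutes all four
# cell labels; "paired_swap" flips the two levels of the tested factor
# jointly across the other factor (one coin per subject), the restricted
# group matched by exhaustive enumeration on small designs.
.perm_indices <- function(n_subjects, n_perm, scheme, effect, exhaustive) {
  swap_of <- function(effect) switch(effect,
                                     congruency = c(2L, 1L, 4L, 3L),
                                     task = c(3L, 4L, 1L, 2L),
                                     interaction = c(2L, 1L, 4L, 3L))
  if (exhaustive) {
    if (scheme == "paired_swap") {
      n_tot <- 2^n_subjects
      if (n_tot > 65536) stopf("exhaustive enumeration too large")
      sw <- swap_of(effect)
      lapply(seq_len(n_tot) - 1L, function(code) {
        vapply(seq_len(n_subjects), function(s)
          if (bitwAnd(code, bitwShiftL(1L, s - 1L)) > 0L) sw else 1:4,
          integer(4))
      })
    } else {
      perms4 <- .all_perms4()
      n_tot <- 24^n_subjects
      if (n_tot > 65536) stopf("exhaustive enumeration too large")
      lapply(seq_len(n_tot) - 1L, function(code) {
        vapply(seq_len(n_subjects), function(s) {
          perms4[[(code %/% 24^(s - 1L)) %% 24L + 1L]]
        }, integer(4))
      })
    }
  } else {
    sw <- swap_of(effect)
    lapply(seq_len(n_perm), function(r) {
      if (scheme == "paired_swap") {
        vapply(seq_len(n_subjects), function(s)
          if (stats::runif(1) < 0.5) sw else 1:4, integer(4))
      } else {
        vapply(seq_len(n_subjects), function(s) sample(4L), integer(4))
      }
    })
  }
}

.all_perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b)))
    out[[length(out) + 1L]] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
  out
}

.make_outcome <- function(observed, perm_stats, n_perm, alpha, seed,
                          exhaustive = FALSE) {
  # ">=" with a relative tolerance so that exact ties (e.g. degenerate
  # designs where every shuffle reproduces the observed statistic up to
  # floating-point noise) count as exceeding
  thr <- observed * (1 - 1e-9) - 1e-12
  if (exhaustive) {
    # identity permutation is enumerated: p = #{perm >= obs} / N
    p <- (colSums(sweep(perm_stats, 2L, thr, `>=`))) / nrow(perm_stats)
  } else {
    p <- (colSums(sweep(perm_stats, 2L, thr, `>=`)) + 1) / (n_perm + 1)
  }
  structure(list(observed = observed, p = p, perm_stats = perm_stats,
                 n_perm = nrow(perm_stats), alpha = alpha, seed = seed,
                 exhaustive = exhaustive),
            class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat(sprintf("<permutation_outcome> %d timepoints, %d runs, alpha = %g; %d point(s) with p < alpha\n",
              length(x$observed), x$n_perm, x$alpha, sum(x$p < x$alpha)))
  invisible(x)
}

#' Topographic consistency test
#'
#' Tests, at every timepoint, whether the subjects share a consistent scalp
#' topography: the observed statistic is the GFP of the across-subject
#' grand-mean map, and the null distribution is built by shuffling the
#' electrode values within every subject's data (one spatial permutation per
#' subject per run, applied at all timepoints) and recomputing the grand-mean
#' GFP. Consistent topographies survive averaging; shuffled ones cancel.
#'
#' @param ds a [study_dataset()].
#' @param cell design cell to test (`"cC"`, `"cI"`, `"wC"`, `"wI"`).
#' @param n_perm randomization runs.
#' @param alpha significance threshold carried into [duration_control()].
#' @param seed integer seed.
#' @param normalize scale each subject map to GFP 1 per timepoint first
#'   (default off).
#' @return a `permutation_outcome` (observed GFP, p per timepoint, retained
#'   run statistics).
#' @export
tct <- function(ds, cell = "cC", n_perm = 1000L, alpha = 0.01, seed = 1L,
                normalize = FALSE) {
  stopifnot(inherits(ds, "study_dataset"))
  cell <- match.arg(cell, CELLS)
  X <- ds$data[, , , cell, drop = FALSE]
  dim(X) <- dim(X)[1:3]
  n_ch <- dim(X)[1L]; n_t <- dim(X)[2L]; ns <- dim(X)[3L]
  if (n_ch < 2L) stopf("TCT needs at least 2 channels")
  if (normalize) {
    for (s in seq_len(ns)) {
      g <- gfp(X[, , s])
      if (any(g <= 0)) stopf("flat map for subject %d", s)
      X[, , s] <- sweep(X[, , s], 2L, g, "/")
    }
  }
  observed <- gfp(apply(X, c(1L, 2L), mean))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm_stats <- matrix(NA_real_, n_perm, n_t)
  for (r in seq_len(n_perm)) {
    acc <- matrix(0, n_ch, n_t)
    for (s in seq_len(ns)) acc <- acc + X[sample(n_ch), , s]
    perm_stats[r, ] <- gfp(acc / ns)
  }
  .make_outcome(observed, perm_stats, n_perm, alpha, seed)
}

#' Topographic analysis of variance (TANOVA)
#'
#' Point-wise randomization test on the GFP of the effect topography. Per
#' timepoint: each subject x cell map is (optionally) scaled to GFP 1; the
#' effect topography is the difference of the marginal mean maps (main
#' effects) or the double difference (interaction); the observed statistic is
#' its GFP. The null distribution shuffles the four condition labels within
#' each subject (one shuffle per subject per run, shared by all timepoints)
#' and recomputes the statistic. Normalization makes the test sensitive to
#' topographic (not field-strength) differences.
#'
#' @param ds a [study_dataset()].
#' @param effect `"congruency"`, `"task"` or `"interaction"`.
#' @param n_perm randomization runs.
#' @param alpha significance threshold.
#' @param normalize scale every subject x cell map to GFP 1 per timepoint
#'   (the default, matching amplitude-normalized topographic testing).
#' @param seed integer seed.
#' @param scheme `"full"` (permute all four labels) or `"paired_swap"` (flip
#'   only the tested factor's levels, one coin per subject).
#' @param exhaustive enumerate the whole permutation group instead of
#'   sampling (small designs only); the identity is included, so
#'   `p = #\{perm >= obs\} / N`.
#' @return a `permutation_outcome`.
#' @export
tanova <- function(ds, effect = "congruency", n_perm = 1000L, alpha = 0.01,
                   normalize = TRUE, seed = 1L,
                   scheme = c("full", "paired_swap"), exhaustive = FALSE) {
  stopifnot(inherits(ds, "study_dataset"))
  scheme <- match.arg(scheme)
  w <- effect_weights(effect)
  d <- dim(ds$data)
  n_ch <- d[1L]; n_t <- d[2L]; ns <- d[3L]
  X <- ds$data
  if (normalize) {
    for (s in seq_len(ns)) for (ci in 1:4) {
      g <- gfp(X[, , s, ci])
      if (any(g <= 0)) {
        tbad <- which(g <= 0)[1L]
        stopf("flat map (GFP = 0) for subject %s, cell %s, timepoint %d; cannot normalize",
              ds$subjects[s], CELLS[ci], tbad)
      }
      X[, , s, ci] <- sweep(X[, , s, ci], 2L, g, "/")
    }
  }
  # (ch*T) x (ns*4) layout: flattening the array keeps subjects fastest, so
  # column (c - 1) * ns + s holds subject s, cell c
  V <- matrix(X, n_ch * n_t, ns * 4L)
  stat_of <- function(wmat) {
    # wmat: (ns*4) x m weight matrix -> m statistic series (m x n_t)
    S <- V %*% wmat
    dim(S) <- c(n_ch, n_t * ncol(wmat))
    m <- sqrt(colMeans(S^2))
    matrix(m, ncol(wmat), n_t, byrow = TRUE)
  }
  # physical cell c of subject s carries the label perm[c, s] after the
  # within-subject shuffle, hence the weight w[perm[c, s]] / ns
  weight_vec <- function(perm) as.vector(vapply(1:4, function(ci)
    unname(w[perm[ci, ]]), numeric(ns))) / ns
  observed <- stat_of(matrix(weight_vec(matrix(rep(1:4, ns), 4L)), ncol = 1L))[1L, ]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perms <- .perm_indices(ns, n_perm, scheme, effect, exhaustive)
  n_runs <- length(perms)
  perm_stats <- matrix(NA_real_, n_runs, n_t)
  chunk <- 200L
  for (start in seq(1L, n_runs, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_runs)
    wmat <- vapply(perms[idx], weight_vec, numeric(ns * 4L))
    perm_stats[idx, ] <- stat_of(wmat)
  }
  .make_outcome(observed, perm_stats, n_perm, alpha, seed, exhaustive)
}

#' Duration-based multiple-testing control
#'
#' Controls the family-wise error of a point-wise randomization test over
#' time by requiring significant periods to last longer than chance. Every
#' retained randomization run is ranked against all runs per timepoint,
#' giving a pseudo-p series per run; the longest run of consecutive
#' pseudo-p < alpha is recorded per run, and the duration threshold is the
#' smallest length attained by at most `100 - percentile` percent of runs.
#' Observed significant periods shorter than the threshold are discarded.
#'
#' @param outcome a `permutation_outcome` with retained `perm_stats`.
#' @param alpha point-wise threshold (default: the outcome's alpha).
#' @param percentile control level (default 95: ~5 percent family-wise rate).
#' @return object of class `duration_control`: `duration_threshold`
#'   (samples), `significant_runs` (matrix of half-open `[start, end)` sample
#'   intervals), `maxlens`, `alpha`, `percentile`.
#' @export
duration_control <- function(outcome, alpha = NULL, percentile = 95) {
  stopifnot(inherits(outcome, "permutation_outcome"))
  if (is.null(outcome$perm_stats)) stopf("perm_stats were not retained")
  alpha <- alpha %||% outcome$alpha
  S <- outcome$perm_stats
  R <- nrow(S)
  # pseudo-p of every run, per timepoint: fraction of runs >= it (self included)
  pseudo <- apply(S, 2L, function(v) (R - rank(v, ties.method = "min") + 1) / R)
  maxlens <- apply(pseudo < alpha, 1L, max_run_length)
  tail_prob <- 1 - percentile / 100
  cand <- sort(unique(maxlens))
  thr <- Inf
  for (d0 in c(cand, max(cand) + 1L)) {
    if (mean(maxlens >= d0) <= tail_prob) { thr <- d0; break }
  }
  runs <- true_runs(outcome$p < alpha)
  keep <- (runs[, "end"] - runs[, "start"]) >= thr
  structure(list(duration_threshold = thr,
                 significant_runs = runs[keep, , drop = FALSE],
                 maxlens = maxlens, alpha = alpha, percentile = percentile),
            class = "duration_control")
}

#' @export
print.duration_control <- function(x, ...) {
  cat(sprintf("<duration_control> threshold = %s samples (alpha = %g, percentile = %g); %d run(s) survive\n",
              format(x$duration_threshold), x$alpha, x$percentile,
              nrow(x$significant_runs)))
  invisible(x)
}

#' Randomization test on microstate parameters
#'
#' Tests condition effects on microstate onset, offset, duration and AUC.
#' The fixed prototypes of `model` are refitted (ordered-contiguous) to the
#' grand-mean ERP of each effect level (main effects: the two marginal grand
#' means; interaction: all four cell grand means combined by the double
#' difference) and the observed statistic per map and parameter is the
#' absolute level difference. Permutations shuffle the condition labels
#' within each subject, rebuild the grand means, refit, and recompute. A map
#' left unassigned in a permuted refit contributes the most extreme
#' statistic (+Inf) for that permutation, a conservative convention; under
#' ordered-contiguous fitting every map is always assigned.
#'
#' @param ds a [study_dataset()].
#' @param model a [cluster_kmeans()] model.
#' @param params parameters to test.
#' @param effect `"congruency"`, `"task"` or `"interaction"`.
#' @param n_perm randomization runs.
#' @param seed integer seed.
#' @param scheme,exhaustive see [tanova()].
#' @return object of class `mstate_param_test`: `observed` and `p`, each a
#'   maps x parameters matrix, plus the per-level observed parameter tables.
#' @export
microstate_param_test <- function(ds, model,
                                  params = c("onset", "offset", "duration", "auc"),
                                  effect = "congruency", n_perm = 1000L,
                                  seed = 1L, scheme = c("full", "paired_swap"),
                                  exhaustive = FALSE) {
  stopifnot(inherits(ds, "study_dataset"), inherits(model, "microstate_model"))
  scheme <- match.arg(scheme)
  params <- match.arg(params, several.ok = TRUE)
  effect <- match.arg(effect, c("congruency", "task", "interaction"))
  d <- dim(ds$data)
  n_ch <- d[1L]; n_t <- d[2L]; ns <- d[3L]
  dt <- 1000 / ds$sfreq
  tms <- times_ms(n_t, ds$sfreq, ds$t0)
  V <- matrix(ds$data, n_ch * n_t, ns * 4L)   # columns subject-major: (s, c)

  # cell-combination weights for the level grand means
  lv <- switch(effect,
               congruency = list(A = c(0, .5, 0, .5), B = c(.5, 0, .5, 0)),
               task = list(A = c(0, 0, .5, .5), B = c(.5, .5, 0, 0)),
               interaction = list(cC = c(1, 0, 0, 0), cI = c(0, 1, 0, 0),
                                  wC = c(0, 0, 1, 0), wI = c(0, 0, 0, 1)))
  n_lv <- length(lv)
  level_wvec <- function(perm) {
    # (ns*4) x n_lv weights building each level's grand mean from permuted
    # cells; the flattened data keep subjects fastest (see tanova)
    out <- matrix(0, ns * 4L, n_lv)
    for (li in seq_len(n_lv)) {
      wcell <- lv[[li]]
      out[, li] <- as.vector(vapply(1:4, function(ci)
        wcell[perm[ci, ]], numeric(ns))) / ns
    }
    out
  }
  params_of <- function(U) {
    # U: ch x n_t grand mean -> k x 4 matrix of onset/offset/duration/auc
    dp <- .fit_dp(.fit_values(model, U))
    starts <- dp$starts
    ends <- c(starts[-1L] - 1L, n_t)
    onset <- tms[starts]
    offset <- c(tms[starts[-1L]], tms[n_t] + dt)
    g <- gfp(U)
    auc <- vapply(seq_len(model$k), function(j)
      sum(g[starts[j]:ends[j]]) * dt, numeric(1))
    cbind(onset = onset, offset = offset, duration = offset - onset, auc = auc)
  }
  stats_of <- function(wmat) {
    # level grand means -> |contrast| per map x parameter
    M <- V %*% wmat
    tabs <- lapply(seq_len(n_lv), function(li)
      params_of(matrix(M[, li], n_ch, n_t)))
    if (n_lv == 2L) {
      list(stat = abs(tabs[[1L]] - tabs[[2L]]), tabs = tabs)
    } else {
      list(stat = abs((tabs[[2L]] - tabs[[1L]]) - (tabs[[4L]] - tabs[[3L]])),
           tabs = tabs)
    }
  }
  id_perm <- matrix(rep(1:4, ns), 4L)
  obs <- stats_of(level_wvec(id_perm))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perms <- .perm_indices(ns, n_perm, scheme, effect, exhaustive)
  n_runs <- length(perms)
  count_ge <- matrix(0, model$k, 4L,
                     dimnames = list(NULL, c("onset", "offset", "duration", "auc")))
  thr <- obs$stat * (1 - 1e-9) - 1e-9   # tie tolerance (ms / ms.uV scales)
  for (r in seq_len(n_runs)) {
    st <- stats_of(level_wvec(perms[[r]]))$stat
    st[is.na(st)] <- Inf
    count_ge <- count_ge + (st >= thr)
  }
  p <- if (exhaustive) count_ge / n_runs else (count_ge + 1) / (n_runs + 1)
  structure(list(observed = obs$stat[, params, drop = FALSE],
                 p = p[, params, drop = FALSE],
                 level_params = obs$tabs, effect = effect, n_perm = n_runs,
                 seed = seed, exhaustive = exhaustive),
            class = "mstate_param_test")
}

#' @export
print.mstate_param_test <- function(x, ...) {
  cat(sprintf("<mstate_param_test> effect %s, %d runs\np values:\n", x$effect, x$n_perm))
  print(round(x$p, 4))
  invisible(x)
}

#' Write a permutation outcome as TSV (time, observed, p)
#'
#' @param outcome a `permutation_outcome`.
#' @param path output file.
#' @param sfreq,t0 time axis of the tested epoch.
#' @export
write_outcome <- function(outcome, path, sfreq, t0 = 0) {
  df <- data.frame(time_ms = times_ms(length(outcome$observed), sfreq, t0),
                   observed = outcome$observed, p = outcome$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
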