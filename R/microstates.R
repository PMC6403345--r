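# Microstate prototype identification (modified k-means maximizing global
# explained variance), split-half cross-validation for the number of maps,
# and fitting of prototypes to grand-mean ERPs with onset/offset/duration/AUC
# extraction.

# Spatial cosine between unit-GFP prototypes P (ch x k) and maps U (ch x T).
# cos_jt = (P_j . U_t) / (ch * GFP_t); columns with GFP 0 give NA.
.spatial_corr <- function(P, U) {
  g <- gfp(U)
  C <- crossprod(P, U) / nrow(P)
  sweep(C, 2L, ifelse(g > 0, g, NA_real_), "/")
}

# Winner-take-all assignment; signed correlation if polarity-sensitive,
# absolute correlation otherwise; ties toward the lower prototype index.
.assign <- function(P, U, polarity_sensitive = TRUE) {
  A <- crossprod(P, U)                 # argmax equivalent to corr argmax
  if (!polarity_sensitive) A <- abs(A)
  lab <- max.col(t(A), ties.method = "first")
  fitval <- .spatial_corr(P, U)[cbind(lab, seq_len(ncol(U)))]
  if (!polarity_sensitive) fitval <- abs(fitval)
  list(labels = lab, fit = fitval)
}

# GEV of an assignment: GFP-weighted squared spatial correlation.
.gev <- function(U, fitval) {
  g2 <- gfp(U)^2
  sum(g2 * fitval^2, na.rm = TRUE) / sum(g2)
}

#' Assign one map to its best-fitting microstate prototype
#'
#' Returns the prototype maximizing the spatial correlation with the map
#' (polarity-sensitive) or its absolute value (polarity-insensitive), plus
#' the attained fit value. A flat map cannot be assigned.
#'
#' @param u channel vector (average-referenced map).
#' @param model a [cluster_kmeans()] model.
#' @return list with `index` and `fit` (`NA` for a flat map).
#' @export
assign_label <- function(u, model) {
  stopifnot(inherits(model, "microstate_model"))
  if (gfp(u) <= 0) return(list(index = NA_integer_, fit = NA_real_))
  a <- .assign(model$maps, matrix(u, ncol = 1L), model$polarity_sensitive)
  list(index = a$labels[1L], fit = a$fit[1L])
}

#' Modified k-means microstate clustering
#'
#' Alternates winner-take-all assignment and prototype update until the
#' labels stabilize (iteration cap 100). The update is the GFP-normalized
#' mean of the assigned maps (polarity-sensitive, the ERP default) or their
#' first principal direction (polarity-insensitive). Among `n_init` random
#' restarts the solution maximizing the global explained variance
#' `GEV = sum((GFP_t * corr_t)^2) / sum(GFP_t^2)` is kept. Prototypes are
#' returned in canonical order of mean assigned time.
#'
#' @param X channels x timepoints matrix of average-referenced training maps.
#' @param k number of prototypes.
#' @param n_init random restarts.
#' @param polarity_sensitive logical; see Details.
#' @param seed integer seed.
#' @param max_iter iteration cap per restart.
#' @param blocks optional integer vector (one id per column of `X`) marking
#'   concatenated condition blocks; the canonical order then averages the
#'   within-block mean assigned positions, which stays correct when the same
#'   map sequence has different window lengths across conditions.
#' @return an object of class `microstate_model`: unit-GFP `maps`
#'   (channels x k), `k`, `polarity_sensitive`, `gev_train`, `seed`, `n_init`.
#' @export
cluster_kmeans <- function(X, k, n_init = 50L, polarity_sensitive = TRUE,
                           seed = 1L, max_iter = 100L, blocks = NULL) {
  X <- as.matrix(X)
  n_t <- ncol(X)
  if (k < 1L) stopf("k must be >= 1")
  if (k >= n_t) stopf("need more timepoints than prototypes")
  usable <- which(gfp(X) > 0)
  if (length(usable) < k) stopf("fewer non-flat timepoints than prototypes")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL
  for (init in seq_len(n_init)) {
    P <- X[, sample(usable, k), drop = FALSE]
    P <- apply(P, 2L, normalize_map)
    lab_prev <- rep(0L, n_t)
    for (iter in seq_len(max_iter)) {
      a <- .assign(P, X, polarity_sensitive)
      if (identical(a$labels, lab_prev)) break
      lab_prev <- a$labels
      for (j in seq_len(k)) {
        idx <- which(a$labels == j)
        if (length(idx) == 0L) {            # dead prototype: seize worst map
          idx <- which.min(abs(a$fit))
        }
        pj <- if (polarity_sensitive) {
          rowMeans(X[, idx, drop = FALSE])
        } else {
          s <- svd(X[, idx, drop = FALSE], nu = 1L, nv = 0L)$u[, 1L]
          if (s[which.max(abs(s))] < 0) -s else s
        }
        if (gfp(pj) > 0) P[, j] <- normalize_map(pj)
      }
    }
    a <- .assign(P, X, polarity_sensitive)
    gev <- .gev(X, a$fit)
    if (is.null(best) || gev > best$gev) best <- list(P = P, gev = gev,
                                                      labels = a$labels)
  }
  # canonical order: mean assigned time, averaged over condition blocks if
  # declared (unassigned prototypes last)
  blocks <- blocks %||% rep(1L, n_t)
  if (length(blocks) != n_t) stopf("blocks must give one id per timepoint")
  mt <- vapply(seq_len(k), function(j) {
    pos <- vapply(unique(blocks), function(b) {
      idx <- which(best$labels == j & blocks == b)
      if (length(idx)) mean(idx - min(which(blocks == b))) else NA_real_
    }, numeric(1))
    if (all(is.na(pos))) Inf else mean(pos, na.rm = TRUE)
  }, numeric(1))
  ord <- order(mt)
  structure(list(maps = best$P[, ord, drop = FALSE], k = k,
                 polarity_sensitive = polarity_sensitive,
                 gev_train = best$gev, seed = seed, n_init = n_init),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d, %s, training GEV = %.4f\n", x$k,
              if (x$polarity_sensitive) "polarity-sensitive" else "polarity-insensitive",
              x$gev_train))
  invisible(x)
}

# Ordered-contiguous segmentation by dynamic programming: assign each
# prototype j one contiguous window, in prototype order, tiling 1..T, and
# maximize the total fit sum(W[j, t] over assigned samples). W is the k x T
# matrix of per-sample fit values. O(kT). Returns integer start sample of
# each window (1-based) plus the total.
.fit_dp <- function(W) {
  k <- nrow(W); n_t <- ncol(W)
  if (k > n_t) stopf("more prototypes than timepoints")
  cum <- t(apply(W, 1L, cumsum))
  if (k == 1L) return(list(starts = 1L, total = cum[1L, n_t]))
  Fm <- matrix(-Inf, k, n_t)      # best total, maps 1..j, ending at t
  arg <- matrix(0L, k, n_t)       # chosen previous end s for backtracking
  Fm[1L, ] <- cum[1L, ]
  for (j in 2L:k) {
    gbest <- -Inf; gargs <- 0L
    for (t in j:n_t) {
      s <- t - 1L                 # candidate previous end
      g <- Fm[j - 1L, s] - cum[j, s]
      if (g > gbest) { gbest <- g; gargs <- s }
      Fm[j, t] <- cum[j, t] + gbest
      arg[j, t] <- gargs
    }
  }
  ends <- integer(k); ends[k] <- n_t
  for (j in k:2L) ends[j - 1L] <- arg[j, ends[j]]
  list(starts = c(1L, ends[-k] + 1L), total = Fm[k, n_t])
}

# Fit-value matrix for DP / labeling: GFP-weighted correlation = (P'U)/ch,
# signed (polarity-sensitive) or absolute.
.fit_values <- function(model, U) {
  W <- crossprod(model$maps, U) / nrow(U)
  if (!model$polarity_sensitive) W <- abs(W)
  W
}

#' Fit microstate prototypes to a grand-mean ERP
#'
#' `ordered-contiguous` (default): a dynamic program assigns each prototype
#' exactly one contiguous window, in the model's canonical map order,
#' maximizing the total GFP-weighted correlation; the windows tile the epoch,
#' so the offset of map m equals the onset of map m + 1 (half-open `[onset,
#' offset)` intervals). `free`: per-timepoint winner-take-all labels; onset is
#' the first and offset one past the last labeled sample.
#'
#' Parameters per map: onset, offset, duration = offset - onset (ms) and
#' `AUC = sum(GFP) * dt` over the map's samples (ms x uV), equivalently
#' duration times mean GFP.
#'
#' @param model a [cluster_kmeans()] model.
#' @param erp an [erp_matrix()] (a condition grand mean).
#' @param mode `"ordered-contiguous"` or `"free"`.
#' @return object of class `segmentation_result`: `labels` (prototype index
#'   per sample) and `params` (data frame map/onset/offset/duration/auc).
#' @export
fit_to_erp <- function(model, erp, mode = c("ordered-contiguous", "free")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "microstate_model"), inherits(erp, "erp_matrix"))
  U <- erp$values
  if (nrow(U) != nrow(model$maps)) stopf("model and ERP channel spaces differ")
  n_t <- ncol(U)
  dt <- 1000 / erp$sfreq
  tms <- times_ms(n_t, erp$sfreq, erp$t0)
  g <- gfp(U)
  if (mode == "ordered-contiguous") {
    dp <- .fit_dp(.fit_values(model, U))
    starts <- dp$starts
    ends <- c(starts[-1L] - 1L, n_t)             # inclusive sample ends
    labels <- rep(seq_len(model$k), ends - starts + 1L)
    onset <- tms[starts]
    offset <- c(tms[starts[-1L]], tms[n_t] + dt) # half-open tiling
  } else {
    a <- .assign(model$maps, U, model$polarity_sensitive)
    labels <- a$labels
    labels[g <= 0] <- NA_integer_
    onset <- offset <- rep(NA_real_, model$k)
    for (j in seq_len(model$k)) {
      idx <- which(labels == j)
      if (length(idx)) {
        onset[j] <- tms[idx[1L]]
        offset[j] <- tms[idx[length(idx)]] + dt
      }
    }
  }
  auc <- vapply(seq_len(model$k), function(j)
    sum(g[which(labels == j)]) * dt, numeric(1))
  params <- data.frame(map = seq_len(model$k), onset = onset, offset = offset,
                       duration = offset - onset, auc = auc)
  structure(list(labels = labels, params = params, mode = mode,
                 sfreq = erp$sfreq, t0 = erp$t0, n_times = n_t),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> mode %s\n", x$mode))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Split-half cross-validation for the number of microstate maps
#'
#' For each repetition the subjects are split at random into halves; the
#' training half's grand mean (all four cells concatenated along time) is
#' clustered at every k in `k_range`, and the trained prototypes are scored
#' on the held-out half's per-cell grand means under ordered-contiguous
#' fitting.
#'
#' Two selection rules are available. `"cv_criterion"` (the default)
#' minimizes the predictive residual variance inflated by the classic
#' microstate complexity factor, `(1 - GEV) * ((C - 1) / (C - 1 - k))^2`
#' with C channels: held-out explained variance alone is weakly monotone in
#' k (surplus prototypes can always absorb a few samples), so the inflation
#' factor is what gives the curve an interior optimum. `"max_gev"` picks the
#' k maximizing the mean test GEV.
#'
#' @param ds a [study_dataset()] (>= 4 subjects).
#' @param k_range candidate numbers of maps.
#' @param reps number of random splits.
#' @param n_init k-means restarts per fit.
#' @param polarity_sensitive passed to [cluster_kmeans()].
#' @param seed integer seed.
#' @param selection `"cv_criterion"` or `"max_gev"` (see Details).
#' @return object of class `cv_curve`: `k_range`, `test_gev` (reps x k),
#'   `mean`, `sd`, `criterion` (mean predictive criterion per k), `chosen_k`.
#' @export
cross_validate_k <- function(ds, k_range = 3:8, reps = 50L, n_init = 6L,
                             polarity_sensitive = TRUE, seed = 1L,
                             selection = c("cv_criterion", "max_gev")) {
  selection <- match.arg(selection)
  stopifnot(inherits(ds, "study_dataset"))
  ns <- length(ds$subjects)
  if (ns < 4L) stopf("cross-validation needs at least 4 subjects")
  n_t <- dim(ds$data)[2L]
  if (max(k_range) >= n_t) stopf("k_range exceeds the number of timepoints")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  test_gev <- matrix(NA_real_, reps, length(k_range),
                     dimnames = list(NULL, paste0("k", k_range)))
  for (rep_i in seq_len(reps)) {
    perm <- sample(ns)
    train <- perm[seq_len(floor(ns / 2))]
    test <- perm[(floor(ns / 2) + 1L):ns]
    Xtr <- do.call(cbind, lapply(CELLS, function(cell)
      grand_mean(ds, cells = cell, subjects = ds$subjects[train])$values))
    tests <- lapply(CELLS, function(cell)
      grand_mean(ds, cells = cell, subjects = ds$subjects[test])$values)
    for (ki in seq_along(k_range)) {
      model <- cluster_kmeans(Xtr, k_range[ki], n_init = n_init,
                              polarity_sensitive = polarity_sensitive,
                              seed = stats::runif(1, 1, 2^30),
                              blocks = rep(1:4, each = n_t))
      num <- den <- 0
      for (U in tests) {
        dp <- .fit_dp(.fit_values(model, U))
        ends <- c(dp$starts[-1L] - 1L, ncol(U))
        lab <- rep(seq_len(model$k), ends - dp$starts + 1L)
        fitval <- .spatial_corr(model$maps, U)[cbind(lab, seq_len(ncol(U)))]
        g2 <- gfp(U)^2
        num <- num + sum(g2 * fitval^2, na.rm = TRUE)
        den <- den + sum(g2)
      }
      test_gev[rep_i, ki] <- num / den
    }
  }
  mu <- colMeans(test_gev)
  n_ch <- dim(ds$data)[1L]
  if (max(k_range) > n_ch - 2L) stopf("k_range too large for %d channels", n_ch)
  criterion <- (1 - mu) * ((n_ch - 1) / (n_ch - 1 - k_range))^2
  chosen_k <- if (selection == "cv_criterion") {
    k_range[which.min(criterion)]
  } else k_range[which.max(mu)]
  structure(list(k_range = k_range, test_gev = test_gev, mean = mu,
                 sd = apply(test_gev, 2L, stats::sd), criterion = criterion,
                 selection = selection, chosen_k = chosen_k, reps = reps,
                 seed = seed),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> chosen_k = %d (%s)\n", x$chosen_k, x$selection))
  print(data.frame(k = x$k_range, mean_test_gev = x$mean, sd = x$sd,
                   criterion = x$criterion), row.names = FALSE)
  invisible(x)
}

#' Write a microstate model / segmentation table as text
#'
#' @param model a `microstate_model`; `seg` a `segmentation_result`.
#' @param path output file.
#' @param condition condition label echoed in the segmentation table.
#' @export
write_microstate_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# k=%d polarity_sensitive=%s gev_train=%.8g",
                     model$k, model$polarity_sensitive, model$gev_train), con)
  utils::write.table(model$maps, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
write_segmentation <- function(seg, path, condition = NA_character_) {
  df <- cbind(condition = condition, seg$params)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
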