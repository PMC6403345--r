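#' Electrode montage
#'
#' A montage holds the channel identities of a recording: an ordered set of
#' unique labels and one 3-D position per channel (arbitrary units; the
#' built-in simulator places electrodes on the upper unit hemisphere).
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix, one row per channel, columns x, y, z.
#' @return an object of class `montage` with fields `labels` and `positions`.
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (length(labels) < 2L) stopf("a montage needs at least 2 channels")
  if (anyDuplicated(labels)) stopf("montage labels must be unique")
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stopf("positions must be a %d x 3 matrix", length(labels))
  check_finite(positions, "montage positions")
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels: %s ...\n", length(x$labels),
              paste(utils::head(x$labels, 6L), collapse = ", ")))
  invisible(x)
}

#' Single-epoch or averaged ERP matrix
#'
#' Channels x timepoints potentials in microvolts, with the sampling rate and
#' the latency of the first sample. `reference` records whether the data have
#' been recomputed against the average reference.
#'
#' @param values numeric matrix (channels x timepoints, uV).
#' @param sfreq sampling rate (Hz).
#' @param t0 time of the first sample relative to stimulus onset (ms).
#' @param reference `"raw"` or `"average"`.
#' @return an object of class `erp_matrix`.
#' @export
erp_matrix <- function(values, sfreq, t0 = 0, reference = c("raw", "average")) {
  reference <- match.arg(reference)
  values <- as.matrix(values)
  check_finite(values, "ERP values")
  if (sfreq <= 0) stopf("sfreq must be positive")
  if (reference == "average") {
    rms <- sqrt(colMeans(values^2))
    bad <- abs(colMeans(values)) > 1e-9 * pmax(rms, 1e-12)
    if (any(bad)) stopf("reference = 'average' but %d column(s) do not sum to 0",
                        sum(bad))
  }
  structure(list(values = values, sfreq = sfreq, t0 = t0,
                 reference = reference), class = "erp_matrix")
}

#' @export
print.erp_matrix <- function(x, ...) {
  cat(sprintf("<erp_matrix> %d channels x %d samples @ %g Hz, t0 = %g ms, %s reference\n",
              nrow(x$values), ncol(x$values), x$sfreq, x$t0, x$reference))
  invisible(x)
}

#' Recompute an ERP against the average reference
#'
#' Subtracts, at every timepoint, the mean over channels, so that each column
#' of the result sums to zero. The operation is idempotent and linear.
#'
#' @param erp an [erp_matrix()] (or a bare channels x time matrix).
#' @return the re-referenced object, `reference = "average"`.
#' @export
apply_average_reference <- function(erp) {
  if (is.matrix(erp)) {
    check_finite(erp, "ERP values")
    return(sweep(erp, 2L, colMeans(erp)))
  }
  stopifnot(inherits(erp, "erp_matrix"))
  v <- sweep(erp$values, 2L, colMeans(erp$values))
  erp_matrix(v, erp$sfreq, erp$t0, reference = "average")
}

#' Amplitude criteria for automatic epoch rejection
#'
#' Defaults follow common ERP practice: a maximal voltage step of 50 uV
#' between consecutive samples, a maximal peak-to-peak range of 150 uV within
#' any 200 ms window, and a maximal absolute amplitude of 100 uV.
#'
#' @param max_step maximal difference between consecutive samples (uV).
#' @param max_range_in_window maximal range within the sliding window (uV).
#' @param window_ms sliding-window length (ms).
#' @param max_abs maximal absolute amplitude (uV).
#' @return an object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(max_step = 50, max_range_in_window = 150,
                               window_ms = 200, max_abs = 100) {
  if (any(c(max_step, max_range_in_window, window_ms, max_abs) <= 0))
    stopf("all rejection criteria must be positive")
  structure(list(max_step = max_step,
                 max_range_in_window = max_range_in_window,
                 window_ms = window_ms, max_abs = max_abs),
            class = "rejection_criteria")
}

# Running min/max over a window of w samples, per row; O(n*w) but epochs are
# short.  Returns max - min for every window start.
.window_range <- function(x, w) {
  n <- length(x)
  if (w >= n) return(max(x) - min(x))
  vapply(seq_len(n - w + 1L), function(i) {
    xi <- x[i:(i + w - 1L)]
    max(xi) - min(xi)
  }, numeric(1))
}

#' Reject epochs violating amplitude criteria
#'
#' An epoch is rejected if any channel violates any criterion. Counts report,
#' per criterion, how many epochs violate it (an epoch may count for several).
#'
#' @param epochs list of [erp_matrix()] sharing dimensions.
#' @param criteria a [rejection_criteria()].
#' @return list with `keep` (logical mask) and `counts` (named integer).
#' @export
reject_epochs <- function(epochs, criteria = rejection_criteria()) {
  if (length(epochs) == 0L) stopf("empty epoch list")
  stopifnot(inherits(criteria, "rejection_criteria"))
  dims <- dim(epochs[[1L]]$values)
  viol <- matrix(FALSE, length(epochs), 3L,
                 dimnames = list(NULL, c("step", "range", "abs")))
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    if (!identical(dim(e$values), dims)) stopf("epochs must share dimensions")
    v <- e$values
    w <- max(2L, ms_to_samples(criteria$window_ms, e$sfreq))
    viol[i, "abs"] <- any(abs(v) > criteria$max_abs)
    viol[i, "step"] <- ncol(v) > 1L &&
      any(abs(v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]) >
            criteria$max_step)
    viol[i, "range"] <- any(apply(v, 1L, function(ch)
      max(.window_range(ch, w)) > criteria$max_range_in_window))
  }
  list(keep = !apply(viol, 1L, any),
       counts = colSums(viol),
       n_rejected = sum(apply(viol, 1L, any)))
}

#' Average kept epochs into an ERP
#'
#' @param epochs list of [erp_matrix()].
#' @param keep logical mask (default: keep all).
#' @return an [erp_matrix()], the elementwise mean over kept epochs.
#' @export
average_trials <- function(epochs, keep = rep(TRUE, length(epochs))) {
  if (length(epochs) == 0L) stopf("empty epoch list")
  if (length(keep) != length(epochs)) stopf("mask length must match epochs")
  kept <- epochs[keep]
  if (length(kept) == 0L) stopf("zero epochs kept; cannot average")
  acc <- Reduce(`+`, lapply(kept, function(e) e$values))
  e1 <- kept[[1L]]
  erp_matrix(acc / length(kept), e1$sfreq, e1$t0, reference = e1$reference)
}

#' Replace a bad channel by inverse-distance-weighted neighbors
#'
#' A simplified adjacent-electrode interpolation: the bad channel's series is
#' replaced by the inverse-distance-weighted mean of its `k_neighbors`
#' nearest good channels on the montage.
#'
#' @param erp an [erp_matrix()].
#' @param mont the [montage()] matching the ERP rows.
#' @param bad label of the channel to rebuild (`NULL` = identity).
#' @param k_neighbors number of good neighbors to use.
#' @return the repaired [erp_matrix()]; other channels untouched.
#' @export
interpolate_channel <- function(erp, mont, bad = NULL, k_neighbors = 4L) {
  stopifnot(inherits(erp, "erp_matrix"), inherits(mont, "montage"))
  if (is.null(bad)) return(erp)
  idx <- match(bad, mont$labels)
  if (is.na(idx)) stopf("unknown channel '%s'", bad)
  good <- setdiff(seq_along(mont$labels), idx)
  if (length(good) < k_neighbors) stopf("need at least %d good channels", k_neighbors)
  d <- sqrt(colSums((t(mont$positions[good, , drop = FALSE]) -
                       mont$positions[idx, ])^2))
  nb <- good[order(d)][seq_len(k_neighbors)]
  wd <- 1 / pmax(sort(d)[seq_len(k_neighbors)], 1e-12)
  w <- wd / sum(wd)
  v <- erp$values
  v[idx, ] <- as.numeric(w %*% v[nb, , drop = FALSE])
  erp_matrix(v, erp$sfreq, erp$t0, reference = "raw")
}

#' Multi-subject, four-condition ERP study
#'
#' The universal input of all statistics in the package: one average-referenced
#' ERP per subject per design cell, stored as a channels x time x subject x
#' cell array. Cells follow the 2x2 within-subject design task
#' (color-naming, word-reading) x congruency (congruent, incongruent), in the
#' fixed order `cC, cI, wC, wI`.
#'
#' @param data 4-d numeric array `[channel, time, subject, cell]`; the cell
#'   dimension must be 4 (named or taken in canonical order).
#' @param mont a [montage()] matching the first dimension.
#' @param sfreq sampling rate (Hz).
#' @param t0 first-sample latency (ms).
#' @param subjects optional subject identifiers.
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(data, mont, sfreq, t0 = 0, subjects = NULL) {
  stopifnot(inherits(mont, "montage"))
  d <- dim(data)
  if (length(d) != 4L) stopf("data must be a 4-d array [channel, time, subject, cell]")
  if (d[1L] != length(mont$labels)) stopf("channel dimension does not match montage")
  if (d[4L] != 4L) stopf("the design has exactly 4 cells (%s)", paste(CELLS, collapse = ", "))
  check_finite(data, "study data")
  subjects <- subjects %||% sprintf("S%02d", seq_len(d[3L]))
  if (length(subjects) != d[3L]) stopf("subjects length does not match data")
  dimnames(data) <- list(mont$labels, NULL, subjects, CELLS)
  structure(list(data = data, montage = mont, sfreq = sfreq, t0 = t0,
                 subjects = subjects,
                 design = list(task = c("color", "word"),
                               congruency = c("congruent", "incongruent"))),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<study_dataset> %d subjects, %d channels x %d samples @ %g Hz, cells %s\n",
              d[3L], d[1L], d[2L], x$sfreq, paste(CELLS, collapse = "/")))
  invisible(x)
}

#' Extract one subject x cell ERP from a study
#'
#' @param ds a [study_dataset()].
#' @param subject subject id or index.
#' @param cell one of `"cC", "cI", "wC", "wI"`.
#' @return an [erp_matrix()] (average reference).
#' @export
get_erp <- function(ds, subject, cell) {
  stopifnot(inherits(ds, "study_dataset"))
  cell <- match.arg(cell, CELLS)
  erp_matrix(ds$data[, , subject, cell], ds$sfreq, ds$t0, reference = "average")
}

#' Grand-mean ERP over subjects (and optionally cells)
#'
#' @param ds a [study_dataset()].
#' @param cells design cells to average over (default: all four).
#' @param subjects subset of subjects (default: all).
#' @return an [erp_matrix()].
#' @export
grand_mean <- function(ds, cells = CELLS, subjects = ds$subjects) {
  stopifnot(inherits(ds, "study_dataset"))
  sub <- ds$data[, , subjects, cells, drop = FALSE]
  m <- apply(sub, c(1L, 2L), mean)
  erp_matrix(m, ds$sfreq, ds$t0, reference = "average")
}
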