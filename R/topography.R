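# Reference-free topographic algebra: global field power, map normalization,
# global map dissimilarity and channel-wise paired t-maps.

#' Global field power of a topographic map
#'
#' The root mean square across the average-referenced electrode values of a
#' map: `sqrt(mean(u^2))`. A global, reference-independent measure of scalp
#' field strength. The divisor is the number of channels N (not N - 1).
#'
#' @param u numeric vector (one value per channel, uV) or a channels x time
#'   matrix, in which case one GFP per column is returned.
#' @return nonnegative scalar (or vector, for a matrix input) in uV.
#' @export
gfp <- function(u) {
  check_finite(u, "map")
  if (is.matrix(u)) sqrt(colMeans(u^2)) else sqrt(mean(u^2))
}

#' Scale a map to unit global field power
#'
#' Divides by the GFP so the result has GFP = 1; the spatial configuration
#' (direction in channel space) is preserved. A flat map has no topography
#' and is rejected.
#'
#' @param u numeric channel vector (average-referenced).
#' @return the normalized map.
#' @export
normalize_map <- function(u) {
  g <- gfp(u)
  if (g <= 0) stopf("flat map (GFP = 0) cannot be normalized")
  u / g
}

#' Global map dissimilarity between two topographies
#'
#' The GFP of the difference of the two GFP-normalized maps; equivalently
#' `sqrt(2 - 2*cos)` where `cos` is the cosine between the maps in channel
#' space. Ranges from 0 (positively proportional maps) to 2 (antipodal maps)
#' and is invariant to positive rescaling of either argument.
#'
#' @param a,b numeric channel vectors (average-referenced, non-flat).
#' @return dissimilarity in `[0, 2]`.
#' @export
dissimilarity <- function(a, b) {
  gfp(normalize_map(a) - normalize_map(b))
}

#' Channel-wise paired t-map between two conditions
#'
#' For every channel, the paired t statistic over subjects of the
#' window-averaged potentials, condition A minus condition B. Channels with
#' zero variance of the paired difference are reported as `NA` (flagged in
#' `zero_variance`) rather than +-Inf.
#'
#' @param maps_a,maps_b channels x subjects matrices of window-averaged
#'   potentials (paired columns = same subject).
#' @param window the `[start, end)` window in ms the maps were averaged over
#'   (metadata echoed in the result).
#' @param contrast labels of the two conditions, A first.
#' @return object of class `tmap_result`: `t` per channel, `df`,
#'   `zero_variance`, `window`, `contrast`.
#' @export
tmap <- function(maps_a, maps_b, window = c(NA_real_, NA_real_),
                 contrast = c("A", "B")) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (!identical(dim(maps_a), dim(maps_b)))
    stopf("condition matrices must have identical dimensions")
  n <- ncol(maps_a)
  if (n < 2L) stopf("paired t needs at least 2 subjects")
  d <- maps_a - maps_b
  m <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - m)^2) / (n - 1L))
  zv <- sd_d <= 1e-12 * pmax(abs(m), 1)
  tv <- m / (sd_d / sqrt(n))
  tv[zv & abs(m) <= 0] <- 0     # identical data: t = 0, not 0/0
  tv[zv & abs(m) > 0] <- NA_real_
  structure(list(t = tv, df = n - 1L, zero_variance = zv,
                 window = window, contrast = contrast),
            class = "tmap_result")
}

#' @export
print.tmap_result <- function(x, ...) {
  cat(sprintf("<tmap> %s - %s, df = %d, window [%g, %g) ms, t range [%.3g, %.3g]\n",
              x$contrast[1L], x$contrast[2L], x$df, x$window[1L], x$window[2L],
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' Write a t-map as TSV
#'
#' @param tm a [tmap()] result.
#' @param path output file; columns channel, t, zero_variance.
#' @param channels optional channel labels.
#' @export
write_tmap <- function(tm, path, channels = NULL) {
  df <- data.frame(channel = channels %||% seq_along(tm$t),
                   t = tm$t, zero_variance = tm$zero_variance)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
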