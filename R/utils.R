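# Internal helpers shared across modules.

# Canonical order of the four design cells: task (color-naming / word-reading)
# crossed with congruency (congruent / incongruent).
CELLS <- c("cC", "cI", "wC", "wI")
CELL_TASK <- c(cC = "color", cI = "color", wC = "word", wI = "word")
CELL_CONGRUENCY <- c(cC = "congruent", cI = "incongruent",
                     wC = "congruent", wI = "incongruent")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

#' Time axis of an epoch in milliseconds
#'
#' Sample index 0 sits at `t0` ms relative to stimulus onset; subsequent
#' samples are spaced by `1000 / sfreq` ms.
#'
#' @param n_times number of samples.
#' @param sfreq sampling rate in Hz.
#' @param t0 time of the first sample (ms).
#' @return numeric vector of length `n_times` (ms).
#' @export
times_ms <- function(n_times, sfreq, t0 = 0) {
  t0 + (seq_len(n_times) - 1L) * 1000 / sfreq
}

# Convert a duration in ms to a whole number of samples (nearest integer).
ms_to_samples <- function(ms, sfreq) as.integer(round(ms * sfreq / 1000))

# Derive a reproducible per-stage seed from one global seed.  Stages are
# numbered in a fixed table so that toggling one stage cannot shift the
# randomness of another; the result stays well inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, tct = 2L, cv = 3L, cluster = 4L, mstats = 5L,
              tanova = 6L, tmap = 7L, source = 8L, bayes = 9L, misc = 10L)
  if (is.character(stage)) stage <- stages[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

# Length of the longest run of TRUE in a logical vector (0 if none).
max_run_length <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(as.logical(x))
  max(r$lengths[r$values])
}

# All maximal runs of TRUE as a two-column matrix of half-open sample
# intervals [start, end) (1-based start, end = one past last TRUE).
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}
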