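# Synthetic multi-subject ERP studies with a planted sequence of quasi-stable
# topographies, condition-specific late latency shifts, spatially and
# temporally correlated sensor noise, and toy lead-field source studies.

#' Simulation configuration
#'
#' Desk-scale defaults (12 subjects, 32 channels, 256 Hz, 0-1000 ms epochs,
#' 5 planted template maps) keep every experiment fast; `preset = "paper"`
#' switches to the full study scale (38 subjects, 64 channels, 1024 Hz,
#' 10 maps).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_channels number of electrodes (>= 2).
#' @param sfreq sampling rate (Hz).
#' @param epoch_ms epoch length (ms), epoch spans `[0, epoch_ms)`.
#' @param seed integer seed fixing all randomness.
#' @param preset `"desk"` or `"paper"`; explicit arguments override.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = NULL, n_channels = NULL, sfreq = NULL,
                       epoch_ms = NULL, seed = 1L,
                       preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") {
    list(n_subjects = 12L, n_channels = 32L, sfreq = 256, epoch_ms = 1000)
  } else {
    list(n_subjects = 38L, n_channels = 64L, sfreq = 1024, epoch_ms = 1000)
  }
  cfg <- list(n_subjects = as.integer(n_subjects %||% def$n_subjects),
              n_channels = as.integer(n_channels %||% def$n_channels),
              sfreq = sfreq %||% def$sfreq,
              epoch_ms = epoch_ms %||% def$epoch_ms,
              seed = as.integer(seed), preset = preset)
  if (cfg$n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (cfg$n_channels < 2L) stopf("n_channels must be >= 2")
  structure(cfg, class = "sim_config")
}

#' Noise model for the simulator
#'
#' Sensor noise is white Gaussian noise mixed by a Gaussian distance kernel on
#' the montage (spatial correlation) and by a Gaussian kernel along time
#' (temporal correlation, emulating band-limited EEG noise); both mixings
#' preserve the per-sample marginal standard deviation. Subjects additionally
#' receive a multiplicative amplitude gain and a common latency shift of all
#' template boundaries.
#'
#' @param sensor_noise_sd per-channel noise SD (uV).
#' @param spatial_smoothness correlation length on the montage (same units as
#'   electrode positions; the built-in montages live on the unit sphere).
#' @param temporal_smoothness_ms temporal correlation length (ms).
#' @param subject_amplitude_sd SD of the log of the per-subject gain.
#' @param subject_latency_jitter_sd SD of the per-subject boundary shift (ms).
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(sensor_noise_sd = 2, spatial_smoothness = 0.5,
                       temporal_smoothness_ms = 20,
                       subject_amplitude_sd = 0.2,
                       subject_latency_jitter_sd = 5) {
  vals <- c(sensor_noise_sd, spatial_smoothness, temporal_smoothness_ms,
            subject_amplitude_sd, subject_latency_jitter_sd)
  if (any(vals < 0)) stopf("noise parameters must be nonnegative")
  structure(list(sensor_noise_sd = sensor_noise_sd,
                 spatial_smoothness = spatial_smoothness,
                 temporal_smoothness_ms = temporal_smoothness_ms,
                 subject_amplitude_sd = subject_amplitude_sd,
                 subject_latency_jitter_sd = subject_latency_jitter_sd),
            class = "noise_spec")
}

#' Quasi-uniform electrode montage on the upper hemisphere
#'
#' Electrodes are placed on a Fibonacci lattice over the upper unit
#' hemisphere (quasi-uniform by construction) and rotated about the vertical
#' axis by a seeded angle, so the layout is deterministic given the seed.
#'
#' @param n_channels number of electrodes (>= 2).
#' @param seed integer seed.
#' @return a [montage()] with labels `E01, E02, ...`.
#' @export
make_montage <- function(n_channels, seed = 1L) {
  if (n_channels < 2L) stopf("a montage needs at least 2 channels")
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels                    # uniform in z over (0, 1): hemisphere
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2  # golden-angle spiral
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rot <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi + rot), y = r * sin(phi + rot), z = z)
  montage(sprintf("E%02d", seq_len(n_channels)), pos)
}

# Seed sandboxing: run seeded code without clobbering the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Gaussian mixing kernel with unit-L2 rows: preserves marginal variance.
.mix_kernel <- function(dist2, len) {
  if (len <= 0) return(diag(nrow(dist2)))
  k <- exp(-dist2 / (2 * len^2))
  k / sqrt(rowSums(k^2))
}

# Mutually orthogonal, average-referenced, unit-GFP smooth random maps.
make_templates <- function(mont, k, seed = 1L, spatial_smoothness = 0.6) {
  n <- length(mont$labels)
  if (k > n - 1L) stopf("at most %d orthogonal average-referenced maps exist", n - 1L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  d2 <- as.matrix(stats::dist(mont$positions))^2
  ks <- .mix_kernel(d2, spatial_smoothness)
  raw <- ks %*% matrix(stats::rnorm(n * k), n, k)
  raw <- sweep(raw, 2L, colMeans(raw))        # average reference
  q <- qr.Q(qr(raw))                          # orthonormal, still centered
  q <- sweep(q, 2L, sqrt(colMeans(q^2)), "/") # unit GFP
  # deterministic sign: largest-|value| channel positive
  for (j in seq_len(k)) if (q[which.max(abs(q[, j])), j] < 0) q[, j] <- -q[, j]
  rownames(q) <- mont$labels
  q
}

#' Planted template-sequence specification
#'
#' Defines the ground truth of a simulated study: `k` average-referenced
#' unit-GFP template topographies, per-cell segment boundaries assigning one
#' contiguous window per template in fixed order, and a nonnegative GFP
#' envelope over time. Orthogonal templates guarantee the pairwise
#' dissimilarity floor.
#'
#' @param mont the [montage()] the templates live on.
#' @param templates channels x k matrix of average-referenced unit-GFP maps.
#' @param boundaries named list (`cC`, `cI`, `wC`, `wI`), each a strictly
#'   increasing numeric vector of k + 1 boundaries (ms) spanning
#'   `[0, epoch_ms]`.
#' @param gfp_envelope function of time (ms) returning the field strength
#'   (uV, nonnegative).
#' @param min_dissimilarity floor on pairwise template dissimilarity.
#' @return a list of class `template_sequence_spec`.
#' @export
template_sequence_spec <- function(mont, templates, boundaries, gfp_envelope,
                                   min_dissimilarity = 0.5) {
  templates <- as.matrix(templates)
  k <- ncol(templates)
  if (nrow(templates) != length(mont$labels))
    stopf("templates do not match montage")
  if (max(abs(colMeans(templates))) > 1e-8)
    stopf("templates must be average-referenced")
  if (max(abs(gfp(templates) - 1)) > 1e-8)
    stopf("templates must have unit GFP")
  if (k > 1L) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (dissimilarity(templates[, a], templates[, b]) < min_dissimilarity)
        stopf("templates %d and %d closer than the dissimilarity floor", a, b)
  }
  if (!all(CELLS %in% names(boundaries))) stopf("boundaries must name all cells")
  epoch_ms <- boundaries[[1L]][length(boundaries[[1L]])]
  for (cell in CELLS) {
    b <- boundaries[[cell]]
    if (length(b) != k + 1L) stopf("cell %s needs %d boundaries", cell, k + 1L)
    if (any(diff(b) <= 0)) stopf("boundaries must be strictly increasing")
    if (b[1L] != 0 || b[length(b)] != epoch_ms)
      stopf("boundaries must span [0, epoch_ms]")
  }
  structure(list(montage = mont, templates = templates, k = k,
                 boundaries = boundaries, gfp_envelope = gfp_envelope,
                 epoch_ms = epoch_ms),
            class = "template_sequence_spec")
}

# Smooth two-bump default GFP envelope (uV), bounded away from zero.
default_envelope <- function(t_ms) {
  1.5 + 3 * exp(-((t_ms - 300) / 120)^2) + 2.5 * exp(-((t_ms - 650) / 180)^2)
}

#' Default planted study: equal segments plus a late-map stretch
#'
#' Builds a [template_sequence_spec()] with `k` orthogonal templates in
#' equal-width windows. In the incongruent cells the windows of
#' `stretched_maps` are each lengthened by `stretch_ms` (later boundaries
#' shift; the final map is shortened so the epoch length is preserved) —
#' the condition-specific late latency shift the package's statistics are
#' designed to detect. `stretch_ms = 0` yields an exact null.
#'
#' @param cfg a [sim_config()].
#' @param k number of template maps.
#' @param stretch_ms lengthening of each stretched map (ms) in `cI`/`wI`.
#' @param stretched_maps indices of the stretched maps (default: map k - 1).
#' @param mont optional [montage()] (default: seeded [make_montage()]).
#' @return a [template_sequence_spec()].
#' @export
planted_stroop_spec <- function(cfg, k = 5L, stretch_ms = 50,
                                stretched_maps = k - 1L, mont = NULL) {
  mont <- mont %||% make_montage(cfg$n_channels, seed = stage_seed(cfg$seed, 1L))
  templates <- make_templates(mont, k, seed = stage_seed(cfg$seed, 2L))
  base <- seq(0, cfg$epoch_ms, length.out = k + 1L)
  stretched <- base
  for (m in stretched_maps) {
    if (m >= k) stopf("only maps 1..k-1 can be stretched (the last absorbs the shift)")
    stretched[(m + 1L):k] <- stretched[(m + 1L):k] + stretch_ms
  }
  if (any(diff(stretched) <= 0))
    stopf("stretch too large: boundaries no longer increasing")
  boundaries <- list(cC = base, cI = stretched, wC = base, wI = stretched)
  template_sequence_spec(mont, templates, boundaries, default_envelope)
}

# Sample-wise template index for one cell given boundaries (ms) and a common
# shift of the interior boundaries; half-open windows [on, off).
.labels_from_boundaries <- function(b, t_ms, shift = 0) {
  k <- length(b) - 1L
  bi <- b
  if (k > 1L) {
    bi[2L:k] <- b[2L:k] + shift
    bi[2L:k] <- pmin(pmax(bi[2L:k], b[1L] + 1e-9), b[k + 1L] - 1e-9)
    bi <- cummax(bi)
  }
  lab <- findInterval(t_ms, bi, rightmost.closed = FALSE, left.open = FALSE)
  pmin(pmax(lab, 1L), k)
}

#' Simulate a multi-subject ERP study with planted ground truth
#'
#' Each subject x cell ERP is `gain_s * envelope(t) * template[active map] +`
#' spatially and temporally correlated noise, recomputed to the average
#' reference. Fully reproducible from `cfg$seed`.
#'
#' @param spec a [template_sequence_spec()] (see [planted_stroop_spec()]).
#' @param noise a [noise_spec()].
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [study_dataset()]) and `truth` (templates,
#'   per-cell boundaries, per-subject gains and jitters, sample labels).
#' @export
simulate_erp_study <- function(spec, noise = noise_spec(), cfg = sim_config()) {
  stopifnot(inherits(spec, "template_sequence_spec"),
            inherits(noise, "noise_spec"), inherits(cfg, "sim_config"))
  mont <- spec$montage
  n_ch <- length(mont$labels)
  if (n_ch != cfg$n_channels) stopf("spec montage does not match cfg$n_channels")
  n_t <- ms_to_samples(cfg$epoch_ms, cfg$sfreq)
  t_ms <- times_ms(n_t, cfg$sfreq, 0)
  env <- spec$gfp_envelope(t_ms)
  if (any(env < 0)) stopf("gfp_envelope must be nonnegative")

  old <- local_seed(stage_seed(cfg$seed, "simulate"))
  on.exit(restore_seed(old))
  gains <- exp(stats::rnorm(cfg$n_subjects, 0, noise$subject_amplitude_sd))
  jitters <- stats::rnorm(cfg$n_subjects, 0, noise$subject_latency_jitter_sd)

  ks <- .mix_kernel(as.matrix(stats::dist(mont$positions))^2,
                    noise$spatial_smoothness)
  kt <- .mix_kernel(outer(t_ms, t_ms, `-`)^2, noise$temporal_smoothness_ms)

  data <- array(0, c(n_ch, n_t, cfg$n_subjects, 4L))
  labels <- array(NA_integer_, c(n_t, 4L), dimnames = list(NULL, CELLS))
  for (ci in seq_along(CELLS)) {
    labels[, ci] <- .labels_from_boundaries(spec$boundaries[[CELLS[ci]]], t_ms, 0)
  }
  for (si in seq_len(cfg$n_subjects)) {
    for (ci in seq_along(CELLS)) {
      lab <- .labels_from_boundaries(spec$boundaries[[CELLS[ci]]], t_ms, jitters[si])
      signal <- spec$templates[, lab, drop = FALSE] *
        rep(env * gains[si], each = n_ch)
      e <- if (noise$sensor_noise_sd > 0) {
        noise$sensor_noise_sd *
          (ks %*% matrix(stats::rnorm(n_ch * n_t), n_ch, n_t) %*% t(kt))
      } else 0
      data[, , si, ci] <- apply_average_reference(signal + e)
    }
  }
  ds <- study_dataset(data, mont, cfg$sfreq, t0 = 0)
  truth <- list(templates = spec$templates, boundaries = spec$boundaries,
                labels = labels, gains = gains, jitters = jitters,
                envelope = env, config = cfg)
  list(dataset = ds, truth = truth)
}

#' Simulate a null study (no condition effect)
#'
#' All four design cells share one template sequence; any condition
#' difference is pure noise. Used for type-I-error calibration of the
#' randomization statistics.
#'
#' @param cfg a [sim_config()].
#' @param noise a [noise_spec()].
#' @param k number of shared template maps.
#' @return a [study_dataset()].
#' @export
simulate_null_study <- function(cfg = sim_config(), noise = noise_spec(), k = 5L) {
  spec <- planted_stroop_spec(cfg, k = k, stretch_ms = 0)
  simulate_erp_study(spec, noise, cfg)$dataset
}

#' Simulate a source-level study on a toy head model
#'
#' Builds a sequence of `n_segments` quasi-stable source configurations
#' (each a spatially compact set of active voxels with a fixed pattern); one
#' designated segment activates the ROI of interest. Each segment is active
#' at a constant amplitude over its window (the microstate assumption of
#' quasi-stable strength), so a timing effect leaves the per-window mean
#' activity untouched. Sensor data are the lead field applied to the source
#' waveforms (each segment's sensor footprint scaled to unit GFP) plus
#' correlated sensor noise. The planted congruency effect is either `none`,
#' `longer` (the ROI segment's window is lengthened by `stretch_ms` in the
#' incongruent cells, amplitude unchanged) or `stronger` (amplitude scaled
#' by `strength_factor` instead, timing unchanged).
#'
#' @param model a [make_toy_headmodel()].
#' @param active_roi name of the ROI driving the effect segment.
#' @param effect `"none"`, `"longer"` or `"stronger"`.
#' @param cfg a [sim_config()] (its `n_channels` must match the model).
#' @param noise a [noise_spec()].
#' @param n_segments number of source configurations in sequence.
#' @param roi_segment which segment activates the ROI (default: next to
#'   last, a late window).
#' @param stretch_ms window lengthening for `effect = "longer"`.
#' @param strength_factor amplitude scaling for `effect = "stronger"`.
#' @return list with `dataset` (a [study_dataset()] of sensor ERPs) and
#'   `truth` (boundaries per cell, active voxels and patterns per segment,
#'   sensor footprints, gains, jitters).
#' @export
simulate_source_study <- function(model, active_roi = "ACC",
                                  effect = c("none", "longer", "stronger"),
                                  cfg = sim_config(), noise = noise_spec(),
                                  n_segments = 5L,
                                  roi_segment = n_segments - 1L,
                                  stretch_ms = 50, strength_factor = 1.5) {
  stopifnot(inherits(model, "toy_headmodel"))
  effect <- match.arg(effect)
  if (!active_roi %in% names(model$roi))
    stopf("unknown ROI '%s' (available: %s)", active_roi,
          paste(names(model$roi), collapse = ", "))
  L <- model$leadfield
  n_sens <- nrow(L); n_vox <- ncol(L)
  if (n_sens != cfg$n_channels) stopf("cfg$n_channels must match the model sensors")
  n_t <- ms_to_samples(cfg$epoch_ms, cfg$sfreq)
  t_ms <- times_ms(n_t, cfg$sfreq, 0)

  old <- local_seed(stage_seed(cfg$seed, "source"))
  on.exit(restore_seed(old))
  roi_idx <- model$roi[[active_roi]]
  cluster_size <- max(2L, length(roi_idx))
  d_vox <- as.matrix(stats::dist(model$voxel_coords))
  patterns <- matrix(0, n_vox, n_segments)
  active <- vector("list", n_segments)
  for (seg in seq_len(n_segments)) {
    idx <- if (seg == roi_segment) roi_idx else {
      ctr <- sample(setdiff(seq_len(n_vox), roi_idx), 1L)
      order(d_vox[ctr, ])[seq_len(cluster_size)]
    }
    amp <- abs(stats::rnorm(length(idx), 1, 0.2))
    p <- numeric(n_vox); p[idx] <- amp
    footprint <- as.numeric(L %*% p)
    p <- p / gfp(footprint)              # unit sensor GFP per segment
    patterns[, seg] <- p
    active[[seg]] <- sort(idx)
  }
  footprints <- L %*% patterns           # sensors x segments, unit GFP
  seg_amp <- stats::runif(n_segments, 2, 4)   # uV scalp field per segment

  base <- seq(0, cfg$epoch_ms, length.out = n_segments + 1L)
  stretched <- base
  if (effect == "longer") {
    if (roi_segment >= n_segments)
      stopf("the last segment cannot be stretched")
    stretched[(roi_segment + 1L):n_segments] <-
      stretched[(roi_segment + 1L):n_segments] + stretch_ms
    if (any(diff(stretched) <= 0)) stopf("stretch too large")
  }
  boundaries <- list(cC = base, cI = stretched, wC = base, wI = stretched)
  amp_factor <- function(cell, seg) {
    if (effect == "stronger" && seg == roi_segment &&
        cell %in% c("cI", "wI")) strength_factor else 1
  }

  gains <- exp(stats::rnorm(cfg$n_subjects, 0, noise$subject_amplitude_sd))
  jitters <- stats::rnorm(cfg$n_subjects, 0, noise$subject_latency_jitter_sd)
  ks <- .mix_kernel(as.matrix(stats::dist(model$montage$positions))^2,
                    noise$spatial_smoothness)
  kt <- .mix_kernel(outer(t_ms, t_ms, `-`)^2, noise$temporal_smoothness_ms)

  data <- array(0, c(n_sens, n_t, cfg$n_subjects, 4L))
  for (si in seq_len(cfg$n_subjects)) {
    for (ci in seq_along(CELLS)) {
      cell <- CELLS[ci]
      lab <- .labels_from_boundaries(boundaries[[cell]], t_ms, jitters[si])
      fac <- vapply(lab, function(seg) amp_factor(cell, seg), numeric(1))
      signal <- footprints[, lab, drop = FALSE] *
        rep(seg_amp[lab] * fac * gains[si], each = n_sens)
      e <- if (noise$sensor_noise_sd > 0) {
        noise$sensor_noise_sd *
          (ks %*% matrix(stats::rnorm(n_sens * n_t), n_sens, n_t) %*% t(kt))
      } else 0
      data[, , si, ci] <- apply_average_reference(signal + e)
    }
  }
  ds <- study_dataset(data, model$montage, cfg$sfreq, t0 = 0)
  truth <- list(boundaries = boundaries, active = active,
                patterns = patterns, footprints = footprints,
                seg_amp = seg_amp, roi_segment = roi_segment,
                effect = effect, gains = gains, jitters = jitters,
                config = cfg)
  list(dataset = ds, truth = truth)
}
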