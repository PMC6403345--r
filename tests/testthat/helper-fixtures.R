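# Shared fixtures, built in code at test time.

random_avg_ref_map <- function(n_ch, seed = 1) {
  set.seed(seed)
  u <- rnorm(n_ch)
  u - mean(u)
}

tiny_montage <- function(n = 8, seed = 1) make_montage(n, seed = seed)

# A small planted study used across modules.
tiny_study <- function(seed = 3, n_subjects = 6, n_channels = 16,
                       sfreq = 128, epoch_ms = 500, k = 4, stretch_ms = 60,
                       noise = noise_spec()) {
  cfg <- sim_config(n_subjects = n_subjects, n_channels = n_channels,
                    sfreq = sfreq, epoch_ms = epoch_ms, seed = seed)
  spec <- planted_stroop_spec(cfg, k = k, stretch_ms = stretch_ms)
  c(simulate_erp_study(spec, noise, cfg), list(spec = spec, cfg = cfg))
}

noiseless_spec <- function() {
  noise_spec(sensor_noise_sd = 0, subject_amplitude_sd = 0,
             subject_latency_jitter_sd = 0)
}

# Build a study_dataset directly from a [ch, time, subj, cell] array of
# average-referenced data.
manual_study <- function(arr, sfreq = 100) {
  mont <- make_montage(dim(arr)[1], seed = 42)
  study_dataset(arr, mont, sfreq = sfreq, t0 = 0)
}

# Average-reference an array over its channel dimension.
center_ch <- function(arr) {
  sweep(arr, seq_along(dim(arr))[-1], apply(arr, seq_along(dim(arr))[-1], mean))
}
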