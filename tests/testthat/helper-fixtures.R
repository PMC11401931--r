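# Shared builders for small test problems.

# Compact session: 2 load runs of 8 trials (plus optional motor runs).
small_design <- function(trials_per_run = 8L, n_runs_load = 2L,
                         n_runs_motor = 0L) {
  design_spec(n_runs_load = n_runs_load, n_runs_motor = n_runs_motor,
              trials_per_run = trials_per_run)
}

# All analyzed layer x load-condition x period cells carry their pattern.
full_pattern_cells <- function(scale = 1) {
  pc <- expand.grid(layer = c("deep", "superficial"),
                    condition = c("high", "low"),
                    period = c("encoding", "delay", "retrieval"),
                    stringsAsFactors = FALSE)
  pc$scale <- scale
  pc
}

# Effects with decodable patterns in both analyzed layers.
pattern_effects <- function(dynamics = "stable", snr = 1.5, leakage = 0) {
  effect_spec(pattern_scale = full_pattern_cells(),
              pattern_dynamics = dynamics, pattern_snr = snr,
              leakage_lambda = leakage)
}

# Moderate noise used across decoding tests.
test_noise <- function(sigma = 0.5) {
  noise_spec(sigma = sigma, ar1_rho = 0.3, drift_order = 3,
             drift_scale = 0.3)
}

# Trial tensor built directly (bypassing simulation) for decoding unit
# tests: class means +/- delta on the first voxel, iid gaussian elsewhere.
toy_tensor <- function(n_trials = 16L, n_voxels = 10L, n_tps = 3L,
                       delta = 0, sigma = 1, seed = 1L) {
  set.seed(seed)
  labels <- rep(c("high", "high", "low", "low"), length.out = n_trials)
  prev <- c(NA_character_, labels[-n_trials])
  mu <- ifelse(labels == "high", delta, -delta)
  dat <- array(rnorm(n_trials * n_voxels * n_tps, sd = sigma),
               dim = c(n_trials, n_voxels, n_tps))
  dat[, 1L, ] <- dat[, 1L, ] + mu
  structure(list(data = dat, labels = labels, prev_labels = prev,
                 timepoint_times = (seq_len(n_tps) - 1L) * 2,
                 voxel_ids = sprintf("v%02d", seq_len(n_voxels)),
                 layer = "superficial", normalized = TRUE),
            class = "trial_tensor")
}

# Synthetic group accuracy matrices (subjects x train x test) with an
# optional added block, for 2-D cluster-test unit tests.
toy_group_mats <- function(n_subj = 9L, nt = 12L, sd = 0.03,
                           block_rows = NULL, block_cols = NULL,
                           block_gain = 0, seed = 1L) {
  set.seed(seed)
  mats <- array(0.5 + rnorm(n_subj * nt * nt, sd = sd),
                dim = c(n_subj, nt, nt))
  if (!is.null(block_rows)) {
    mats[, block_rows, block_cols] <- mats[, block_rows, block_cols] +
      block_gain
  }
  mats
}

# Subject-level null distributions drawn from the same generative law as a
# null cohort's observed accuracies (exchangeable by construction).
toy_subject_nulls <- function(n_subj = 9L, n_perm = 100L, nt = 16L,
                              sd = 0.05) {
  lapply(seq_len(n_subj), function(s) {
    structure(list(samples = matrix(0.5 + rnorm(n_perm * nt, sd = sd),
                                    n_perm, nt),
                   level = "subject",
                   timepoint_times = (seq_len(nt) - 1L) * 2),
              class = "null_distribution")
  })
}
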