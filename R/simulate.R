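#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the response peaking at
#' `peak_s` and the undershoot at `undershoot_s`, undershoot amplitude
#' `1/ratio`; normalized to unit time-integral so that a sustained boxcar
#' convolved with it plateaus at the boxcar's amplitude (injected amplitudes
#' are therefore in steady-state percent-signal-change units).
#'
#' @param t times in seconds (>= 0 contribute; negative times give 0).
#' @param peak_s,undershoot_s,ratio shape parameters.
#' @return numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = peak_s, rate = 1) -
                stats::dgamma(t, shape = undershoot_s, rate = 1) / ratio)
  h / (1 - 1 / ratio)
}

#' Trial-period windows used for signal injection
#'
#' Windows follow the task clock before any hemodynamic shift: encoding spans
#' sample plus mask, delay spans the maintenance period, retrieval spans the
#' probe/response window.
#'
#' @param spec a [design_spec()].
#' @return data.frame with columns `period`, `start_s`, `end_s` (seconds
#'   post trial onset).
#' @export
injection_periods <- function(spec) {
  enc_end <- spec$sample_s + spec$mask_s
  del_end <- enc_end + spec$delay_s
  ret_end <- del_end + spec$response_window_s
  data.frame(period = PERIODS,
             start_s = c(0, enc_end, del_end),
             end_s = c(enc_end, del_end, ret_end),
             stringsAsFactors = FALSE)
}

# Convolve per-(condition, period) boxcars with the HRF on a fine grid and
# sample at scan times. Returns array [scan, condition, period].
period_regressors <- function(events, spec, conditions, dt = 0.1,
                              hrf_fun = hrf_double_gamma) {
  periods <- injection_periods(spec)
  if (any(periods$end_s > spec$trial_duration_s + 1e-9)) {
    stop_ld("period boxcars extend past the trial window")
  }
  n_scans <- spec$n_scans
  scan_t <- (seq_len(n_scans) - 1L) * spec$tr_s
  grid_t <- seq(0, spec$run_length_s + 32, by = dt)
  hrf <- hrf_fun(seq(0, 32, by = dt))
  reg <- array(0, dim = c(n_scans, length(conditions), nrow(periods)),
               dimnames = list(NULL, conditions, periods$period))
  for (ci in seq_along(conditions)) {
    onsets <- events$onset_s[events$condition == conditions[ci]]
    if (!length(onsets)) next
    for (pi in seq_len(nrow(periods))) {
      box <- numeric(length(grid_t))
      for (on in onsets) {
        a <- on + periods$start_s[pi]
        b <- on + periods$end_s[pi]
        box <- box + as.numeric(grid_t >= a & grid_t < b)
      }
      conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid_t)] * dt
      reg[, ci, pi] <- stats::approx(grid_t, conv, xout = scan_t,
                                     rule = 2)$y
    }
  }
  reg
}

# AR(1) noise with marginal SD sigma plus random Legendre drift.
draw_noise <- function(n_voxels, n_scans, noise) {
  out <- matrix(0, n_voxels, n_scans)
  if (noise$sigma > 0) {
    innov_sd <- noise$sigma * sqrt(1 - noise$ar1_rho^2)
    eps <- matrix(stats::rnorm(n_voxels * n_scans, sd = innov_sd),
                  n_voxels, n_scans)
    eps[, 1L] <- stats::rnorm(n_voxels, sd = noise$sigma)
    out <- t(apply(eps, 1L, function(e) {
      stats::filter(e, noise$ar1_rho, method = "recursive")
    }))
  }
  if (noise$drift_order > 0 && noise$drift_scale > 0) {
    P <- legendre_basis(n_scans, noise$drift_order)[, -1L, drop = FALSE]
    coefs <- matrix(stats::rnorm(n_voxels * ncol(P), sd = noise$drift_scale),
                    n_voxels, ncol(P))
    out <- out + coefs %*% t(P)
  }
  out
}

#' Simulate one laminar fMRI run
#'
#' Builds the noise-free signal as, per voxel, the sum over conditions and
#' trial periods of `(univariate amplitude + pattern_snr * pattern scale *
#' pattern entry) * (period boxcar convolved with the HRF)` sampled at TRs,
#' adds deep-to-superficial leakage (`superficial <- superficial +
#' leakage_lambda * deep`, applied to the signal before noise), then AR(1)
#' noise and polynomial drift, and maps PSC-scale signal onto the raw
#' baseline (`raw = baseline + baseline/100 * psc` when `baseline > 0`, raw
#' = PSC otherwise).
#'
#' @param events one event table from [generate_design()].
#' @param patterns a [generate_patterns()] result.
#' @param effects an [effect_spec()].
#' @param noise a [noise_spec()].
#' @param spec the [design_spec()] the events were generated from.
#' @param seed integer seed for the noise draw.
#' @param keep_signal store the noise-free PSC signal in the ground truth.
#' @param hrf_fun HRF function of time in seconds.
#'
#' @return An object of class `voxel_timeseries`: list with `data`
#'   (voxels x scans), `tr_s`, `run`, `run_type`, `voxel_ids`, `layer` and
#'   `depth` per voxel, and a `ground_truth` record of everything injected.
#' @export
simulate_run <- function(events, patterns, effects, noise, spec,
                         seed = NULL, keep_signal = FALSE,
                         hrf_fun = hrf_double_gamma) {
  stopifnot(inherits(events, "event_table"), inherits(patterns, "pattern_set"),
            inherits(effects, "effect_spec"), inherits(noise, "noise_spec"),
            inherits(spec, "design_spec"))
  conditions <- run_conditions(events$run_type[1L])
  reg <- period_regressors(events, spec, conditions, hrf_fun = hrf_fun)
  n_scans <- spec$n_scans
  nv <- patterns$n_voxels
  sig <- lapply(LAYERS, function(layer) {
    s <- matrix(0, nv, n_scans)
    for (cond in conditions) {
      for (period in PERIODS) {
        amp <- cell_value(effects$amplitudes, layer, cond, period,
                          "amplitude", 0)
        psc <- cell_value(effects$pattern_scale, layer, cond, period,
                          "scale", 1) * effects$pattern_snr
        if (amp == 0 && psc == 0) next
        voxel_amp <- amp + psc * patterns$patterns[[layer]][[cond]][[period]]
        s <- s + voxel_amp %o% reg[, cond, period]
      }
    }
    s
  })
  names(sig) <- LAYERS
  if (effects$leakage_lambda > 0) {
    sig$superficial <- sig$superficial + effects$leakage_lambda * sig$deep
  }
  psc_signal <- do.call(rbind, sig)
  with_local_seed(seed, {
    eta <- draw_noise(nrow(psc_signal), n_scans, noise)
    psc_total <- psc_signal + eta
    gain <- if (noise$baseline > 0) noise$baseline / 100 else 1
    data <- noise$baseline + gain * psc_total
    # deterministic depths: voxel j of layer l sits at an evenly spaced
    # position inside the layer's third of [0, 1]; identical across runs
    depth <- (match(rep(LAYERS, each = nv), LAYERS) - 1L) / 3 +
      (rep(seq_len(nv), 3L) - 0.5) / (3 * nv)
    structure(list(
      data = data,
      tr_s = spec$tr_s,
      run = events$run[1L],
      run_type = events$run_type[1L],
      voxel_ids = paste0(rep(LAYERS, each = nv), "_",
                         sprintf("%04d", rep(seq_len(nv), 3L))),
      layer = rep(LAYERS, each = nv),
      depth = depth,
      ground_truth = list(
        effects = effects, noise = noise,
        periods = injection_periods(spec),
        signal_psc = if (keep_signal) psc_signal else NULL
      )
    ), class = "voxel_timeseries")
  })
}

#' Simulate a full single-subject session
#'
#' Generates the pseudorandomized design, ground-truth patterns (shared
#' across runs) and every run's voxel time series.
#'
#' @inheritParams simulate_run
#' @param spec a [design_spec()].
#' @param n_voxels_per_layer voxels per layer.
#' @param seed integer seed driving design, patterns and noise.
#' @param ensure_transitions redraw the design (bounded retries) until every
#'   trial-transition subtype occurs, so the session supports
#'   transition-balanced decoding; see [all_transitions_present()].
#' @param max_design_tries bounded retries for `ensure_transitions`.
#' @return list with `events` (list per run, previous conditions filled
#'   across runs), `runs` (list of `voxel_timeseries`), `patterns`, `spec`.
#' @export
simulate_subject <- function(spec, effects, noise, n_voxels_per_layer = 200L,
                             seed = NULL, keep_signal = FALSE,
                             ensure_transitions = TRUE,
                             max_design_tries = 50L) {
  with_local_seed(seed, {
    events <- NULL
    for (try in seq_len(max_design_tries)) {
      events <- fill_prev_across_runs(generate_design(spec))
      if (!ensure_transitions || all_transitions_present(events)) break
      if (try == max_design_tries) {
        stop_ld("could not draw a design with all transition subtypes in ",
                max_design_tries, " tries")
      }
    }
    patterns <- generate_patterns(n_voxels_per_layer, effects)
    runs <- lapply(events, function(ev) {
      simulate_run(ev, patterns, effects, noise, spec,
                   keep_signal = keep_signal)
    })
    list(events = events, runs = runs, patterns = patterns, spec = spec)
  })
}

#' Simulate a cohort of subjects
#'
#' @inheritParams simulate_subject
#' @param n_subjects number of subjects (study default 9).
#' @param seed integer; subject s uses sub-seed `seed + s`.
#' @return list of [simulate_subject()] results.
#' @export
simulate_cohort <- function(spec, effects, noise, n_subjects = 9L,
                            n_voxels_per_layer = 200L, seed = 1L) {
  lapply(seq_len(n_subjects), function(s) {
    simulate_subject(spec, effects, noise, n_voxels_per_layer,
                     seed = seed + s)
  })
}
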