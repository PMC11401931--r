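LAYERS <- c("deep", "middle", "superficial")
PERIODS <- c("encoding", "delay", "retrieval")
ALL_CONDITIONS <- c("high", "low", "response", "abstain")

#' Ground-truth effect specification for the simulator
#'
#' Describes what signal is injected into each cortical layer: a univariate
#' (spatially uniform) amplitude per layer x condition x period cell, in
#' percent-signal-change units of the peak hemodynamic response, and a
#' multivariate component built from unit-norm voxel patterns scaled by
#' `pattern_snr`. Patterns can be `stable` (one pattern per layer x
#' condition, shared by all trial periods) or `dynamic` (a near-orthogonal
#' pattern per period). A fraction `leakage_lambda` of the deep-layer signal
#' is added to the superficial layer, emulating venous draining in
#' gradient-echo BOLD.
#'
#' @param amplitudes `NULL` (all zero) or a data.frame with columns `layer`
#'   (`deep`, `middle`, `superficial`), `condition`, `period` (`encoding`,
#'   `delay`, `retrieval`) and `amplitude` (PSC). Unlisted cells are 0.
#' @param pattern_scale like `amplitudes` but with column `scale`,
#'   multiplying `pattern_snr` per cell; unlisted cells default to 1 when
#'   `pattern_snr > 0`, i.e. every cell carries its pattern unless turned
#'   off.
#' @param pattern_dynamics `"stable"` or `"dynamic"`.
#' @param leakage_lambda deep-to-superficial leakage fraction in `[0, 1)`.
#' @param pattern_snr scale of the multivariate pattern component (PSC units
#'   per unit pattern entry times sqrt(n voxels); a pattern entry has typical
#'   magnitude 1/sqrt(n voxels)).
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(amplitudes = NULL, pattern_scale = NULL,
                        pattern_dynamics = c("stable", "dynamic"),
                        leakage_lambda = 0, pattern_snr = 0) {
  pattern_dynamics <- match.arg(pattern_dynamics)
  check_number(leakage_lambda, "leakage_lambda", lower = 0, upper = 1 - 1e-12)
  check_number(pattern_snr, "pattern_snr", lower = 0)
  validate_cells <- function(df, value_col) {
    if (is.null(df)) return(NULL)
    needed <- c("layer", "condition", "period", value_col)
    if (!all(needed %in% names(df))) {
      stop_ld("cell table must have columns ", paste(needed, collapse = ", "))
    }
    if (!all(df$layer %in% LAYERS)) stop_ld("unknown layer in cell table")
    if (!all(df$period %in% PERIODS)) stop_ld("unknown period in cell table")
    if (!all(is.finite(df[[value_col]]))) stop_ld("cell values must be finite")
    df
  }
  structure(list(
    amplitudes = validate_cells(amplitudes, "amplitude"),
    pattern_scale = validate_cells(pattern_scale, "scale"),
    pattern_dynamics = pattern_dynamics,
    leakage_lambda = leakage_lambda,
    pattern_snr = pattern_snr
  ), class = "effect_spec")
}

# Look up a cell value (0 / default if unlisted).
cell_value <- function(df, layer, condition, period, value_col, default) {
  if (is.null(df)) return(default)
  hit <- df$layer == layer & df$condition == condition & df$period == period
  if (!any(hit)) return(default)
  sum(df[[value_col]][hit])
}

#' Noise specification for the simulator
#'
#' @param sigma marginal SD of the AR(1) noise, in the same
#'   percent-signal-change units as the injected amplitudes.
#' @param ar1_rho lag-1 autocorrelation, `|rho| < 1`.
#' @param drift_order polynomial order of the slow drift (0 disables the
#'   non-constant part).
#' @param drift_scale SD of the random Legendre drift coefficients (PSC).
#' @param baseline mean signal level in raw scanner units; the constant
#'   against which percent signal change is defined. With `baseline = 0` the
#'   output is in PSC units directly.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 1, ar1_rho = 0.3, drift_order = 3,
                       drift_scale = 0.5, baseline = 100) {
  check_number(sigma, "sigma", lower = 0)
  check_number(ar1_rho, "ar1_rho", lower = -1 + 1e-12, upper = 1 - 1e-12)
  drift_order <- check_count(drift_order, "drift_order")
  check_number(drift_scale, "drift_scale", lower = 0)
  check_number(baseline, "baseline", lower = 0)
  structure(list(sigma = sigma, ar1_rho = ar1_rho, drift_order = drift_order,
                 drift_scale = drift_scale, baseline = baseline),
            class = "noise_spec")
}

# Draw a unit-norm gaussian pattern.
unit_pattern <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

#' Generate ground-truth voxel patterns
#'
#' One unit-norm pattern per layer x condition (stable mode, shared across
#' trial periods) or per layer x condition x period (dynamic mode, resampled
#' until all within-cell period pairs satisfy |cosine| < `max_abs_cos`).
#'
#' @param n_voxels_per_layer voxels per layer (>= 2).
#' @param effects an [effect_spec()]; `pattern_dynamics` selects the mode.
#' @param seed integer seed.
#' @param conditions conditions to generate patterns for.
#' @param max_abs_cos orthogonality bound enforced in dynamic mode.
#' @param max_tries bounded resampling attempts.
#'
#' @return An object of class `pattern_set`: nested list
#'   `patterns[[layer]][[condition]][[period]]` of unit-norm vectors, with
#'   `n_voxels` and `dynamics` fields.
#' @export
generate_patterns <- function(n_voxels_per_layer, effects, seed = NULL,
                              conditions = ALL_CONDITIONS,
                              max_abs_cos = 0.3, max_tries = 200L) {
  n_voxels_per_layer <- check_count(n_voxels_per_layer, "n_voxels_per_layer",
                                    lower = 2L)
  stopifnot(inherits(effects, "effect_spec"))
  with_local_seed(seed, {
    pats <- lapply(LAYERS, function(layer) {
      by_cond <- lapply(conditions, function(cond) {
        if (effects$pattern_dynamics == "stable") {
          p <- unit_pattern(n_voxels_per_layer)
          stats::setNames(rep(list(p), length(PERIODS)), PERIODS)
        } else {
          for (i in seq_len(max_tries)) {
            ps <- replicate(length(PERIODS), unit_pattern(n_voxels_per_layer),
                            simplify = FALSE)
            cosines <- utils::combn(length(ps), 2, function(ij) {
              abs(sum(ps[[ij[1]]] * ps[[ij[2]]]))
            })
            if (all(cosines < max_abs_cos)) {
              return(stats::setNames(ps, PERIODS))
            }
          }
          stop_ld(sprintf(
            "could not draw period patterns with |cos| < %g in %d tries",
            max_abs_cos, max_tries))
        }
      })
      stats::setNames(by_cond, conditions)
    })
    structure(list(patterns = stats::setNames(pats, LAYERS),
                   n_voxels = n_voxels_per_layer,
                   dynamics = effects$pattern_dynamics),
              class = "pattern_set")
  })
}
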