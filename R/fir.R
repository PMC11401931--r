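# Tent (piecewise-linear hat) function centered at 0 with half-width w.
tent <- function(x, w) pmax(0, 1 - abs(x) / w)

# Legendre-style polynomials of degree 0..order on n equally spaced points
# mapped to [-1, 1], re-orthogonalized on the discrete scan grid
# (Gram polynomials) so columns are exactly orthogonal; the degree-0 column
# stays the constant 1 (the baseline predictor).
legendre_basis <- function(n, order) {
  if (order >= n) stop_ld("polynomial order must be < number of scans")
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) {
    for (k in seq_len(order)) {
      v <- x^k
      for (j in seq_len(k)) {
        v <- v - sum(v * P[, j]) / sum(P[, j]^2) * P[, j]
      }
      # scale to 1 at the right endpoint, matching Legendre convention
      P[, k + 1L] <- if (abs(v[n]) > 0) v / v[n] else v
    }
  }
  P
}

#' Tent-basis FIR design matrix with zero endpoints
#'
#' Builds the deconvolution basis for one event stream: `n_knots` knots
#' equally spaced over `[0, window_s]` seconds post-onset, a piecewise-linear
#' tent at each interior knot, and the first and last knots constrained to
#' zero (no regressor), so the estimated trial timecourse is anchored at 0 at
#' both ends. Each regressor is the tent evaluated at scan times relative to
#' every onset, summed over events — onsets need not be TR-locked.
#'
#' @param n_scans number of scans in the run.
#' @param tr_s repetition time, seconds.
#' @param onsets event onsets, seconds from run start.
#' @param window_s response window length, seconds.
#' @param n_knots total knots including the two zero endpoints (>= 3).
#'
#' @return list of class `basis_matrix`: `X` (scans x free knots),
#'   `knot_times` (free-knot times, seconds), `window_s`, `kind = "tentzero"`.
#' @export
build_tentzero_basis <- function(n_scans, tr_s, onsets, window_s = 32,
                                 n_knots = 17L) {
  n_knots <- check_count(n_knots, "n_knots", lower = 3L)
  check_number(window_s, "window_s", lower = 1e-9)
  spacing <- window_s / (n_knots - 1L)
  free_knots <- spacing * seq_len(n_knots - 2L)  # endpoints carry no regressor
  scan_t <- (seq_len(n_scans) - 1L) * tr_s
  X <- matrix(0, n_scans, length(free_knots))
  for (on in onsets) {
    rel <- scan_t - on
    inside <- rel > 0 & rel < window_s
    if (!any(inside)) next
    for (k in seq_along(free_knots)) {
      X[inside, k] <- X[inside, k] + tent(rel[inside] - free_knots[k], spacing)
    }
  }
  structure(list(X = X, knot_times = free_knots, window_s = window_s,
                 spacing = spacing, kind = "tentzero"),
            class = "basis_matrix")
}

#' Polynomial nuisance basis
#'
#' Legendre polynomials of degree 0..`order` over the run's scans, used to
#' detrend slow drift; degree 0 is the run's constant (baseline) predictor.
#'
#' @param n_scans scans in the run.
#' @param order highest polynomial degree (default 5).
#' @return list of class `basis_matrix`: `X` (scans x (order+1)), `kind =
#'   "nuisance"`.
#' @export
build_nuisance <- function(n_scans, order = 5L) {
  order <- check_count(order, "order")
  structure(list(X = legendre_basis(n_scans, order), order = order,
                 kind = "nuisance"),
            class = "basis_matrix")
}

#' Fit a finite-impulse-response GLM across concatenated runs
#'
#' Ordinary least squares of `[per-condition tent bases | per-run polynomial
#' nuisance]` on the run-concatenated voxel time series. Condition regressors
#' are built per run from that run's events and stacked; nuisance regressors
#' are block-diagonal by run so each run is detrended independently. The
#' run-wise degree-0 (constant) coefficients are averaged into the baseline
#' used for percent-signal-change scaling.
#'
#' @param runs list of `voxel_timeseries` sharing TR and voxel set.
#' @param events list of event tables, parallel to `runs`.
#' @param conditions condition labels to estimate; each must occur in at
#'   least one run.
#' @param window_s,n_knots tent basis parameters (see
#'   [build_tentzero_basis()]).
#' @param poly_order nuisance polynomial order per run.
#' @param exclude optional data.frame of trials to drop (columns `run`,
#'   `trial_index`), e.g. error trials; default keeps all trials.
#'
#' @return `fir_estimates`: list with `beta` (named list per condition of
#'   voxels x free-knots matrices), `knot_times`, `constant` (per-voxel mean
#'   baseline), `scale = "raw"`, `voxel_ids`, `layer`, `tr_s`.
#' @export
fit_fir <- function(runs, events, conditions, window_s = 32, n_knots = 17L,
                    poly_order = 5L, exclude = NULL) {
  stopifnot(length(runs) == length(events), length(runs) >= 1L)
  tr <- runs[[1L]]$tr_s
  vox <- runs[[1L]]$voxel_ids
  for (r in runs) {
    if (!isTRUE(all.equal(r$tr_s, tr)) || !identical(r$voxel_ids, vox)) {
      stop_ld("all runs must share TR and voxel set")
    }
  }
  seen <- unique(unlist(lapply(events, function(e) e$condition)))
  if (!all(conditions %in% seen)) {
    stop_ld("condition(s) absent from events: ",
            paste(setdiff(conditions, seen), collapse = ", "))
  }
  n_scans <- vapply(runs, function(r) ncol(r$data), integer(1L))
  cond_blocks <- list()
  nuis_blocks <- list()
  knot_times <- NULL
  for (i in seq_along(runs)) {
    ev <- events[[i]]
    if (!is.null(exclude)) {
      drop <- paste(ev$run, ev$trial_index) %in%
        paste(exclude$run, exclude$trial_index)
      ev <- ev[!drop, , drop = FALSE]
    }
    Xc <- lapply(conditions, function(cond) {
      b <- build_tentzero_basis(n_scans[i], tr,
                                ev$onset_s[ev$condition == cond],
                                window_s = window_s, n_knots = n_knots)
      knot_times <<- b$knot_times
      b$X
    })
    cond_blocks[[i]] <- do.call(cbind, Xc)
    nuis_blocks[[i]] <- build_nuisance(n_scans[i], poly_order)$X
  }
  n_free <- n_knots - 2L
  X_cond <- do.call(rbind, cond_blocks)
  # block-diagonal nuisance
  total_scans <- sum(n_scans)
  n_nuis <- poly_order + 1L
  X_nuis <- matrix(0, total_scans, n_nuis * length(runs))
  off <- 0L
  for (i in seq_along(runs)) {
    rows <- off + seq_len(n_scans[i])
    cols <- (i - 1L) * n_nuis + seq_len(n_nuis)
    X_nuis[rows, cols] <- nuis_blocks[[i]]
    off <- off + n_scans[i]
  }
  X <- cbind(X_cond, X_nuis)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- setdiff(seq_len(ncol(X)), qr_X$pivot[seq_len(qr_X$rank)])
    stop_ld("rank-deficient FIR design; aliased columns: ",
            paste(aliased, collapse = ", "))
  }
  Y <- t(do.call(cbind, lapply(runs, function(r) r$data)))  # scans x voxels
  B <- qr.coef(qr_X, Y)                                     # coefs x voxels
  beta <- lapply(seq_along(conditions), function(ci) {
    t(B[(ci - 1L) * n_free + seq_len(n_free), , drop = FALSE])
  })
  names(beta) <- conditions
  const_rows <- ncol(X_cond) + (seq_along(runs) - 1L) * n_nuis + 1L
  constant <- stats::setNames(colMeans(B[const_rows, , drop = FALSE]), vox)
  structure(list(beta = beta, knot_times = knot_times, constant = constant,
                 scale = "raw", voxel_ids = vox, layer = runs[[1L]]$layer,
                 tr_s = tr),
            class = "fir_estimates")
}

#' Convert FIR estimates to percent signal change
#'
#' Scales each voxel's tent coefficients by `100 / constant`, the run-mean
#' baseline from the constant predictor. Voxels with non-positive baseline
#' cannot be expressed in PSC and are dropped (with a message naming how
#' many).
#'
#' @param est `fir_estimates` with `scale = "raw"`.
#' @return `fir_estimates` with `scale = "psc"`.
#' @export
to_percent_signal_change <- function(est) {
  stopifnot(inherits(est, "fir_estimates"))
  if (est$scale != "raw") stop_ld("estimates are already in PSC")
  bad <- est$constant <= 0
  if (any(bad)) {
    message(sum(bad), " voxel(s) with non-positive baseline excluded from PSC")
  }
  keep <- which(!bad)
  est$beta <- lapply(est$beta, function(b) {
    100 * b[keep, , drop = FALSE] / est$constant[keep]
  })
  est$constant <- est$constant[keep]
  est$voxel_ids <- est$voxel_ids[keep]
  est$layer <- est$layer[keep]
  est$scale <- "psc"
  est
}

#' Layer-mean trial timecourses
#'
#' Unweighted mean of the per-voxel FIR estimates across a layer's ROI
#' voxels, per condition and knot.
#'
#' @param est `fir_estimates` (usually PSC-scaled).
#' @param layer_map a `layer_map` covering the estimate's voxels.
#' @param roi ROI id to average within.
#' @param layers which bins to report (default: the analyzed ones).
#' @return `trial_timecourse`: data.frame with columns `layer`, `condition`,
#'   `knot_time`, `value`.
#' @export
layer_timecourse <- function(est, layer_map, roi = NULL,
                             layers = c("deep", "superficial")) {
  stopifnot(inherits(est, "fir_estimates"), inherits(layer_map, "layer_map"))
  map <- layer_map
  if (!is.null(roi)) map <- map[map$roi == roi, , drop = FALSE]
  out <- list()
  for (layer in layers) {
    ids <- map$voxel_id[map$bin == layer]
    rows <- which(est$voxel_ids %in% ids)
    if (!length(rows)) stop_ld("no voxels for layer '", layer, "' in ROI")
    for (cond in names(est$beta)) {
      out[[length(out) + 1L]] <- data.frame(
        layer = layer, condition = cond, knot_time = est$knot_times,
        value = colMeans(est$beta[[cond]][rows, , drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  tc <- do.call(rbind, out)
  class(tc) <- c("trial_timecourse", "data.frame")
  tc
}
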