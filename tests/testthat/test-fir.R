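test_that("tentzero basis has 15 free regressors at 2 s spacing", {
  b <- build_tentzero_basis(n_scans = 50, tr_s = 2, onsets = 0,
                            window_s = 32, n_knots = 17)
  expect_equal(ncol(b$X), 15L)
  expect_equal(b$knot_times, seq(2, 30, by = 2))
  expect_equal(b$spacing, 2)
})

test_that("a TR-locked event loads each knot's regressor at its own scan", {
  b <- build_tentzero_basis(n_scans = 20, tr_s = 2, onsets = 0)
  # knot at 10 s is column 5; equals 1 at scan index 6 (time 10 s), 0 at
  # every other TR-locked scan
  expect_equal(b$X[6L, 5L], 1)
  expect_equal(b$X[-6L, 5L], rep(0, 19L))
})

test_that("non-TR-locked events split load between knots like a direct
           tent evaluation", {
  b <- build_tentzero_basis(n_scans = 20, tr_s = 2, onsets = 1.0)
  # brute-force oracle: evaluate every tent at every scan time directly
  scan_t <- (0:19) * 2
  oracle <- sapply(seq(2, 30, 2), function(knot) {
    rel <- scan_t - 1.0
    ifelse(rel > 0 & rel < 32, pmax(0, 1 - abs(rel - knot) / 2), 0)
  })
  expect_equal(b$X, unname(oracle))
  # scan at 2.0 s (rel 1.0 s) loads 0.5 on the 2 s knot only
  expect_equal(b$X[2L, 1L], 0.5)
  expect_equal(b$X[2L, -1L], rep(0, 14L))
})

test_that("nuisance basis is Legendre-orthogonal and absorbs drift", {
  b0 <- build_nuisance(30, order = 0)
  expect_equal(ncol(b0$X), 1L)
  expect_true(all(b0$X == 1))
  b5 <- build_nuisance(101, order = 5)
  expect_equal(ncol(b5$X), 6L)
  G <- crossprod(b5$X)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-10))
  expect_error(build_nuisance(4, order = 5), "order")

  # projection oracle: order >= 2 removes a pure quadratic drift
  x <- seq(-1, 1, length.out = 101)
  drift <- 3 * x^2 - 1
  resid <- drift - b5$X %*% solve(crossprod(b5$X), crossprod(b5$X, drift))
  expect_lt(sum(resid^2) / sum(drift^2), 1e-20)
})

test_that("fit_fir recovers known tent coefficients exactly (noise-free)", {
  spec <- small_design(n_runs_load = 1L)
  ev <- generate_design(spec, seed = 4)[[1L]]
  n_scans <- spec$n_scans
  beta_high <- sin(seq(2, 30, 2) / 5)
  beta_low <- cos(seq(2, 30, 2) / 7) * 0.5
  bh <- build_tentzero_basis(n_scans, 2, ev$onset_s[ev$condition == "high"])
  bl <- build_tentzero_basis(n_scans, 2, ev$onset_s[ev$condition == "low"])
  drift <- build_nuisance(n_scans, 5)$X %*% c(100, 2, -1, 0.5, 0.2, -0.3)
  y <- bh$X %*% beta_high + bl$X %*% beta_low + drift
  run <- structure(list(data = rbind(as.vector(y), as.vector(2 * y)),
                        tr_s = 2, run = 1L, run_type = "load",
                        voxel_ids = c("a", "b"),
                        layer = c("deep", "superficial")),
                   class = "voxel_timeseries")
  est <- fit_fir(list(run), list(ev), c("high", "low"))
  expect_equal(est$beta$high[1L, ], beta_high, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(est$beta$low[1L, ], beta_low, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(est$beta$high[2L, ], 2 * beta_high, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(est$constant, c(a = 100, b = 200), tolerance = 1e-8)

  # zero data give zero betas
  run0 <- run
  run0$data[] <- 0
  est0 <- fit_fir(list(run0), list(ev), c("high", "low"))
  expect_true(all(abs(unlist(est0$beta)) < 1e-10))
})

test_that("FIR equals event-locked averaging on spaced TR-locked designs", {
  # independent oracle: with non-overlapping TR-locked events and no drift,
  # the FIR estimate at knot k is the mean of the data k seconds post onset
  onsets <- c(20, 60, 100, 140)
  n_scans <- 90L
  set.seed(2)
  resp <- c(0, cumsum(rnorm(14)))  # arbitrary response, zero at endpoints
  y <- numeric(n_scans)
  for (on in onsets) {
    idx <- on / 2 + seq_len(15L) + 1L
    y[idx] <- y[idx] + resp
  }
  ev <- data.frame(onset_s = onsets, duration_s = 30, condition = "high",
                   run = 1L, run_type = "load",
                   trial_index = seq_along(onsets),
                   prev_condition = NA_character_)
  class(ev) <- c("event_table", "data.frame")
  run <- structure(list(data = matrix(y, 1L), tr_s = 2, run = 1L,
                        run_type = "load", voxel_ids = "a", layer = "deep"),
                   class = "voxel_timeseries")
  est <- fit_fir(list(run), list(ev), "high", poly_order = 0L)
  locked <- sapply(seq(2, 30, 2), function(k) {
    mean(y[onsets / 2 + k / 2 + 1L])
  })
  expect_equal(est$beta$high[1L, ], locked, tolerance = 1e-8,
               ignore_attr = TRUE)
  # endpoint constraint: nothing is estimated at 0 s or 32 s
  expect_false(any(est$knot_times %in% c(0, 32)))
})

test_that("conditions with identical events and data get identical betas", {
  spec <- small_design(n_runs_load = 1L)
  ev <- generate_design(spec, seed = 6)[[1L]]
  # duplicate the events under two labels at the same onsets: the design is
  # collinear, which fit_fir must refuse with a helpful error
  ev2 <- ev
  ev2$condition <- ifelse(ev$condition == "high", "low", "high")
  both <- rbind(ev, ev2)
  both <- both[order(both$onset_s), ]
  class(both) <- c("event_table", "data.frame")
  run <- structure(list(data = matrix(rnorm(spec$n_scans), 1L), tr_s = 2,
                        run = 1L, run_type = "load", voxel_ids = "a",
                        layer = "deep"),
                   class = "voxel_timeseries")
  expect_error(fit_fir(list(run), list(both), c("high", "low")),
               "rank-deficient")
})

test_that("PSC conversion scales by the constant and ignores raw gain", {
  est <- structure(list(beta = list(high = matrix(c(1, 2.5), 2L, 1L)),
                        knot_times = 2, constant = c(100, 50),
                        scale = "raw", voxel_ids = c("a", "b"),
                        layer = c("deep", "deep"), tr_s = 2),
                   class = "fir_estimates")
  psc <- to_percent_signal_change(est)
  expect_equal(psc$beta$high[, 1L], c(1, 5), ignore_attr = TRUE)
  expect_equal(psc$scale, "psc")
  expect_error(to_percent_signal_change(psc), "already")

  est2 <- est
  est2$beta$high <- est$beta$high * 7
  est2$constant <- est$constant * 7
  expect_equal(to_percent_signal_change(est2)$beta$high, psc$beta$high)

  est3 <- est
  est3$constant[2L] <- -1
  expect_message(psc3 <- to_percent_signal_change(est3), "excluded")
  expect_equal(psc3$voxel_ids, "a")
})

test_that("layer timecourses average voxels within each layer", {
  est <- structure(list(
    beta = list(high = rbind(rep(0, 15), rep(2, 15))),
    knot_times = seq(2, 30, 2), constant = c(100, 100), scale = "psc",
    voxel_ids = c("a", "b"), layer = c("deep", "deep"), tr_s = 2),
    class = "fir_estimates")
  map <- assign_layers(c(a = 0.1, b = 0.2))
  tc <- layer_timecourse(est, map, layers = "deep")
  expect_equal(tc$value, rep(1, 15))
  expect_error(layer_timecourse(est, map, layers = "superficial"),
               "no voxels")
})

test_that("FIR recovery is unbiased across noise seeds at moderate SNR", {
  spec <- small_design(n_runs_load = 1L)
  amps <- data.frame(layer = c("superficial", "deep"),
                     condition = "high", period = "delay",
                     amplitude = c(0.5, 0.5))
  eff <- effect_spec(amplitudes = amps)
  pat <- generate_patterns(10, eff, seed = 1)
  ev <- generate_design(spec, seed = 8)[[1L]]
  noise0 <- noise_spec(sigma = 0, drift_order = 0, drift_scale = 0,
                       baseline = 100)
  run0 <- simulate_run(ev, pat, eff, noise0, spec, seed = 1)
  ref <- to_percent_signal_change(
    fit_fir(list(run0), list(ev), c("high", "low")))
  ref_beta <- ref$beta$high
  slopes <- sapply(1:20, function(s) {
    noi <- noise_spec(sigma = 0.1, ar1_rho = 0.3, drift_order = 3,
                      drift_scale = 0.1, baseline = 100)
    run <- simulate_run(ev, pat, eff, noi, spec, seed = 100 + s)
    est <- to_percent_signal_change(
      fit_fir(list(run), list(ev), c("high", "low")))
    as.vector(coef(lm(as.vector(est$beta$high) ~ as.vector(ref_beta)))[2L])
  })
  expect_equal(mean(slopes), 1, tolerance = 0.05)
})
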