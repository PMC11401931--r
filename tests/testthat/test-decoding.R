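test_that("preprocessing zeroes means, unit-scales voxels, removes drift", {
  spec <- small_design(n_runs_load = 1L)
  eff <- effect_spec()
  noi <- test_noise(sigma = 1)
  run <- simulate_subject(spec, eff, noi, n_voxels_per_layer = 5,
                          seed = 4)$runs[[1L]]
  pp <- preprocess_run(run)
  expect_true(all(abs(rowMeans(pp$data)) < 1e-10))
  expect_equal(apply(pp$data, 1L, sd), rep(1, nrow(pp$data)),
               tolerance = 1e-10)

  # filter response oracle: a slow sine (period 500 s >> 128 s cutoff) must
  # lose almost all its power; a fast sine (period 20 s) must keep its shape
  t <- (0:251) * 2
  slow <- sin(2 * pi * t / 500)
  fast <- sin(2 * pi * t / 20)
  run2 <- run
  run2$data <- rbind(slow + 0.05 * fast, fast)
  bf <- signal::butter(3, (1 / 128) / (1 / 4), type = "high")
  filt_slow <- signal::filtfilt(bf, slow)
  expect_lt(sum(filt_slow^2) / sum(slow^2), 0.05)

  run3 <- run
  run3$data <- rbind(run$data, rep(5, ncol(run$data)))  # flat voxel
  expect_message(pp3 <- preprocess_run(run3, hp_cutoff_s = NULL),
                 "zero-variance")
  expect_equal(nrow(pp3$data), nrow(run$data))
})

test_that("epoching uses the rounded-down TR and drops clipped trials", {
  run <- structure(list(data = matrix(seq_len(3 * 40), 3L, 40L,
                                      byrow = TRUE),
                        tr_s = 2, run = 1L, run_type = "load",
                        voxel_ids = c("a", "b", "c"),
                        layer = rep("deep", 3L),
                        depth = c(0.1, 0.2, 0.3)),
                   class = "voxel_timeseries")
  ev <- data.frame(onset_s = c(5.3, 30.7, 50.0), duration_s = 30.7,
                   condition = c("high", "low", "high"), run = 1L,
                   run_type = "load", trial_index = 1:3,
                   prev_condition = c(NA, "high", "low"))
  class(ev) <- c("event_table", "data.frame")
  expect_message(tt <- epoch_trials(run, ev, n_trs = 17L), "dropped")
  expect_equal(dim(tt$data), c(2L, 3L, 17L))
  # floor(5.3/2) = 2 -> scans 3..19 (1-based); data row a holds 1..40
  expect_equal(tt$data[1L, 1L, ], seq(3, 19))
  # floor(30.7/2) = 15 -> scans 16..32
  expect_equal(tt$data[2L, 1L, ], seq(16, 32))
  expect_equal(tt$timepoint_times, seq(0, 32, 2))
  expect_equal(tt$labels, c("high", "low"))
})

test_that("a 16-trial run yields 16 epochs of 17 TRs given an adequate tail", {
  spec <- design_spec(baseline_s = 4)  # tail covers the last 32 s epoch
  eff <- effect_spec()
  subj <- simulate_subject(spec, eff, test_noise(), n_voxels_per_layer = 4,
                           seed = 1)
  tt <- epoch_trials(preprocess_run(subj$runs[[1L]]), subj$events[[1L]],
                     layer = "deep")
  expect_equal(dim(tt$data), c(16L, 4L, 17L))

  # without the tail, the default 504 s run clips the final trial's epoch,
  # which is dropped with a log message
  subj0 <- simulate_subject(design_spec(), eff, test_noise(),
                            n_voxels_per_layer = 4, seed = 1)
  expect_message(
    tt0 <- epoch_trials(preprocess_run(subj0$runs[[1L]]),
                        subj0$events[[1L]], layer = "deep"),
    "dropped")
  expect_equal(dim(tt0$data)[1L], 15L)
})

test_that("pair averaging is a 2-point moving mean labelled by the later TR", {
  tt <- toy_tensor(n_trials = 4L, n_voxels = 3L, n_tps = 3L, seed = 5)
  tt$data[1L, 1L, ] <- c(0, 2, 4)
  pa <- pair_average(tt)
  expect_equal(pa$data[1L, 1L, ], c(1, 3))
  expect_equal(pa$timepoint_times, c(2, 4))

  const <- toy_tensor(n_trials = 2L, n_voxels = 2L, n_tps = 4L)
  const$data[] <- 7
  expect_true(all(pair_average(const)$data == 7))

  # variance of the mean of two iid points is half the variance
  big <- toy_tensor(n_trials = 1000L, n_voxels = 1L, n_tps = 2L, seed = 6)
  v_in <- var(as.vector(big$data))
  v_out <- var(as.vector(pair_average(big)$data))
  expect_equal(v_out / v_in, 0.5, tolerance = 0.1)
})

test_that("trial normalization spatially z-scores and ignores offsets", {
  tt <- toy_tensor(n_trials = 1L, n_voxels = 3L, n_tps = 1L)
  tt$data[1L, , 1L] <- c(1, 2, 3)
  tn <- trial_normalize(tt)
  expect_equal(tn$data[1L, , 1L], c(-1, 0, 1) / sd(c(1, 2, 3)) * 1,
               tolerance = 1e-12)
  expect_equal(tn$data[1L, , 1L], c(-1, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  tt2 <- tt
  tt2$data <- tt$data + 100
  expect_equal(trial_normalize(tt2)$data, tn$data, tolerance = 1e-12)

  flat <- tt
  flat$data[] <- 3
  expect_message(fz <- trial_normalize(flat), "zero spatial SD")
  expect_true(all(fz$data == 0))
})

test_that("transition-balanced folds have the documented counts and balance", {
  mk <- function(counts) {
    # build labels/prev with given subtype counts (A<-A, A<-B, B<-A, B<-B)
    lab <- c(rep("a", counts[1]), rep("a", counts[2]),
             rep("b", counts[3]), rep("b", counts[4]))
    prev <- c(rep("a", counts[1]), rep("b", counts[2]),
              rep("a", counts[3]), rep("b", counts[4]))
    list(lab = lab, prev = prev)
  }
  x <- mk(c(6, 8, 8, 8))
  f <- build_folds(x$lab, x$prev, seed = 1)
  expect_equal(f$n_folds, 24L)
  x2 <- mk(c(4, 4, 4, 4))
  f2 <- build_folds(x2$lab, x2$prev, seed = 1)
  expect_equal(f2$n_folds, 16L)
  expect_equal(f2$k, 3L)
  subtype <- paste(x2$lab, x2$prev, sep = "<-")
  for (fold in f2$folds) {
    expect_length(intersect(fold$train, fold$test), 0L)
    expect_true(all(table(subtype[fold$train]) == f2$k))
  }
  keys <- sapply(f2$folds, function(fd) paste(fd$train, collapse = ","))
  expect_equal(anyDuplicated(keys), 0L)

  x3 <- mk(c(2, 2, 2, 0))
  expect_error(build_folds(x3$lab, x3$prev, seed = 1), "b<-b")
})

test_that("folds never overlap and NA-prev trials are test-only, many seeds", {
  lab <- rep(c("a", "a", "b", "b"), 4L)
  prev <- c(NA, lab[-16L])
  for (seed in 1:100) {
    f <- build_folds(lab, prev, seed = seed)
    for (fold in f$folds) {
      expect_length(intersect(fold$train, fold$test), 0L)
      expect_false(1L %in% fold$train)
    }
  }
  expect_identical(build_folds(lab, prev, seed = 7),
                   build_folds(lab, prev, seed = 7))
})

test_that("decoding is perfect on separable data and at chance on noise", {
  tt <- toy_tensor(n_trials = 16L, n_voxels = 6L, n_tps = 2L, delta = 50,
                   sigma = 0.1, seed = 8)
  tt <- trial_normalize(tt)
  f <- build_folds(tt$labels, tt$prev_labels, seed = 2)
  expect_equal(decode_timepoint(tt, f, 1L), 1.0)

  null <- toy_tensor(n_trials = 200L, n_voxels = 6L, n_tps = 1L, delta = 0,
                     seed = 9)
  null <- trial_normalize(null)
  fn <- build_folds(null$labels, null$prev_labels, seed = 3)
  acc <- decode_timepoint(null, fn, 1L)
  # binomial 99% CI around 0.5 at the test-set sizes involved
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("the SVM rule matches an exhaustive maximum-margin search on a
           2-voxel, 8-trial example", {
  set.seed(13)
  # well-separated classes, scaled so no slack is active at cost = 1
  X <- rbind(matrix(rnorm(8, mean = 4), 4L, 2L),
             matrix(rnorm(8, mean = -4), 4L, 2L))
  y <- rep(c("high", "low"), each = 4L)
  oracle <- brute_force_max_margin(X, y)
  expect_false(is.null(oracle))
  rule <- laminardyn:::svm_linear_rule(X, y, cost = 1)
  grid <- as.matrix(expand.grid(seq(-6, 6, 0.5), seq(-6, 6, 0.5)))
  dv <- as.vector(grid %*% rule$w) - rule$rho
  pred_svm <- ifelse(dv > 0, rule$lev_pos, rule$lev_neg)
  sc <- as.vector(grid %*% oracle$w) + oracle$b
  pred_oracle <- ifelse(sc > 0, "high", "low")
  away <- abs(sc) / sqrt(sum(oracle$w^2)) > 1e-6
  expect_identical(pred_svm[away], pred_oracle[away])
  # and the normal directions agree
  cosang <- sum(rule$w * oracle$w) /
    sqrt(sum(rule$w^2) * sum(oracle$w^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-4)
})

test_that("per-trial gain/offset class differences decode at chance after
           trial normalization", {
  set.seed(14)
  n_trials <- 48L
  n_vox <- 12L
  pattern <- rnorm(n_vox)
  labels <- rep(c("high", "high", "low", "low"), n_trials / 4L)
  gain <- ifelse(labels == "high", 2.0, 1.0)
  offset <- ifelse(labels == "high", 1.0, 0)
  dat <- array(0, dim = c(n_trials, n_vox, 2L))
  for (t in seq_len(n_trials)) {
    dat[t, , ] <- gain[t] * pattern + offset[t] +
      matrix(rnorm(n_vox * 2L, sd = 0.05), n_vox, 2L)
  }
  tt <- structure(list(data = dat, labels = labels,
                       prev_labels = c(NA, labels[-n_trials]),
                       timepoint_times = c(0, 2),
                       voxel_ids = sprintf("v%02d", seq_len(n_vox)),
                       layer = "superficial", normalized = FALSE),
                  class = "trial_tensor")
  tn <- trial_normalize(tt)
  f <- build_folds(tn$labels, tn$prev_labels, seed = 5)
  acc <- decode_timepoint(tn, f, 1L)
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
  # without normalization the same data are trivially decodable
  raw <- tt
  raw$normalized <- TRUE
  expect_gt(decode_timepoint(raw, f, 1L), 0.9)
})

test_that("cross-decoding diagonal equals the decoding timecourse and
           generalization reflects pattern dynamics", {
  spec <- small_design()
  noi <- test_noise(sigma = 0.3)
  stable <- simulate_subject(spec, pattern_effects("stable", snr = 2), noi,
                             n_voxels_per_layer = 30, seed = 31)
  ts <- prepare_decoding_tensor(stable$runs, stable$events, "superficial")
  fs <- build_folds(ts$labels, ts$prev_labels, seed = 6)
  cds <- cross_decode(ts, fs)
  tcs <- decode_timecourse(ts, fs)
  expect_equal(unname(diag(cds$a)), tcs$accuracy)

  # stable code: off-diagonal close to diagonal once the response is up
  up <- which(cds$timepoint_times >= 8 & cds$timepoint_times <= 26)
  offdiag <- outer(up, up, function(i, j) abs(cds$a[cbind(i, i)] -
                                                cds$a[cbind(i, j)]))
  expect_lt(mean(offdiag), 0.15)

  dynamic <- simulate_subject(spec, pattern_effects("dynamic", snr = 2), noi,
                              n_voxels_per_layer = 30, seed = 31)
  td <- prepare_decoding_tensor(dynamic$runs, dynamic$events, "superficial")
  fd <- build_folds(td$labels, td$prev_labels, seed = 6)
  cdd <- cross_decode(td, fd)
  enc <- which(cdd$timepoint_times %in% c(8, 10))
  ret <- which(cdd$timepoint_times %in% c(24, 26))
  expect_gt(mean(cdd$a[cbind(enc, enc)]), 0.8)
  expect_gt(mean(cdd$a[cbind(ret, ret)]), 0.8)
  expect_lt(mean(cdd$a[enc, ret]), 0.62)
  expect_lt(mean(cdd$a[ret, enc]), 0.62)
})
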