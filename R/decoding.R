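#' High-pass filter and z-score one run
#'
#' Third-order Butterworth high-pass (cutoff `1 / hp_cutoff_s` Hz) applied
#' zero-phase (forward and backward) to every voxel, followed by temporal
#' z-scoring of each voxel over the run. Voxels with zero variance are
#' excluded (with a message).
#'
#' @param run a `voxel_timeseries`.
#' @param hp_cutoff_s high-pass cutoff period in seconds; `NULL` or `Inf`
#'   skips filtering (z-scoring still applies).
#' @return the run with filtered, z-scored `data` (mean 0, SD 1 per voxel).
#' @export
preprocess_run <- function(run, hp_cutoff_s = 128) {
  x <- run$data
  if (!is.null(hp_cutoff_s) && is.finite(hp_cutoff_s)) {
    fs <- 1 / run$tr_s
    if (ncol(x) <= 2 * hp_cutoff_s / run$tr_s) {
      stop_ld("run too short for the requested high-pass cutoff")
    }
    bf <- signal::butter(3, (1 / hp_cutoff_s) / (fs / 2), type = "high")
    x <- t(apply(x, 1L, function(v) signal::filtfilt(bf, v)))
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  bad <- sdv == 0
  if (any(bad)) {
    message(sum(bad), " zero-variance voxel(s) excluded")
    x <- x[!bad, , drop = FALSE]
    run$voxel_ids <- run$voxel_ids[!bad]
    run$layer <- run$layer[!bad]
    run$depth <- run$depth[!bad]
    mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  run$data <- (x - mu) / sdv
  run
}

#' Cut a run into trial epochs
#'
#' Trial onsets are not TR-locked; each trial starts at the nearest
#' rounded-down TR (`floor(onset / TR)`) and spans `n_trs` scans (default 17
#' TRs = 32 s after the start TR). Trials extending past the run end are
#' dropped with a message.
#'
#' @param run a (preprocessed) `voxel_timeseries`.
#' @param events the run's event table.
#' @param n_trs scans per epoch.
#' @param layer optionally restrict to one depth bin's voxels.
#' @return `trial_tensor`: list with `data` (trials x voxels x timepoints),
#'   `labels`, `prev_labels`, `timepoint_times` (0, TR, ..., seconds),
#'   `voxel_ids`, `layer`, `normalized = FALSE`.
#' @export
epoch_trials <- function(run, events, n_trs = 17L, layer = NULL) {
  n_trs <- check_count(n_trs, "n_trs", lower = 2L)
  keep_vox <- if (is.null(layer)) seq_along(run$voxel_ids) else
    which(run$layer == layer)
  if (!length(keep_vox)) stop_ld("no voxels in layer '", layer, "'")
  starts <- floor(events$onset_s / run$tr_s)  # 0-based start scan
  ok <- starts + n_trs <= ncol(run$data)
  if (any(!ok)) {
    message(sum(!ok), " trial(s) extending past run end dropped")
  }
  starts <- starts[ok]
  dat <- array(NA_real_,
               dim = c(length(starts), length(keep_vox), n_trs))
  for (t in seq_along(starts)) {
    dat[t, , ] <- run$data[keep_vox, starts[t] + seq_len(n_trs), drop = FALSE]
  }
  structure(list(data = dat,
                 labels = events$condition[ok],
                 prev_labels = events$prev_condition[ok],
                 timepoint_times = (seq_len(n_trs) - 1L) * run$tr_s,
                 voxel_ids = run$voxel_ids[keep_vox],
                 layer = if (is.null(layer)) run$layer[keep_vox] else layer,
                 normalized = FALSE),
            class = "trial_tensor")
}

#' Concatenate trial tensors across runs
#'
#' @param tensors list of `trial_tensor`s sharing voxels and timepoints.
#' @return one `trial_tensor`.
#' @export
bind_tensors <- function(tensors) {
  t1 <- tensors[[1L]]
  for (t in tensors[-1L]) {
    if (!identical(t$voxel_ids, t1$voxel_ids) ||
        !identical(t$timepoint_times, t1$timepoint_times)) {
      stop_ld("tensors must share voxel set and timepoint grid")
    }
  }
  t1$data <- do.call(abind3, lapply(tensors, `[[`, "data"))
  t1$labels <- unlist(lapply(tensors, `[[`, "labels"))
  t1$prev_labels <- unlist(lapply(tensors, `[[`, "prev_labels"))
  t1
}

# rbind for trials x voxels x timepoints arrays
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1L],
                                            integer(1L))), d[2L], d[3L]))
  off <- 0L
  for (p in parts) {
    out[off + seq_len(dim(p)[1L]), , ] <- p
    off <- off + dim(p)[1L]
  }
  out
}

#' Moving average of adjacent timepoints
#'
#' Decoding timepoint k (k >= 2) becomes the mean of TRs k-1 and k; the
#' first timepoint is dropped and the remaining points keep the later TR's
#' timestamp.
#'
#' @param tensor a `trial_tensor`.
#' @return the tensor with one fewer timepoint.
#' @export
pair_average <- function(tensor) {
  d <- tensor$data
  nt <- dim(d)[3L]
  if (nt < 2L) stop_ld("need >= 2 timepoints")
  tensor$data <- (d[, , -1L, drop = FALSE] + d[, , -nt, drop = FALSE]) / 2
  tensor$timepoint_times <- tensor$timepoint_times[-1L]
  tensor
}

#' Spatial z-scoring of each trial pattern
#'
#' For every trial x timepoint, subtracts the across-voxel mean and divides
#' by the across-voxel SD, so classifiers cannot exploit per-trial univariate
#' gain or offset differences between conditions. Patterns with zero spatial
#' SD are mean-centered only (with a message).
#'
#' @param tensor a `trial_tensor` with >= 2 voxels.
#' @return the tensor with `normalized = TRUE`.
#' @export
trial_normalize <- function(tensor) {
  d <- tensor$data
  if (dim(d)[2L] < 2L) stop_ld("need >= 2 voxels")
  n_flag <- 0L
  for (t in seq_len(dim(d)[1L])) {
    m <- d[t, , , drop = FALSE]
    dim(m) <- dim(d)[2:3]
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    zero <- sdv == 0
    n_flag <- n_flag + sum(zero)
    sdv[zero] <- 1
    d[t, , ] <- sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  }
  if (n_flag > 0L) {
    message(n_flag, " trial-timepoint(s) with zero spatial SD mean-centered only")
  }
  tensor$data <- d
  tensor$normalized <- TRUE
  tensor
}

# Column z-scoring with zero-SD columns left centered.
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2L, mu), 2L, sdv, "/")
}

# Pre-extract, per fold and timepoint, feature-z-scored train and test
# matrices. Feature scaling is fit on the training set; test features are
# z-scored within the test set independently. Reused across label
# permutations (features do not change under relabelling).
prepare_fold_data <- function(tensor, folds) {
  stopifnot(inherits(tensor, "trial_tensor"), inherits(folds, "fold_set"))
  if (!isTRUE(tensor$normalized)) {
    stop_ld("tensor must be trial-normalized before decoding")
  }
  nt <- dim(tensor$data)[3L]
  slice <- function(rows, tp) {
    x <- tensor$data[rows, , tp, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    x
  }
  lapply(folds$folds, function(f) {
    Xtr <- lapply(seq_len(nt), function(tp) zscore_cols(slice(f$train, tp)))
    Xte <- lapply(seq_len(nt), function(tp) zscore_cols(slice(f$test, tp)))
    list(Xtr = Xtr, Xte_stack = do.call(rbind, Xte), n_test_tps = nt,
         y_train = tensor$labels[f$train],
         y_test = tensor$labels[f$test])
  })
}

# Train a linear SVM and return its linear decision rule. Positive decision
# values map to m$levels[m$labels[1]] (libsvm's internal first class); exact
# zeros predict the class with the lower label index.
svm_linear_rule <- function(X, y, cost) {
  m <- e1071::svm(X, factor(y), kernel = "linear", cost = cost,
                  scale = FALSE, fitted = FALSE)
  list(w = as.vector(crossprod(m$coefs, m$SV)),
       rho = m$rho,
       lev_pos = m$levels[m$labels[1L]],
       lev_neg = m$levels[m$labels[2L]],
       lev_tie = m$levels[1L])
}

# Core engine: accuracy for every (train_tp, test_tp) pair, averaged over
# folds. `relabel` optionally permutes each fold's training labels. All test
# timepoints are predicted in one matrix product per trained classifier.
decode_engine <- function(prep, train_tps, test_tps, cost = 1,
                          relabel = NULL) {
  acc <- matrix(0, length(train_tps), length(test_tps))
  for (f in prep) {
    y_tr <- if (is.null(relabel)) f$y_train else relabel(f$y_train)
    if (length(unique(y_tr)) < 2L) stop_ld("single-class training fold")
    n_te <- length(f$y_test)
    rows <- as.vector(outer(seq_len(n_te), (test_tps - 1L) * n_te, `+`))
    Xte <- f$Xte_stack[rows, , drop = FALSE]
    y_te <- rep(f$y_test, length(test_tps))
    for (i in seq_along(train_tps)) {
      rule <- svm_linear_rule(f$Xtr[[train_tps[i]]], y_tr, cost)
      dv <- as.vector(Xte %*% rule$w) - rule$rho
      pred <- rep(rule$lev_neg, length(dv))
      pred[dv > 0] <- rule$lev_pos
      pred[dv == 0] <- rule$lev_tie
      acc[i, ] <- acc[i, ] +
        colMeans(matrix(pred == y_te, n_te, length(test_tps)))
    }
  }
  acc / length(prep)
}

#' Decode condition labels at one (train, test) timepoint pair
#'
#' Linear support vector machine (cost `c = 1` by default) trained on the
#' trial-normalized, feature-z-scored training patterns at `train_tp` and
#' evaluated at `test_tp`; accuracy averaged over folds.
#'
#' @param tensor a trial-normalized `trial_tensor`.
#' @param folds a `fold_set` from [build_folds()].
#' @param train_tp,test_tp timepoint indices.
#' @param cost SVM cost parameter.
#' @return mean accuracy over folds.
#' @export
decode_timepoint <- function(tensor, folds, train_tp, test_tp = train_tp,
                             cost = 1) {
  prep <- prepare_fold_data(tensor, folds)
  decode_engine(prep, train_tp, test_tp, cost)[1L, 1L]
}

#' Temporal decoding timecourse
#'
#' Accuracy at every timepoint, training and testing on the same timepoint
#' under the same folds; equals the diagonal of [cross_decode()] run with
#' the same folds.
#'
#' @inheritParams decode_timepoint
#' @return `decoding_timecourse`: list with `accuracy` (per timepoint),
#'   `timepoint_times`, `chance = 0.5`.
#' @export
decode_timecourse <- function(tensor, folds, cost = 1) {
  prep <- prepare_fold_data(tensor, folds)
  nt <- dim(tensor$data)[3L]
  acc <- vapply(seq_len(nt), function(tp) {
    decode_engine(prep, tp, tp, cost)[1L, 1L]
  }, numeric(1L))
  structure(list(accuracy = acc, timepoint_times = tensor$timepoint_times,
                 chance = 0.5),
            class = "decoding_timecourse")
}

#' Temporal cross-decoding matrix
#'
#' Trains a classifier at every timepoint and tests it on every timepoint in
#' turn. Train and test trials never overlap at any matrix element, so the
#' diagonal is the ordinary decoding timecourse and off-diagonal elements
#' measure generalization of the multivariate code across time.
#'
#' @inheritParams decode_timepoint
#' @return `cross_decoding_matrix`: list with `a` (train x test accuracy
#'   matrix), `timepoint_times`, `chance = 0.5`.
#' @export
cross_decode <- function(tensor, folds, cost = 1) {
  prep <- prepare_fold_data(tensor, folds)
  nt <- dim(tensor$data)[3L]
  a <- decode_engine(prep, seq_len(nt), seq_len(nt), cost)
  dimnames(a) <- list(train = tensor$timepoint_times,
                      test = tensor$timepoint_times)
  structure(list(a = a, timepoint_times = tensor$timepoint_times,
                 chance = 0.5),
            class = "cross_decoding_matrix")
}

#' Prepare one subject's trial tensor for decoding
#'
#' Convenience wrapper over the per-run steps: high-pass filter + z-score
#' each run, epoch into 17-TR trials for one layer, concatenate runs,
#' moving-average adjacent TRs, and spatially z-score each trial pattern.
#'
#' @param runs list of `voxel_timeseries` (e.g. both load runs).
#' @param events matching event tables (previous conditions filled across
#'   runs; see [fill_prev_across_runs()]).
#' @param layer depth bin to decode from.
#' @param hp_cutoff_s high-pass cutoff, seconds.
#' @param n_trs scans per epoch before pair-averaging.
#' @return a trial-normalized `trial_tensor`.
#' @export
prepare_decoding_tensor <- function(runs, events, layer,
                                    hp_cutoff_s = 128, n_trs = 17L) {
  tensors <- lapply(seq_along(runs), function(i) {
    pr <- preprocess_run(runs[[i]], hp_cutoff_s)
    epoch_trials(pr, events[[i]], n_trs = n_trs, layer = layer)
  })
  trial_normalize(pair_average(bind_tensors(tensors)))
}
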