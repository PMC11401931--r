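#' Subject-level permutation null for decoding accuracy
#'
#' Re-runs the decoding with training labels permuted within each fold's
#' training set (test labels stay intact for scoring), `n_perm` times,
#' recording the accuracy timecourse of each permutation. Feature matrices
#' are unchanged by relabelling and are reused across permutations.
#'
#' @param tensor a trial-normalized `trial_tensor`.
#' @param folds the `fold_set` used for the empirical decoding.
#' @param n_perm number of permutations (study default 250).
#' @param seed integer seed.
#' @param cost SVM cost.
#' @return `null_distribution`: list with `samples` (n_perm x timepoints
#'   accuracy matrix), `level = "subject"`, `timepoint_times`.
#' @export
subject_null <- function(tensor, folds, n_perm = 250L, seed = NULL,
                         cost = 1) {
  n_perm <- check_count(n_perm, "n_perm", lower = 1L)
  prep <- prepare_fold_data(tensor, folds)
  nt <- dim(tensor$data)[3L]
  with_local_seed(seed, {
    samples <- matrix(NA_real_, n_perm, nt)
    for (p in seq_len(n_perm)) {
      relabel <- function(y) sample(y)
      samples[p, ] <- vapply(seq_len(nt), function(tp) {
        decode_engine(prep, tp, tp, cost, relabel = relabel)[1L, 1L]
      }, numeric(1L))
    }
    structure(list(samples = samples, level = "subject",
                   timepoint_times = tensor$timepoint_times),
              class = "null_distribution")
  })
}

#' Population-level null distribution of t-values
#'
#' For each draw, samples one whole permutation (a row of the subject null)
#' per subject and computes, per timepoint, a one-sample t versus chance
#' (above-chance tests) or a paired t between two layers' sampled values
#' (layer comparisons). Sampling whole permutations preserves each
#' permutation's own temporal covariance, which the cluster-level null
#' requires.
#'
#' @param subject_nulls list (one per subject) of subject
#'   `null_distribution`s.
#' @param subject_nulls2 optional second list (e.g. the other layer); when
#'   given the statistic is the paired t of the per-subject differences.
#' @param chance chance accuracy subtracted in the one-sample case.
#' @param n_draws number of population draws (study default 10,000).
#' @param seed integer seed.
#' @return `null_distribution` with `t_draws` (n_draws x timepoints),
#'   `level = "population"`.
#' @export
population_null <- function(subject_nulls, subject_nulls2 = NULL,
                            chance = 0.5, n_draws = 10000L, seed = NULL) {
  n_subj <- length(subject_nulls)
  if (n_subj < 2L) stop_ld("need >= 2 subjects")
  mats <- lapply(subject_nulls, `[[`, "samples")
  nt <- ncol(mats[[1L]])
  paired <- !is.null(subject_nulls2)
  if (paired) {
    mats2 <- lapply(subject_nulls2, `[[`, "samples")
    if (length(mats2) != n_subj) stop_ld("subject null lists differ in length")
  }
  with_local_seed(seed, {
    sums <- matrix(0, n_draws, nt)
    sumsq <- matrix(0, n_draws, nt)
    for (s in seq_len(n_subj)) {
      rows <- sample.int(nrow(mats[[s]]), n_draws, replace = TRUE)
      v <- mats[[s]][rows, , drop = FALSE]
      if (paired) {
        rows2 <- sample.int(nrow(mats2[[s]]), n_draws, replace = TRUE)
        v <- v - mats2[[s]][rows2, , drop = FALSE]
      } else {
        v <- v - chance
      }
      sums <- sums + v
      sumsq <- sumsq + v^2
    }
    m <- sums / n_subj
    v <- pmax(0, (sumsq - n_subj * m^2) / (n_subj - 1L))
    t_draws <- m / sqrt(v / n_subj)
    t_draws[v == 0] <- 0  # degenerate draws carry no evidence
    structure(list(t_draws = t_draws, level = "population",
                   n_subjects = n_subj, chance = chance, paired = paired),
              class = "null_distribution")
  })
}

# One-sample t per column of a subjects x elements matrix, against `center`.
col_tstats <- function(x, center = 0) {
  n <- nrow(x)
  m <- colMeans(x) - center
  v <- apply(x, 2L, stats::var)
  t <- m / sqrt(v / n)
  t[v == 0] <- NA_real_
  t
}

# Contiguous 1-D clusters of TRUE entries; returns list of index vectors.
runs_1d <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

# Clusters in a 1-D t vector given suprathreshold masks for each sign.
clusters_1d <- function(tvec, pos_mask, neg_mask) {
  cl <- c(lapply(runs_1d(pos_mask), function(ix) list(ix = ix, sign = 1)),
          lapply(runs_1d(neg_mask), function(ix) list(ix = ix, sign = -1)))
  lapply(cl, function(c) {
    c$summed_t <- sum(tvec[c$ix])
    c
  })
}

#' Temporal cluster-permutation test
#'
#' Computes pointwise t-statistics of the group accuracies against chance
#' (or of per-subject differences against 0), forms clusters of contiguous
#' timepoints whose pointwise permutation p is below
#' `cluster_forming_alpha` under the population null, and compares each
#' cluster's summed t against the null distribution of the maximum cluster
#' summed t across draws.
#'
#' @param group_values subjects x timepoints matrix (accuracies, or
#'   between-layer differences with `chance = 0`).
#' @param pop_null a population `null_distribution` built under the same
#'   statistic.
#' @param tail `"one"` (above chance) or `"two"` (layer comparisons).
#' @param chance value subtracted before the t-test.
#' @param cluster_forming_alpha pointwise threshold.
#' @return `cluster_result`: list with `clusters` (data.frame: `id`,
#'   `start`, `end`, `n_elements`, `summed_t`, `p`, `mean_d`, `sign`),
#'   `elements` (list of timepoint indices), `t` (pointwise), `tail`.
#'   No suprathreshold points gives an empty cluster list.
#' @export
temporal_cluster_test <- function(group_values, pop_null,
                                  tail = c("one", "two"), chance = 0.5,
                                  cluster_forming_alpha = 0.05) {
  tail <- match.arg(tail)
  stopifnot(inherits(pop_null, "null_distribution"),
            pop_null$level == "population")
  nt <- ncol(group_values)
  n <- nrow(group_values)
  if (nt < 2L) stop_ld("need >= 2 timepoints")
  t_obs <- col_tstats(group_values, chance)
  t_null <- pop_null$t_draws
  if (tail == "one") {
    hi <- apply(t_null, 2L, stats::quantile, probs = 1 - cluster_forming_alpha,
                na.rm = TRUE)
    lo <- rep(-Inf, nt)
  } else {
    hi <- apply(t_null, 2L, stats::quantile,
                probs = 1 - cluster_forming_alpha / 2, na.rm = TRUE)
    lo <- apply(t_null, 2L, stats::quantile, probs = cluster_forming_alpha / 2,
                na.rm = TRUE)
  }
  obs_cl <- clusters_1d(t_obs, !is.na(t_obs) & t_obs > hi,
                        !is.na(t_obs) & t_obs < lo)
  n_draws <- nrow(t_null)
  max_null <- vapply(seq_len(n_draws), function(dr) {
    tv <- t_null[dr, ]
    cl <- clusters_1d(tv, tv > hi, tv < lo)
    if (!length(cl)) 0 else max(vapply(cl, function(c) abs(c$summed_t),
                                       numeric(1L)))
  }, numeric(1L))
  summary_df <- do.call(rbind, lapply(seq_along(obs_cl), function(i) {
    c <- obs_cl[[i]]
    data.frame(id = i, start = min(c$ix), end = max(c$ix),
               n_elements = length(c$ix), summed_t = c$summed_t,
               p = (1 + sum(max_null >= abs(c$summed_t))) / (1 + n_draws),
               mean_d = mean(t_obs[c$ix] / sqrt(n)), sign = c$sign)
  }))
  structure(list(clusters = summary_df,
                 elements = lapply(obs_cl, `[[`, "ix"),
                 t = t_obs, tail = tail,
                 thresholds = list(hi = hi, lo = lo)),
            class = "cluster_result")
}

# 4-connected components of a logical matrix; returns list of linear index
# vectors. Only suprathreshold cells are visited.
label_4conn <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  lab <- integer(nr * nc)
  comps <- list()
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- integer(0)
    stack <- start
    lab[start] <- 1L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      nbrs <- c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                if (j > 1L) cur - nr, if (j < nc) cur + nr)
      for (nb in nbrs) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- 1L
          stack <- c(stack, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Clusters of a 2-D t matrix given sign-specific suprathreshold masks.
clusters_2d <- function(tmat, pos_mask, neg_mask) {
  cl <- c(lapply(label_4conn(pos_mask), function(ix) list(ix = ix, sign = 1)),
          lapply(label_4conn(neg_mask), function(ix) list(ix = ix, sign = -1)))
  lapply(cl, function(c) {
    c$summed_t <- sum(tmat[c$ix])
    c
  })
}

#' 2-D cluster-permutation test on cross-decoding matrices
#'
#' Element-wise t of the subjects' matrices against `chance`; the null is a
#' subject sign-flip: each permutation multiplies every subject's centered
#' matrix by an independent random sign. Elements whose pointwise permutation
#' p is below `cluster_forming_alpha` form 4-connected clusters; each
#' observed cluster's summed t is compared to the null distribution of the
#' maximum cluster summed t.
#'
#' @param group_mats subjects x train x test array (accuracies, or
#'   differences with `chance = 0`).
#' @param chance value subtracted before testing.
#' @param n_perm number of sign-flip permutations.
#' @param alternative `"greater"` (above chance), `"less"` (below, used by
#'   the dynamic-coding tests) or `"two.sided"`.
#' @param seed integer seed.
#' @param cluster_forming_alpha pointwise threshold.
#' @param exclude_diag drop the diagonal from clusters (used when testing
#'   `a_ij - a_ii` style differences whose diagonal is identically 0).
#' @return `cluster_result` with 2-D clusters; `elements` holds linear
#'   indices into the train x test matrix, and `t_matrix` the pointwise t.
#' @export
matrix_cluster_test <- function(group_mats, chance = 0.5, n_perm = 10000L,
                                alternative = c("greater", "less",
                                                "two.sided"),
                                seed = NULL, cluster_forming_alpha = 0.05,
                                exclude_diag = FALSE) {
  alternative <- match.arg(alternative)
  dims <- dim(group_mats)
  if (length(dims) != 3L || dims[1L] < 2L) {
    stop_ld("need a subjects x train x test array with >= 2 subjects")
  }
  n <- dims[1L]; nr <- dims[2L]; nc <- dims[3L]
  M <- matrix(group_mats, n, nr * nc) - chance  # subjects x elements
  keep <- rep(TRUE, nr * nc)
  if (exclude_diag) keep[(seq_len(min(nr, nc)) - 1L) * nr +
                           seq_len(min(nr, nc))] <- FALSE
  ss <- colSums(M^2)  # invariant under sign flips
  t_from_means <- function(m) {
    v <- pmax(0, (ss - n * m^2) / (n - 1L))
    t <- m / sqrt(v / n)
    t[v == 0] <- NA_real_
    t
  }
  t_obs <- t_from_means(colMeans(M))
  with_local_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    Mt <- S %*% M / n  # n_perm x elements matrix of flipped means
    t_perm <- t(apply(Mt, 1L, t_from_means))
    probs <- switch(alternative,
                    greater = c(1 - cluster_forming_alpha, NA),
                    less = c(NA, cluster_forming_alpha),
                    two.sided = c(1 - cluster_forming_alpha / 2,
                                  cluster_forming_alpha / 2))
    hi <- if (is.na(probs[1L])) rep(Inf, nr * nc) else
      apply(t_perm, 2L, stats::quantile, probs = probs[1L], na.rm = TRUE)
    lo <- if (is.na(probs[2L])) rep(-Inf, nr * nc) else
      apply(t_perm, 2L, stats::quantile, probs = probs[2L], na.rm = TRUE)
    hi[!keep] <- Inf
    lo[!keep] <- -Inf
    supra <- function(tv) {
      list(pos = matrix(!is.na(tv) & tv > hi, nr, nc),
           neg = matrix(!is.na(tv) & tv < lo, nr, nc))
    }
    so <- supra(t_obs)
    tmat_obs <- matrix(t_obs, nr, nc)
    obs_cl <- clusters_2d(tmat_obs, so$pos, so$neg)
    max_null <- vapply(seq_len(n_perm), function(p) {
      tv <- t_perm[p, ]
      sp <- supra(tv)
      cl <- clusters_2d(matrix(tv, nr, nc), sp$pos, sp$neg)
      if (!length(cl)) 0 else max(vapply(cl, function(c) abs(c$summed_t),
                                         numeric(1L)))
    }, numeric(1L))
    summary_df <- do.call(rbind, lapply(seq_along(obs_cl), function(i) {
      c <- obs_cl[[i]]
      data.frame(id = i, n_elements = length(c$ix), summed_t = c$summed_t,
                 p = (1 + sum(max_null >= abs(c$summed_t))) / (1 + n_perm),
                 mean_d = mean(tmat_obs[c$ix] / sqrt(n)), sign = c$sign)
    }))
    structure(list(clusters = summary_df,
                   elements = lapply(obs_cl, `[[`, "ix"),
                   t_matrix = tmat_obs, alternative = alternative,
                   dim = c(nr, nc)),
              class = "cluster_result")
  })
}

# Linear indices of significant clusters of a cluster_result.
significant_elements <- function(res, alpha = 0.05) {
  if (is.null(res$clusters) || !nrow(res$clusters)) return(integer(0))
  sig <- res$clusters$id[res$clusters$p < alpha]
  sort(unique(unlist(res$elements[sig])))
}

#' Dynamic-coding elements of cross-decoding matrices
#'
#' Off-diagonal elements a_ij are dynamic when they decode worse than both
#' of their diagonal partners (a_ij < a_ii and a_ij < a_jj): two one-tailed
#' ("less") 2-D cluster tests are run on a_ij - a_ii and a_ij - a_jj, and an
#' element is marked dynamic only if it lies in a significant cluster of
#' both tests and both its diagonal partners lie inside significant
#' above-chance clusters.
#'
#' @param group_mats subjects x train x test accuracy array.
#' @param above_chance a `cluster_result` from [matrix_cluster_test()] run
#'   on the same matrices with `alternative = "greater"`.
#' @param n_perm sign-flip permutations for the two difference tests.
#' @param seed integer seed.
#' @param alpha significance level for all cluster memberships.
#' @return `dynamic_mask`: list with `mask` (logical train x test matrix),
#'   `test_ii`, `test_jj` (the two `cluster_result`s).
#' @export
dynamic_elements <- function(group_mats, above_chance, n_perm = 10000L,
                             seed = NULL, alpha = 0.05) {
  dims <- dim(group_mats)
  nr <- dims[2L]; nc <- dims[3L]
  if (nr != nc) stop_ld("cross-decoding matrices must be square")
  # D1[s,i,j] = a[s,i,j] - a[s,i,i]; D2[s,i,j] = a[s,i,j] - a[s,j,j]
  diag_vals <- vapply(seq_len(nr), function(i) group_mats[, i, i],
                      numeric(dims[1L]))  # subjects x i
  D1 <- group_mats
  D2 <- group_mats
  for (i in seq_len(nr)) D1[, i, ] <- group_mats[, i, ] - diag_vals[, i]
  for (j in seq_len(nc)) D2[, , j] <- group_mats[, , j] - diag_vals[, j]
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  test_ii <- matrix_cluster_test(D1, chance = 0, n_perm = n_perm,
                                 alternative = "less", seed = seed,
                                 exclude_diag = TRUE)
  test_jj <- matrix_cluster_test(D2, chance = 0, n_perm = n_perm,
                                 alternative = "less", seed = seed2,
                                 exclude_diag = TRUE)
  sig1 <- significant_elements(test_ii, alpha)
  sig2 <- significant_elements(test_jj, alpha)
  sig_above <- significant_elements(above_chance, alpha)
  mask <- matrix(FALSE, nr, nc)
  cand <- intersect(sig1, sig2)
  for (lin in cand) {
    i <- (lin - 1L) %% nr + 1L
    j <- (lin - 1L) %/% nr + 1L
    if (i == j) next
    ii_lin <- (i - 1L) * nr + i
    jj_lin <- (j - 1L) * nr + j
    if (ii_lin %in% sig_above && jj_lin %in% sig_above) mask[i, j] <- TRUE
  }
  structure(list(mask = mask, test_ii = test_ii, test_jj = test_jj,
                 alpha = alpha),
            class = "dynamic_mask")
}
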