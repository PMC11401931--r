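test_that("identity relabelling reproduces the empirical accuracy and
           permuted labels hover at chance", {
  tt <- trial_normalize(toy_tensor(n_trials = 16L, n_voxels = 8L,
                                   n_tps = 2L, delta = 3, sigma = 0.5,
                                   seed = 21))
  f <- build_folds(tt$labels, tt$prev_labels, seed = 4)
  prep <- laminardyn:::prepare_fold_data(tt, f)
  emp <- laminardyn:::decode_engine(prep, 1L, 1L)
  ident <- laminardyn:::decode_engine(prep, 1L, 1L, relabel = identity)
  expect_identical(emp, ident)

  sn <- subject_null(tt, f, n_perm = 20L, seed = 5)
  expect_equal(dim(sn$samples), c(20L, 2L))
  expect_lt(abs(mean(sn$samples) - 0.5), 0.08)
  expect_identical(subject_null(tt, f, n_perm = 5L, seed = 9)$samples,
                   subject_null(tt, f, n_perm = 5L, seed = 9)$samples)
})

test_that("population nulls have the right shape, symmetry and determinism", {
  nulls <- toy_subject_nulls(n_subj = 9L, n_perm = 60L, nt = 8L)
  pn <- population_null(nulls, n_draws = 2000L, seed = 6)
  expect_equal(dim(pn$t_draws), c(2000L, 8L))
  # symmetric subject nulls about chance give a t-null centred on 0
  expect_lt(abs(mean(pn$t_draws)), 0.05)
  pn2 <- population_null(nulls, n_draws = 2000L, seed = 6)
  expect_identical(pn$t_draws, pn2$t_draws)

  # degenerate nulls at exactly chance are flagged as zero-evidence draws
  degen <- lapply(1:3, function(s) {
    structure(list(samples = matrix(0.5, 10L, 4L), level = "subject"),
              class = "null_distribution")
  })
  pd <- population_null(degen, n_draws = 50L, seed = 1)
  expect_true(all(pd$t_draws == 0))

  paired <- population_null(nulls, toy_subject_nulls(9L, 60L, 8L),
                            n_draws = 500L, seed = 7)
  expect_true(paired$paired)
  expect_lt(abs(mean(paired$t_draws)), 0.05)
  expect_error(population_null(nulls[1L]), ">= 2 subjects")
})

test_that("temporal cluster test recovers an injected contiguous effect", {
  set.seed(8)
  nt <- 16L
  group <- matrix(0.5 + rnorm(9L * nt, sd = 0.03), 9L, nt)
  group[, 4:6] <- group[, 4:6] + 0.25
  pn <- population_null(toy_subject_nulls(9L, 100L, nt, sd = 0.03),
                        n_draws = 1000L, seed = 9)
  res <- temporal_cluster_test(group, pn, tail = "one")
  expect_equal(nrow(res$clusters), 1L)
  expect_identical(res$elements[[1L]], 4:6)
  expect_lt(res$clusters$p, 0.05)
  expect_equal(res$clusters$mean_d,
               mean(res$t[4:6] / sqrt(9)), tolerance = 1e-12)
})

test_that("single suprathreshold points form size-1 clusters and null data
           give empty results", {
  set.seed(10)
  nt <- 12L
  pn <- population_null(toy_subject_nulls(9L, 100L, nt, sd = 0.03),
                        n_draws = 1000L, seed = 11)
  spike <- matrix(0.5 + rnorm(9L * nt, sd = 0.03), 9L, nt)
  spike[, 7L] <- spike[, 7L] + 0.3
  res <- temporal_cluster_test(spike, pn, tail = "one")
  expect_true(any(res$clusters$n_elements == 1L &
                    vapply(res$elements, function(e) 7L %in% e,
                           logical(1L))))

  # exactly-at-chance data have no suprathreshold points: empty result is
  # a valid outcome
  null_group <- matrix(0.5, 9L, nt)
  res0 <- temporal_cluster_test(null_group, pn, tail = "one")
  expect_null(res0$clusters)
  expect_length(res0$elements, 0L)
})

test_that("matrix cluster test recovers injected blocks and respects
           sign symmetry", {
  mats <- toy_group_mats(block_rows = 3:5, block_cols = 3:5,
                         block_gain = 0.25, seed = 12)
  res <- matrix_cluster_test(mats, n_perm = 500L, seed = 13)
  expect_gte(nrow(res$clusters), 1L)
  best <- res$elements[[which.min(res$clusters$p)]]
  true_block <- as.vector(outer(3:5, (3:5 - 1L) * 12L, `+`))
  expect_gte(length(intersect(best, true_block)) / 9, 0.9)
  expect_lte(length(setdiff(best, true_block)) / (144 - 9), 0.05)
  expect_lt(min(res$clusters$p), 0.05)

  # flipping every subject's sign mirrors t under the two-sided test
  centered <- mats - 0.5
  res_pos <- matrix_cluster_test(0.5 + centered, n_perm = 100L,
                                 alternative = "two.sided", seed = 14)
  res_neg <- matrix_cluster_test(0.5 - centered, n_perm = 100L,
                                 alternative = "two.sided", seed = 14)
  expect_equal(abs(res_pos$t_matrix), abs(res_neg$t_matrix),
               tolerance = 1e-12)
  expect_error(matrix_cluster_test(mats[1L, , , drop = FALSE]),
               ">= 2 subjects")
})

test_that("dynamic elements require both diagonal partners and both
           conjunction tests", {
  # construct matrices with strong diagonal everywhere and a dip at the
  # encoding x retrieval intersections
  nt <- 10L
  set.seed(15)
  base <- array(0.5 + rnorm(9 * nt * nt, sd = 0.02), dim = c(9L, nt, nt))
  within <- rbind(c(1, 4), c(5, 8))  # two "periods" of timepoints
  for (b in 1:2) {
    r <- within[b, 1L]:within[b, 2L]
    base[, r, r] <- base[, r, r] + 0.4
  }
  for (i in seq_len(nt)) base[, i, i] <- base[, i, i] + 0.05
  res_above <- matrix_cluster_test(base, n_perm = 300L, seed = 16)
  dyn <- dynamic_elements(base, res_above, n_perm = 300L, seed = 17)
  expect_true(any(dyn$mask))
  # dynamic elements sit strictly off-diagonal
  expect_true(all(!diag(dyn$mask)))
  # every masked element is below both diagonal partners on average
  means <- apply(base, c(2L, 3L), mean)
  for (lin in which(dyn$mask)) {
    i <- (lin - 1L) %% nt + 1L
    j <- (lin - 1L) %/% nt + 1L
    expect_lt(means[i, j], means[i, i])
    expect_lt(means[i, j], means[j, j])
  }

  # stable code: off-diagonal as strong as the diagonal leaves no dynamic
  # elements
  stable <- array(0.9 + rnorm(9 * nt * nt, sd = 0.02), dim = c(9L, nt, nt))
  res_above_s <- matrix_cluster_test(stable, n_perm = 300L, seed = 18)
  dyn_s <- dynamic_elements(stable, res_above_s, n_perm = 300L, seed = 19)
  expect_false(any(dyn_s$mask))
})

test_that("an element decoding above its diagonal partner can never be
           dynamic", {
  nt <- 6L
  set.seed(20)
  mats <- array(0.8 + rnorm(9 * nt * nt, sd = 0.01), dim = c(9L, nt, nt))
  mats[, 2L, 5L] <- 0.99  # better than both partners
  above <- matrix_cluster_test(mats, n_perm = 200L, seed = 21)
  dyn <- dynamic_elements(mats, above, n_perm = 200L, seed = 22)
  expect_false(dyn$mask[2L, 5L])
})

test_that("seeded permutation machinery is bit-reproducible", {
  mats <- toy_group_mats(seed = 23)
  r1 <- matrix_cluster_test(mats, n_perm = 200L, seed = 24)
  r2 <- matrix_cluster_test(mats, n_perm = 200L, seed = 24)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$t_matrix, r2$t_matrix)
})
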