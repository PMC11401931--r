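#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with validation.
#' `mode = "simulate"` generates a synthetic cohort from the design, effect
#' and noise specs; `mode = "external"` reads per-subject fixture
#' directories written by [write_fixture()] (or of the same shape).
#'
#' @param out_dir output directory.
#' @param mode `"simulate"` or `"external"`.
#' @param subject_dirs fixture directories, one per subject (external mode).
#' @param contrast `"load"` or `"motor"`.
#' @param n_subjects,n_voxels_per_layer cohort size (simulate mode).
#' @param design,effects,noise simulation specs.
#' @param periods univariate analysis windows ([analysis_periods()]).
#' @param cost,hp_cutoff_s,n_trs decoding parameters.
#' @param n_subject_perm,n_population_draws,n_matrix_perm,alpha permutation
#'   parameters; `alpha` must lie strictly inside (0, 1).
#' @param run_univariate,run_decoding,run_crossdecoding,figures stage
#'   toggles.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, mode = c("simulate", "external"),
                            subject_dirs = NULL, contrast = "load",
                            n_subjects = 9L, n_voxels_per_layer = 200L,
                            design = design_spec(), effects = effect_spec(),
                            noise = noise_spec(),
                            periods = analysis_periods(), cost = 1,
                            hp_cutoff_s = 128, n_trs = 17L,
                            n_subject_perm = 250L,
                            n_population_draws = 10000L,
                            n_matrix_perm = 10000L, alpha = 0.05,
                            run_univariate = TRUE, run_decoding = TRUE,
                            run_crossdecoding = TRUE, figures = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_ld("alpha must be strictly inside (0, 1)")
  }
  contrast_conditions(contrast)  # validates
  if (mode == "external") {
    if (is.null(subject_dirs) || !all(dir.exists(subject_dirs))) {
      stop_ld("external mode requires existing subject_dirs")
    }
  } else {
    stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"),
              inherits(noise, "noise_spec"))
  }
  structure(list(out_dir = out_dir, mode = mode, subject_dirs = subject_dirs,
                 contrast = contrast, n_subjects = n_subjects,
                 n_voxels_per_layer = n_voxels_per_layer, design = design,
                 effects = effects, noise = noise, periods = periods,
                 cost = cost, hp_cutoff_s = hp_cutoff_s, n_trs = n_trs,
                 n_subject_perm = n_subject_perm,
                 n_population_draws = n_population_draws,
                 n_matrix_perm = n_matrix_perm, alpha = alpha,
                 run_univariate = run_univariate, run_decoding = run_decoding,
                 run_crossdecoding = run_crossdecoding, figures = figures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reduced-size demonstration configuration
#'
#' A configuration that exercises every stage on a small synthetic cohort
#' (9 subjects, 40 voxels/layer, 8 trials/run, reduced permutation counts)
#' with superficial-layer load effects and dynamic patterns injected.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
demo_config <- function(out_dir, seed = 1L) {
  amps <- data.frame(
    layer = "superficial",
    condition = "high",
    period = c("encoding", "delay", "retrieval"),
    amplitude = c(0.3, 0.25, 0.3))
  pattern_cells <- expand.grid(layer = c("deep", "superficial"),
                               condition = c("high", "low"),
                               period = PERIODS,
                               stringsAsFactors = FALSE)
  pattern_cells$scale <- 1
  pipeline_config(
    out_dir = out_dir, mode = "simulate", contrast = "load",
    n_subjects = 9L, n_voxels_per_layer = 40L,
    design = design_spec(trials_per_run = 8L),
    effects = effect_spec(amplitudes = amps, pattern_scale = pattern_cells,
                          pattern_dynamics = "dynamic", pattern_snr = 1.5,
                          leakage_lambda = 0.2),
    noise = noise_spec(sigma = 0.5, ar1_rho = 0.3, drift_order = 3,
                       drift_scale = 0.3),
    n_subject_perm = 30L, n_population_draws = 500L, n_matrix_perm = 500L,
    seed = seed)
}

write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, assign depth bins and check layer balance,
#' estimate univariate layer timecourses and period contrasts, run temporal
#' decoding with permutation cluster inference, temporal cross-decoding with
#' 2-D cluster tests and the dynamic-coding conjunction, and the
#' period-by-layer permutation ANOVA. All outputs (TSV tables, a
#' machine-readable `results.json`, a parameter log, and optionally figures)
#' are written under `config$out_dir`. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the results list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_ld(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  results <- list(seed = config$seed, contrast = config$contrast)

  cohort <- stage("simulate", {
    if (config$mode == "simulate") {
      simulate_cohort(config$design, config$effects, config$noise,
                      n_subjects = config$n_subjects,
                      n_voxels_per_layer = config$n_voxels_per_layer,
                      seed = config$seed)
    } else {
      lapply(config$subject_dirs, read_fixture)
    }
  })

  stage("layers", {
    maps <- lapply(cohort, function(s) layer_map_from_run(s$runs[[1L]]))
    bal <- check_layer_balance(maps)
    write_results_tsv(bal$tests, file.path(config$out_dir,
                                           "layer_balance.tsv"))
    results$layer_balance <- bal$tests
  })

  if (config$run_univariate) {
    stage("univariate", {
      uni <- univariate_layer_analysis(cohort, config$contrast,
                                       config$periods)
      write_results_tsv(uni$tests, file.path(config$out_dir,
                                             "univariate_tests.tsv"))
      write_results_tsv(uni$effects, file.path(config$out_dir,
                                               "univariate_effects.tsv"))
      results$univariate <- uni$tests
    })
  }

  decode <- NULL
  if (config$run_decoding || config$run_crossdecoding) {
    decode <- stage("decode", {
      cohort_cross_decode(cohort, config$contrast, seed = config$seed + 100L,
                          cost = config$cost,
                          hp_cutoff_s = config$hp_cutoff_s,
                          n_trs = config$n_trs)
    })
  }

  if (config$run_decoding) {
    stage("stats_temporal", {
      temporal <- list()
      nulls <- list()
      for (layer in names(decode$layers)) {
        L <- decode$layers[[layer]]
        nulls[[layer]] <- lapply(seq_along(L$tensors), function(s) {
          subject_null(L$tensors[[s]], L$folds[[s]],
                       n_perm = config$n_subject_perm,
                       seed = config$seed + 200L + s, cost = config$cost)
        })
        pn <- population_null(nulls[[layer]],
                              n_draws = config$n_population_draws,
                              seed = config$seed + 300L)
        temporal[[layer]] <- temporal_cluster_test(L$accuracy, pn,
                                                   tail = "one")
      }
      pn_diff <- population_null(nulls[["superficial"]], nulls[["deep"]],
                                 n_draws = config$n_population_draws,
                                 seed = config$seed + 301L)
      temporal[["layer_comparison"]] <- temporal_cluster_test(
        decode$layers[["superficial"]]$accuracy -
          decode$layers[["deep"]]$accuracy,
        pn_diff, tail = "two", chance = 0)
      cl_rows <- do.call(rbind, lapply(names(temporal), function(nm) {
        cl <- temporal[[nm]]$clusters
        if (is.null(cl) || !nrow(cl)) return(NULL)
        cl$analysis <- nm
        cl
      }))
      if (!is.null(cl_rows)) {
        write_results_tsv(cl_rows, file.path(config$out_dir,
                                             "temporal_clusters.tsv"))
      }
      results$temporal_clusters <- cl_rows
      results$accuracy <- lapply(decode$layers, function(L) {
        colMeans(L$accuracy)
      })
      anova_tab <- decoding_period_table(decode)
      an <- perm_rm_anova(anova_tab, n_perm = config$n_matrix_perm,
                          seed = config$seed + 400L)
      results$rm_anova <- list(F = an$F, eta_sq = an$eta_sq, p = an$p)
    })
  }

  if (config$run_crossdecoding) {
    stage("stats_matrix", {
      cross <- list()
      for (layer in names(decode$layers)) {
        mats <- decode$layers[[layer]]$matrices
        above <- matrix_cluster_test(mats, n_perm = config$n_matrix_perm,
                                     alternative = "greater",
                                     seed = config$seed + 500L)
        dyn <- dynamic_elements(mats, above, n_perm = config$n_matrix_perm,
                                seed = config$seed + 600L,
                                alpha = config$alpha)
        cross[[layer]] <- list(above = above, dynamic = dyn)
        utils::write.table(dyn$mask * 1L,
                           file.path(config$out_dir,
                                     paste0("dynamic_mask_", layer, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      results$cross_decoding <- lapply(cross, function(x) {
        list(above_chance_clusters = x$above$clusters,
             n_dynamic_elements = sum(x$dynamic$mask))
      })
    })
  }

  if (config$figures && requireNamespace("ggplot2", quietly = TRUE)) {
    stage("figures", write_figures(results, decode, config))
  }

  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s", config$mode),
    sprintf("contrast: %s", config$contrast),
    sprintf("hp_cutoff_s: %g (3rd-order Butterworth, zero-phase)",
            config$hp_cutoff_s),
    sprintf("svm cost: %g", config$cost),
    sprintf("n_trs per epoch: %d (pair-averaged to %d decoding points)",
            config$n_trs, config$n_trs - 1L),
    sprintf("subject permutations: %d", config$n_subject_perm),
    sprintf("population draws: %d", config$n_population_draws),
    sprintf("matrix sign-flip permutations: %d", config$n_matrix_perm),
    sprintf("alpha: %g; cluster-forming pointwise p < 0.05", config$alpha),
    "2-D adjacency: 4-connectivity",
    "fold k: min subtype count - 1 (>= 1)")
  writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  invisible(results)
}

# Figures mirroring the layer-timecourse and cross-decoding layouts.
write_figures <- function(results, decode, config) {
  acc <- do.call(rbind, lapply(names(decode$layers), function(layer) {
    data.frame(layer = layer, time_s = decode$timepoint_times,
               accuracy = colMeans(decode$layers[[layer]]$accuracy))
  }))
  p1 <- ggplot2::ggplot(acc, ggplot2::aes(x = time_s, y = accuracy,
                                          colour = layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "decoding accuracy")
  ggplot2::ggsave(file.path(config$out_dir, "decoding_timecourse.png"), p1,
                  width = 6, height = 4, dpi = 120)
  for (layer in names(decode$layers)) {
    m <- apply(decode$layers[[layer]]$matrices, c(2L, 3L), mean)
    df <- expand.grid(train = decode$timepoint_times,
                      test = decode$timepoint_times)
    df$accuracy <- as.vector(m)
    p2 <- ggplot2::ggplot(df, ggplot2::aes(x = test, y = train,
                                           fill = accuracy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(midpoint = 0.5) +
      ggplot2::labs(x = "test time (s)", y = "train time (s)")
    ggplot2::ggsave(file.path(config$out_dir,
                              paste0("cross_decoding_", layer, ".png")),
                    p2, width = 5, height = 4, dpi = 120)
  }
  invisible(NULL)
}
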