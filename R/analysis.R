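contrast_conditions <- function(contrast) {
  switch(contrast,
         load = c("high", "low"),
         motor = c("response", "abstain"),
         stop_ld("contrast must be 'load' or 'motor'"))
}

#' Layer-wise univariate period analysis of a cohort
#'
#' Per subject: FIR trial timecourses for the contrast's two conditions on
#' the contrast's runs, percent-signal-change scaling, layer-mean
#' timecourses, condition contrast, and period averages; then, per period, a
#' two-tailed paired t-test of the superficial versus deep effect across
#' subjects.
#'
#' @param cohort list of [simulate_subject()]-shaped datasets (fields
#'   `runs`, `events`).
#' @param contrast `"load"` (high - low) or `"motor"` (response - abstain).
#' @param periods data.frame from [analysis_periods()].
#' @param poly_order nuisance polynomial order.
#' @return list with `effects` (subject x layer x period values) and `tests`
#'   (per period: t, df, p, ci, d for superficial minus deep).
#' @export
univariate_layer_analysis <- function(cohort, contrast = "load",
                                      periods = analysis_periods(),
                                      poly_order = 5L) {
  conds <- contrast_conditions(contrast)
  run_type <- if (contrast == "load") "load" else "motor"
  effects <- do.call(rbind, lapply(seq_along(cohort), function(s) {
    subj <- cohort[[s]]
    sel <- vapply(subj$runs, function(r) r$run_type == run_type, logical(1L))
    est <- fit_fir(subj$runs[sel], subj$events[sel], conds,
                   poly_order = poly_order)
    est <- to_percent_signal_change(est)
    lmap <- layer_map_from_run(subj$runs[sel][[1L]])
    tc <- layer_timecourse(est, lmap)
    pe <- period_effects(tc, conds[1L], conds[2L], periods)
    pe$subject <- s
    pe
  }))
  tests <- do.call(rbind, lapply(unique(effects$period), function(p) {
    sup <- effects$value[effects$period == p &
                           effects$layer == "superficial"]
    dee <- effects$value[effects$period == p & effects$layer == "deep"]
    tt <- paired_ttest(sup, dee)
    data.frame(period = p, contrast = contrast, t = tt$t, df = tt$df,
               p = tt$p, ci_low = tt$ci95[1L], ci_high = tt$ci95[2L],
               d = tt$d, stringsAsFactors = FALSE)
  }))
  list(effects = effects, tests = tests)
}

#' Temporal (cross-)decoding of a cohort, per layer
#'
#' Per subject and layer: preprocess and epoch the contrast's runs, build
#' transition-balanced folds, and compute the temporal cross-decoding matrix
#' (its diagonal is the decoding timecourse).
#'
#' @param cohort list of subject datasets.
#' @param contrast `"load"` or `"motor"`.
#' @param layers depth bins to decode from.
#' @param seed integer; subject s's folds use `seed + s`.
#' @param cost,hp_cutoff_s,n_trs decoding parameters.
#' @return list with `matrices` (per layer: subjects x train x test array),
#'   `accuracy` (per layer: subjects x timepoints diagonal),
#'   `timepoint_times`, `tensors`, `folds`.
#' @export
cohort_cross_decode <- function(cohort, contrast = "load",
                                layers = c("deep", "superficial"),
                                seed = 1L, cost = 1, hp_cutoff_s = 128,
                                n_trs = 17L) {
  run_type <- if (contrast == "load") "load" else "motor"
  per_layer <- lapply(layers, function(layer) {
    per_subj <- lapply(seq_along(cohort), function(s) {
      subj <- cohort[[s]]
      sel <- vapply(subj$runs, function(r) r$run_type == run_type,
                    logical(1L))
      tensor <- prepare_decoding_tensor(subj$runs[sel], subj$events[sel],
                                        layer, hp_cutoff_s, n_trs)
      folds <- build_folds(tensor$labels, tensor$prev_labels, seed = seed + s)
      list(tensor = tensor, folds = folds,
           mat = cross_decode(tensor, folds, cost))
    })
    nt <- length(per_subj[[1L]]$mat$timepoint_times)
    mats <- array(NA_real_, dim = c(length(per_subj), nt, nt))
    acc <- matrix(NA_real_, length(per_subj), nt)
    for (s in seq_along(per_subj)) {
      mats[s, , ] <- per_subj[[s]]$mat$a
      acc[s, ] <- diag(per_subj[[s]]$mat$a)
    }
    list(matrices = mats, accuracy = acc,
         timepoint_times = per_subj[[1L]]$mat$timepoint_times,
         tensors = lapply(per_subj, `[[`, "tensor"),
         folds = lapply(per_subj, `[[`, "folds"))
  })
  names(per_layer) <- layers
  list(layers = per_layer,
       timepoint_times = per_layer[[1L]]$timepoint_times)
}

#' Average decoding accuracy over trial-period windows
#'
#' Builds the subject x period x layer table feeding the period-by-layer
#' interaction test; windows are closed intervals on the decoding timepoint
#' grid (seconds).
#'
#' @param decode result of [cohort_cross_decode()].
#' @param windows named list of `c(start, end)` windows in seconds; defaults
#'   to encoding 8-12 s, delay 14-20 s, retrieval 22-24 s (hemodynamically
#'   shifted task periods).
#' @return data.frame `subject`, `period`, `layer`, `value`.
#' @export
decoding_period_table <- function(decode,
                                  windows = list(encoding = c(8, 12),
                                                 delay = c(14, 20),
                                                 retrieval = c(22, 24))) {
  times <- decode$timepoint_times
  out <- list()
  for (layer in names(decode$layers)) {
    acc <- decode$layers[[layer]]$accuracy
    for (w in names(windows)) {
      sel <- times >= windows[[w]][1L] & times <= windows[[w]][2L]
      if (!any(sel)) stop_ld("no timepoints inside window '", w, "'")
      for (s in seq_len(nrow(acc))) {
        out[[length(out) + 1L]] <- data.frame(
          subject = s, period = w, layer = layer,
          value = mean(acc[s, sel]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
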