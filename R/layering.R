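#' Assign voxels to equidistant cortical depth bins
#'
#' Bins relative cortical depth (0 = white-matter surface, 1 = pial surface)
#' into `n_bins` equidistant bins: bin k covers `[(k-1)/n, k/n)`, with the
#' top bin closed at 1. With the default three bins, the bins are labelled
#' `deep`, `middle` and `superficial`; only `deep` and `superficial` are
#' flagged as analyzed, the middle bin acting as a buffer against partial
#' volume overlap between the two analyzed depths.
#'
#' @param depths numeric vector of depth fractions in `[0, 1]`, optionally
#'   named with voxel ids.
#' @param n_bins number of equidistant bins (>= 2).
#' @param upsample_factor anatomical upsampling factor recorded as metadata
#'   (the volumetric resampling itself happens upstream; depths are taken as
#'   given).
#' @param roi optional ROI id per voxel (recycled if length 1).
#'
#' @return A `layer_map`: data.frame with columns `voxel_id`, `depth`,
#'   `bin` (factor, deep to superficial), `analyzed` (logical), `roi`;
#'   attributes `n_bins` and `upsample_factor`.
#' @export
assign_layers <- function(depths, n_bins = 3L, upsample_factor = 5L,
                          roi = "roi1") {
  n_bins <- check_count(n_bins, "n_bins", lower = 2L)
  if (any(!is.finite(depths)) || any(depths < 0) || any(depths > 1)) {
    stop_ld("depths must be finite fractions in [0, 1]")
  }
  idx <- pmin(floor(depths * n_bins) + 1L, n_bins)  # top bin closed at 1
  if (n_bins == 3L) {
    levels <- LAYERS
    analyzed <- idx != 2L
  } else {
    levels <- paste0("bin", seq_len(n_bins))
    analyzed <- rep(TRUE, length(idx))
  }
  ids <- names(depths)
  if (is.null(ids)) ids <- sprintf("v%05d", seq_along(depths))
  map <- data.frame(
    voxel_id = ids,
    depth = as.numeric(depths),
    bin = factor(levels[idx], levels = levels),
    analyzed = analyzed,
    roi = rep_len(roi, length(depths)),
    stringsAsFactors = FALSE
  )
  attr(map, "n_bins") <- n_bins
  attr(map, "upsample_factor") <- as.integer(upsample_factor)
  class(map) <- c("layer_map", "data.frame")
  map
}

#' Layer map from a simulated run
#'
#' @param run a `voxel_timeseries` from [simulate_run()].
#' @param roi ROI id to record.
#' @return a `layer_map` for the run's voxels.
#' @export
layer_map_from_run <- function(run, roi = "roi1") {
  assign_layers(stats::setNames(run$depth, run$voxel_ids), roi = roi)
}

#' Check voxel-count comparability between analyzed layers
#'
#' Tabulates per-subject, per-ROI voxel counts per depth bin and runs a
#' two-tailed paired t-test of deep versus superficial counts across
#' subjects within each ROI, to verify that layer comparisons are not
#' confounded by unequal voxel numbers.
#'
#' @param layer_maps list of `layer_map`s, one per subject (>= 2 subjects).
#' @param rois ROIs to test; defaults to every ROI present.
#' @return list with `counts` (data.frame subject x roi x bin) and `tests`
#'   (data.frame per ROI: t, df, p, ci, Cohen's d from [paired_ttest()]).
#'   Empty bins are recorded as a warning, not an error.
#' @export
check_layer_balance <- function(layer_maps, rois = NULL) {
  if (length(layer_maps) < 2L) stop_ld("need >= 2 subjects for the paired test")
  counts <- do.call(rbind, lapply(seq_along(layer_maps), function(s) {
    m <- layer_maps[[s]]
    tab <- as.data.frame(table(roi = m$roi, bin = m$bin),
                         stringsAsFactors = FALSE)
    tab$subject <- s
    tab
  }))
  if (any(counts$Freq == 0L)) {
    warning("empty layer bin(s) in at least one subject/ROI", call. = FALSE)
  }
  if (is.null(rois)) rois <- unique(counts$roi)
  tests <- do.call(rbind, lapply(rois, function(r) {
    deep <- counts$Freq[counts$roi == r & counts$bin == "deep"]
    sup <- counts$Freq[counts$roi == r & counts$bin == "superficial"]
    tt <- paired_ttest(sup, deep)
    data.frame(roi = r, t = tt$t, df = tt$df, p = tt$p,
               ci_low = tt$ci95[1L], ci_high = tt$ci95[2L], d = tt$d,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, tests = tests)
}
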