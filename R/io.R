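# Smallest x-y grid that holds n voxels (single slice).
fixture_grid <- function(n) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  c(nx, ny, 1L)
}

#' Write a run's events as a BIDS-style TSV
#'
#' Tab-delimited, "." decimal, columns `onset`, `duration`, `trial_type`,
#' `prev_trial_type`; missing previous conditions are written as `n/a`.
#'
#' @param events an event table.
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  df <- data.frame(onset = events$onset_s, duration = events$duration_s,
                   trial_type = events$condition,
                   prev_trial_type = ifelse(is.na(events$prev_condition),
                                            "n/a", events$prev_condition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path TSV written by [write_events_tsv()] (or any events file with
#'   `onset`, `duration`, `trial_type` columns; `prev_trial_type` optional).
#' @param run run id to record.
#' @param run_type `"load"` or `"motor"`; inferred from the trial types when
#'   omitted.
#' @return an `event_table`.
#' @export
read_events_tsv <- function(path, run = 1L, run_type = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  prev <- if ("prev_trial_type" %in% names(df)) {
    ifelse(df$prev_trial_type == "n/a", NA_character_, df$prev_trial_type)
  } else {
    c(NA_character_, df$trial_type[-nrow(df)])
  }
  if (is.null(run_type)) {
    run_type <- if (any(df$trial_type %in% c("high", "low"))) "load"
    else "motor"
  }
  ev <- data.frame(onset_s = df$onset, duration_s = df$duration,
                   condition = df$trial_type, run = run, run_type = run_type,
                   trial_index = seq_len(nrow(df)), prev_condition = prev,
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write a simulated dataset to disk as NIfTI + TSV + JSON
#'
#' Writes, per run, a 4-D NIfTI with the voxels arranged on a dummy 3-D grid
#' and an events TSV; plus a 3-D integer layer-map NIfTI (1 = deep,
#' 2 = middle, 3 = superficial, 0 = unused grid cell) and a ground-truth
#' JSON with voxel ids, depths and the injected effect/noise parameters.
#'
#' @param dataset a [simulate_subject()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the list of files written.
#' @export
write_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- dataset$runs
  nv <- length(runs[[1L]]$voxel_ids)
  grid <- fixture_grid(nv)
  files <- character(0)
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    arr <- array(0, dim = c(grid, ncol(r$data)))
    flat <- matrix(arr, prod(grid), ncol(r$data))
    flat[seq_len(nv), ] <- r$data
    arr <- array(flat, dim = c(grid, ncol(r$data)))
    img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, r$tr_s))
    f_nii <- file.path(out_dir, sprintf("run-%02d_bold.nii.gz", i))
    RNifti::writeNifti(img, f_nii)
    f_ev <- file.path(out_dir, sprintf("run-%02d_events.tsv", i))
    write_events_tsv(dataset$events[[i]], f_ev)
    files <- c(files, f_nii, f_ev)
  }
  lay <- array(0L, dim = grid)
  lay[seq_len(nv)] <- match(runs[[1L]]$layer, LAYERS)
  f_lay <- file.path(out_dir, "layers.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lay, datatype = "int16"), f_lay)
  gt <- list(
    voxel_ids = runs[[1L]]$voxel_ids,
    layer = runs[[1L]]$layer,
    depth = runs[[1L]]$depth,
    tr_s = runs[[1L]]$tr_s,
    run_types = vapply(runs, `[[`, character(1L), "run_type"),
    effects = runs[[1L]]$ground_truth$effects[
      c("pattern_dynamics", "leakage_lambda", "pattern_snr")],
    amplitudes = runs[[1L]]$ground_truth$effects$amplitudes,
    noise = unclass(runs[[1L]]$ground_truth$noise),
    periods = runs[[1L]]$ground_truth$periods
  )
  f_gt <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, f_gt, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, f_lay, f_gt))
}

#' Read a dataset written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `runs` (list of `voxel_timeseries`), `events`,
#'   `layer_map_codes` (integer vector per voxel), `ground_truth`.
#' @export
read_fixture <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  lay_img <- RNifti::readNifti(file.path(dir, "layers.nii.gz"))
  codes <- as.integer(lay_img)
  used <- which(codes > 0L)
  run_files <- sort(list.files(dir, pattern = "_bold\\.nii\\.gz$",
                               full.names = TRUE))
  ev_files <- sort(list.files(dir, pattern = "_events\\.tsv$",
                              full.names = TRUE))
  events <- lapply(seq_along(ev_files), function(i) {
    read_events_tsv(ev_files[i], run = i, run_type = gt$run_types[i])
  })
  runs <- lapply(seq_along(run_files), function(i) {
    img <- RNifti::readNifti(run_files[i])
    d <- dim(img)
    flat <- matrix(img, prod(d[1:3]), d[4L])
    structure(list(data = flat[used, , drop = FALSE], tr_s = gt$tr_s,
                   run = i, run_type = gt$run_types[i],
                   voxel_ids = gt$voxel_ids,
                   layer = LAYERS[codes[used]], depth = gt$depth),
              class = "voxel_timeseries")
  })
  list(runs = runs, events = events, layer_map_codes = codes[used],
       ground_truth = gt)
}

#' Write / read a layer map as two-column TSV
#'
#' @param map a `layer_map`.
#' @param path file path.
#' @export
write_layer_map_tsv <- function(map, path) {
  utils::write.table(data.frame(voxel_id = map$voxel_id,
                                bin = as.character(map$bin)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
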