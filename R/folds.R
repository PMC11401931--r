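#' Transition-balanced cross-validation folds
#'
#' Builds folds whose training sets contain equal numbers of the four trial
#' transition subtypes (current label x previous label), cancelling
#' carry-over effects from the preceding trial. The number of folds is four
#' times the smallest subtype count; each fold trains on `k` randomly drawn
#' trials per subtype (`k` = smallest subtype count minus one, at least 1) so
#' every fold holds out at least one trial per subtype, and tests on all
#' remaining trials. Trials without a previous label (first trial of the
#' first run of a type) are never trained on but are always available for
#' testing. Fold train/test sets are disjoint and fold compositions pairwise
#' distinct.
#'
#' @param labels condition label per trial (two classes).
#' @param prev_labels previous-trial condition per trial (`NA` allowed).
#' @param seed integer seed.
#' @param k training trials per subtype; default `max(1, min subtype - 1)`.
#' @param max_tries bounded retries to realize distinct folds.
#'
#' @return `fold_set`: list with `folds` (list of `train`/`test` index
#'   vectors), `n_folds`, `subtype_counts`, `k`.
#' @export
build_folds <- function(labels, prev_labels, seed = NULL, k = NULL,
                        max_tries = 1000L) {
  labels <- as.character(labels)
  prev_labels <- as.character(prev_labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop_ld("need exactly two classes")
  trainable <- which(!is.na(prev_labels))
  subtype <- paste(labels, prev_labels, sep = "<-")
  wanted <- as.vector(outer(classes, classes,
                            function(a, b) paste(a, b, sep = "<-")))
  counts <- vapply(wanted, function(s) sum(subtype[trainable] == s),
                   integer(1L))
  if (any(counts == 0L)) {
    stop_ld("empty transition subtype(s): ",
            paste(wanted[counts == 0L], collapse = ", "))
  }
  min_count <- min(counts)
  n_folds <- 4L * min_count
  if (is.null(k)) k <- max(1L, min_count - 1L)
  if (k > min_count) stop_ld("k exceeds the smallest subtype count")
  by_subtype <- lapply(wanted, function(s) trainable[subtype[trainable] == s])
  with_local_seed(seed, {
    folds <- list()
    seen <- character(0L)
    tries <- 0L
    while (length(folds) < n_folds) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_ld("could not realize ", n_folds, " distinct folds in ",
                max_tries, " tries")
      }
      train <- sort(unlist(lapply(by_subtype, function(ix) {
        ix[sample.int(length(ix), k)]
      })))
      key <- paste(train, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      folds[[length(folds) + 1L]] <-
        list(train = train, test = setdiff(seq_along(labels), train))
    }
    structure(list(folds = folds, n_folds = n_folds,
                   subtype_counts = stats::setNames(counts, wanted), k = k),
              class = "fold_set")
  })
}
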