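#' Evaluate a trained network against ground truth
#'
#' Predicts B1+ maps for the selected subjects/orientations of a
#' normalized library and scores them against the stored ground truth
#' with the full metric panel.
#'
#' @param net A trained `ptx_network`.
#' @param dataset A normalized library.
#' @param subjects Subject ids to evaluate (default all).
#' @param orientations Orientation labels to evaluate (default all).
#' @return Long `data.frame` as in [metrics_report()], one block per
#'   subject and orientation.
#' @export
evaluate_model <- function(net, dataset, subjects = NULL,
                           orientations = NULL) {
  if (!isTRUE(dataset$normalized))
    stop("evaluate_model expects a normalized dataset")
  ids <- if (is.null(subjects)) names(dataset$subjects) else subjects
  out <- list()
  for (id in ids) {
    sub <- dataset$subjects[[id]]
    if (is.null(sub)) stop("unknown subject ", id)
    for (o in names(sub$orientations)) {
      if (!is.null(orientations) && !(o %in% orientations)) next
      ob <- sub$orientations[[o]]
      pred <- predict_b1(net, ob)
      out[[length(out) + 1L]] <-
        metrics_report(pred, ob$b1, ob$mask, subject = id, orientation = o)
    }
  }
  do.call(rbind, out)
}

#' Subject-wise k-fold cross-validation of the mapping network
#'
#' Builds subject-disjoint folds once from the seed (so the identical
#' partitioning can be reused across network variants), trains one network
#' per fold on the training subjects and scores the held-out subjects on
#' all their orientations.
#'
#' @param dataset A library (normalized on the fly if needed).
#' @param cfg A [network_config()].
#' @param tc A [train_config()] (its seed also seeds the fold split).
#' @param k Number of folds.
#' @param orientations Training-orientation restriction (e.g.
#'   `"transversal"` for an orientation-specific variant); evaluation
#'   always covers all stored orientations of the held-out subjects.
#' @param build_seed Weight-initialization seed.
#' @param verbose Progress messages.
#' @return List with `folds` (the [make_subject_folds()] split), `reports`
#'   (combined long data frame with a `fold` column) and `networks`
#'   (trained networks, one per fold).
#' @export
run_crossval <- function(dataset, cfg, tc, k = 5L, orientations = NULL,
                         build_seed = 1L, verbose = FALSE) {
  if (!isTRUE(dataset$normalized))
    dataset <- normalize_dataset(dataset)$dataset
  folds <- make_subject_folds(names(dataset$subjects), k, seed = tc$seed)
  reports <- list(); nets <- list()
  for (f in seq_along(folds)) {
    if (verbose)
      message("fold ", f, ": holding out ",
              paste(folds[[f]]$test, collapse = ", "))
    net <- if (cfg$variant == "complex") build_cx_unet(cfg, seed = build_seed)
           else build_net(cfg, seed = build_seed)
    net <- train_model(net, dataset, tc, subjects = folds[[f]]$train,
                       orientations = orientations, verbose = verbose)
    rep <- evaluate_model(net, dataset, subjects = folds[[f]]$test)
    rep$fold <- f
    reports[[f]] <- rep
    nets[[f]] <- net
  }
  list(folds = folds, reports = do.call(rbind, reports), networks = nets)
}
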