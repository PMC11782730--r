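#' Write a paired localizer/B1+ library to disk
#'
#' Serializes the library container (schema-versioned; complex arrays are
#' stored losslessly). [read_dataset()] refuses files that do not carry
#' the expected schema tag or version.
#'
#' @param dataset A library from [generate_library()] (normalized or not).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  saveRDS(dataset, path, version = 3L)
  invisible(path)
}

validate_dataset <- function(dataset) {
  if (!is.list(dataset) || !identical(dataset$schema, "ptxmap-library"))
    stop("not a ptxmap library (missing or foreign schema tag)")
  if (!identical(as.integer(dataset$version), 1L))
    stop("unsupported library schema version: ", dataset$version)
  if (!length(dataset$subjects)) stop("library contains no subjects")
  for (id in names(dataset$subjects)) {
    sub <- dataset$subjects[[id]]
    for (o in names(sub$orientations)) {
      ob <- sub$orientations[[o]]
      for (f in c("localizer", "b1", "mask", "meta"))
        if (is.null(ob[[f]]))
          stop("subject ", id, " orientation ", o, " lacks '", f, "'")
      if (!identical(dim(ob$localizer)[c(1L, 2L, 4L)], dim(ob$b1)[c(1L, 2L, 4L)]))
        stop("subject ", id, " orientation ", o,
             ": localizer and b1 grids disagree")
    }
  }
  invisible(dataset)
}

#' Read a library written by [write_dataset()]
#' @param path File path.
#' @return The validated library list.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read '", path,
                                           "' as a ptxmap library: ",
                                           conditionMessage(e), call. = FALSE))
  validate_dataset(obj)
  obj
}

#' Save a trained network checkpoint
#'
#' The checkpoint stores weights, the architecture configuration, the
#' per-subject normalization scales and the training history, enough to
#' reconstruct the network exactly with [load_checkpoint()].
#'
#' @param net A `ptx_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "ptx_network"))
  saveRDS(list(schema = "ptxmap-checkpoint", version = 1L,
               cfg = net$cfg, params = net$params, seed = net$seed,
               trained = net$trained, norm = net$norm,
               history = net$history, train_info = net$train_info),
          path, version = 3L)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path File path.
#' @return The reconstructed `ptx_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint file: ", path)
  ck <- tryCatch(readRDS(path),
                 error = function(e) stop("cannot read '", path,
                                          "' as a checkpoint: ",
                                          conditionMessage(e), call. = FALSE))
  if (!identical(ck$schema, "ptxmap-checkpoint"))
    stop("not a ptxmap checkpoint")
  if (!identical(as.integer(ck$version), 1L))
    stop("unsupported checkpoint version: ", ck$version)
  net <- structure(list(cfg = ck$cfg, plan = layer_plan(ck$cfg),
                        params = ck$params, seed = ck$seed,
                        trained = isTRUE(ck$trained), norm = ck$norm,
                        history = ck$history, train_info = ck$train_info),
                   class = "ptx_network")
  net
}

#' Read a run configuration file
#'
#' YAML configuration with blocks `simulator`, `network`, `training`,
#' `shim`, `ktpoints` and `paths`; missing entries fall back to the
#' package defaults. Every stochastic component has an explicit seed
#' (block seeds default to the top-level `seed`). The parsed list
#' round-trips losslessly through YAML and carries its own hash for
#' provenance.
#'
#' @param path YAML file path.
#' @return Nested configuration list with attribute `hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    paths = list(dataset = "library.rds", checkpoint = "model.rds",
                 metrics = "metrics.csv", out_dir = "."),
    simulator = list(n_subjects = 15L,
                     orientations = c("transversal", "sagittal", "coronal"),
                     slices_per_orientation = NULL, snr = 30,
                     nominal_fa = 8, grid = c(128L, 96L), spacing = 0.002),
    network = list(height = 128L, width = 96L, base_features = 16L,
                   dropout_rate = 0.1, variant = "complex",
                   full_split_decoder = FALSE),
    training = list(lr0 = 1e-4, lr_decay = 0.0019, epochs = 1000L,
                    lambda_l2 = 1, orientations = NULL, subjects = NULL),
    shim = list(efficiency_target = 0.6, n_starts = 8L),
    ktpoints = list(n_points = 4L, target_fa = 10, reg = 1e-2),
    crossval = list(k = 5L))
  cfg <- modifyList(defaults, if (is.null(user)) list() else user)
  for (blk in c("simulator", "training", "shim", "ktpoints", "crossval"))
    if (is.null(cfg[[blk]]$seed)) cfg[[blk]]$seed <- cfg$seed
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Serialize a kt-point pulse to JSON
#'
#' Plain-text exchange format: k-space locations (rad/m), complex RF
#' weights as real/imaginary pairs, timings and units.
#'
#' @param pulse A `kt_pulse`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pulse_json <- function(pulse, path) {
  stopifnot(inherits(pulse, "kt_pulse"))
  obj <- list(schema = "ptxmap-ktpulse", version = 1L,
              n_points = pulse$n_points,
              k_points_rad_per_m = unclass(pulse$k_points),
              rf_weights_re = Re(pulse$weights),
              rf_weights_im = Im(pulse$weights),
              subpulse_dur_s = pulse$subpulse_dur,
              blip_dur_s = pulse$blip_dur,
              target_fa_deg = pulse$target_fa,
              gamma_rad_per_s_per_T = pulse$gamma,
              b1_unit = pulse$b1_unit, reg = pulse$reg,
              predicted_cv = pulse$predicted_cv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kt-point pulse written by [write_pulse_json()]
#' @param path JSON path.
#' @return A `kt_pulse`.
#' @export
read_pulse_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ptxmap-ktpulse")) stop("not a kt-pulse file")
  structure(list(k_points = matrix(obj$k_points_rad_per_m, obj$n_points, 3L),
                 weights = matrix(complex(real = obj$rf_weights_re,
                                          imaginary = obj$rf_weights_im),
                                  obj$n_points),
                 n_points = obj$n_points, subpulse_dur = obj$subpulse_dur_s,
                 blip_dur = obj$blip_dur_s, target_fa = obj$target_fa_deg,
                 gamma = obj$gamma_rad_per_s_per_T, b1_unit = obj$b1_unit,
                 reg = obj$reg, predicted_cv = obj$predicted_cv),
            class = "kt_pulse")
}

#' Export a flip-angle map as NIfTI
#' @param fa An `fa_map` (or numeric 3D array, degrees).
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing in metres (written as mm pixdim).
#' @return `path`, invisibly.
#' @export
export_fa_nifti <- function(fa, path, spacing = 0.002) {
  arr <- if (is.list(fa)) fa$fa else fa
  img <- RNifti::asNifti(arr, pixdim = rep(spacing * 1000, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
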