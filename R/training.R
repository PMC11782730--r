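#' Training configuration
#'
#' Optimization schedule for the B1+ mapping networks: Adam with a
#' learning rate starting at `1e-4` and decaying by 0.19% per epoch
#' (`lr(e) = lr0 * (1 - lr_decay)^e`), batch size 1. The full-scale
#' schedule runs 1000 epochs; scaled-down profiles (see
#' [scaled_profile()]) use far fewer.
#'
#' @param lr0 Initial learning rate.
#' @param lr_decay Per-epoch decay fraction.
#' @param epochs Number of epochs.
#' @param batch_size Only 1 is supported (slice-wise optimization).
#' @param lambda_l2 Weight of the magnitude-L2 term in [perp_l2_loss()].
#' @param clip_norm Global gradient-norm ceiling per step (`Inf` disables
#'   clipping). Batch-size-1 steps occasionally produce outlier gradients;
#'   clipping them keeps larger learning rates stable.
#' @param seed Integer seed governing weight updates order, dropout masks
#'   and any other randomness inside [train_model()].
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, lr_decay = 0.0019, epochs = 1000L,
                         batch_size = 1L, lambda_l2 = 1, clip_norm = Inf,
                         seed = 1L) {
  if (batch_size != 1L) stop("only batch_size = 1 is supported")
  if (lr_decay < 0 || lr_decay >= 1) stop("lr_decay must be in [0, 1)")
  structure(list(lr0 = lr0, lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = 1L, lambda_l2 = lambda_l2,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#' @param tc A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return `lr0 * (1 - lr_decay)^epoch`.
#' @export
learning_rate <- function(tc, epoch) tc$lr0 * (1 - tc$lr_decay)^epoch

#' Subject-wise cross-validation folds
#'
#' Randomly partitions subjects into `k` disjoint folds; every subject is
#' held out exactly once. Deterministic for a fixed seed, so the identical
#' partitioning can be reused across network variants.
#'
#' @param subject_ids Character or integer vector of subject identifiers.
#' @param k Number of folds (e.g. 15 subjects, k = 5 -> folds of 3).
#' @param seed Integer seed.
#' @return A list of `k` folds, each `list(test = ..., train = ...)`;
#'   near-equal sizes when `length(subject_ids)` is not divisible by `k`.
#' @export
make_subject_folds <- function(subject_ids, k, seed) {
  n <- length(subject_ids)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop("k must be between 2 and the number of subjects (", n, ")")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  perm <- with_seed(seed, sample(n))
  assign_fold <- rep(seq_len(k), length.out = n)  # applied to shuffled order
  folds <- lapply(seq_len(k), function(f) {
    test <- subject_ids[perm[assign_fold == f]]
    list(test = test, train = setdiff(subject_ids, test))
  })
  structure(folds, class = "fold_split", seed = seed, k = k)
}

#' Normalize a paired localizer/B1+ library
#'
#' Training targets are normalized per subject: all complex B1+ maps are
#' divided by the 99th percentile of the in-mask channel-combined CP+
#' magnitude. Localizers are scaled by a single library-wide constant (the
#' median over subjects of the maximum combined-magnitude value): on a
#' scanner the transmit voltage and receiver gain are fixed across a
#' study, so localizer intensity carries the absolute field scale, and a
#' per-subject input normalization would erase exactly the information the
#' network needs to predict the per-subject target scale. Scales are
#' recorded so absolute maps can be recovered with [denormalize_b1()].
#'
#' @param dataset A library from [generate_library()] or [read_dataset()].
#' @return `list(dataset = normalized library, scales = data.frame)` with
#'   columns subject, b1_scale, loc_scale.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(is.list(dataset), !is.null(dataset$subjects))
  if (isTRUE(dataset$normalized)) stop("dataset is already normalized")
  ids <- names(dataset$subjects)
  scales <- data.frame(subject = ids, b1_scale = NA_real_,
                       loc_scale = NA_real_)
  for (i in seq_along(ids)) {
    sub <- dataset$subjects[[ids[i]]]
    mags <- c(); locmax <- 0
    for (ob in sub$orientations) {
      w <- cp_plus_weights(dim(ob$b1)[3L])
      for (s in seq_len(dim(ob$b1)[4L])) {
        cp <- combine_channels(ob$b1[, , , s, drop = TRUE], w)
        mags <- c(mags, Mod(cp)[ob$mask[, , s]])
      }
      locmax <- max(locmax, max(Mod(ob$localizer[, , dim(ob$localizer)[3L], ])))
    }
    if (!length(mags) || all(mags == 0) || locmax == 0)
      stop("subject ", ids[i], " has an all-zero field; cannot normalize")
    scales$b1_scale[i] <- quantile(mags, 0.99, names = FALSE)
    scales$loc_scale[i] <- locmax
  }
  # one localizer scale for the whole library (fixed "scanner gain")
  scales$loc_scale <- median(scales$loc_scale)
  for (i in seq_along(ids)) {
    sub <- dataset$subjects[[ids[i]]]
    for (o in names(sub$orientations)) {
      dataset$subjects[[ids[i]]]$orientations[[o]]$b1 <-
        sub$orientations[[o]]$b1 / scales$b1_scale[i]
      dataset$subjects[[ids[i]]]$orientations[[o]]$localizer <-
        sub$orientations[[o]]$localizer / scales$loc_scale[i]
    }
  }
  dataset$normalized <- TRUE
  dataset$norm_scales <- scales
  list(dataset = dataset, scales = scales)
}

#' Undo per-subject B1+ normalization
#' @param b1 Complex B1+ array in normalized units.
#' @param scales The scale table from [normalize_dataset()].
#' @param subject Subject id the maps belong to.
#' @return Array in the original units.
#' @export
denormalize_b1 <- function(b1, scales, subject) {
  row <- scales[scales$subject == subject, ]
  if (nrow(row) != 1L) stop("unknown subject ", subject)
  b1 * row$b1_scale
}

# gather (x, y, mask) training slices from a library
collect_slices <- function(dataset, subjects = NULL, orientations = NULL) {
  ids <- names(dataset$subjects)
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, ids)
    if (length(missing)) stop("unknown subjects: ", paste(missing, collapse = ", "))
    ids <- intersect(ids, subjects)
  }
  out <- list()
  for (id in ids) {
    for (o in names(dataset$subjects[[id]]$orientations)) {
      if (!is.null(orientations) && !(o %in% orientations)) next
      ob <- dataset$subjects[[id]]$orientations[[o]]
      for (s in seq_len(dim(ob$localizer)[4L]))
        out[[length(out) + 1L]] <- list(
          x = ob$localizer[, , , s, drop = TRUE],
          y = ob$b1[, , , s, drop = TRUE],
          mask = ob$mask[, , s], subject = id, orientation = o, slice = s)
    }
  }
  out
}

# masked mean-squared error on real channels, for the real split baseline
mse_real_loss <- function(pred, target, mask = NULL, grad = FALSE) {
  sel <- rep(as.logical(if (is.null(mask)) TRUE else mask),
             length.out = length(pred))
  if (!any(sel)) stop("mask selects no voxels")
  diff <- Re(pred) - Re(target)
  loss <- mean(diff[sel]^2)
  if (!grad) return(loss)
  g <- numeric(length(pred))
  g[sel] <- 2 * diff[sel] / sum(sel)
  gfull <- complex(real = g, imaginary = numeric(length(pred)))
  dim(gfull) <- dim(pred)
  list(loss = loss, grad = gfull)
}

adam_init <- function(net) {
  lapply(net$params, function(p) list(
    mw = complex(length(p$w)), vwr = numeric(length(p$w)),
    vwi = numeric(length(p$w)),
    mb = complex(length(p$b)), vbr = numeric(length(p$b)),
    vbi = numeric(length(p$b)),
    mm = numeric(length(p$mb)), vm = numeric(length(p$mb))))
}

# one Adam step on a complex parameter treated as independent real pairs
adam_cx <- function(p, g, m, vr, vi, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  vr <- b2 * vr + (1 - b2) * Re(g)^2
  vi <- b2 * vi + (1 - b2) * Im(g)^2
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  upd <- complex(real = Re(m) / c1 / (sqrt(vr / c2) + eps),
                 imaginary = Im(m) / c1 / (sqrt(vi / c2) + eps))
  list(p = p - lr * upd, m = m, vr = vr, vi = vi)
}

#' Train a B1+ mapping network
#'
#' Minimizes the perpendicular + L2 loss over brain-masked voxels with
#' Adam, batch size 1 (one localizer slice per step), learning rate
#' `lr0 * (1 - lr_decay)^epoch`. Slice order is reshuffled each epoch; all
#' randomness (shuffling, dropout) derives from `tc$seed`, so training is
#' bit-reproducible.
#'
#' @param net A `ptx_network` from [build_cx_unet()] or [build_real_unet()].
#' @param dataset A library, normalized via [normalize_dataset()] (an
#'   unnormalized library is normalized on the fly and the scales stored in
#'   the returned network).
#' @param tc A [train_config()].
#' @param subjects,orientations Optional restriction of the training slices
#'   (e.g. `orientations = "transversal"` for an orientation-specific
#'   model).
#' @param verbose Print one line per epoch.
#' @return The trained network; `$history` holds a data.frame with columns
#'   epoch, lr, loss (mean training loss per epoch).
#' @export
train_model <- function(net, dataset, tc = train_config(), subjects = NULL,
                        orientations = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "ptx_network"), inherits(tc, "train_config"))
  if (!isTRUE(dataset$normalized)) {
    nd <- normalize_dataset(dataset)
    dataset <- nd$dataset
  }
  net$norm <- dataset$norm_scales
  slices <- collect_slices(dataset, subjects, orientations)
  if (!length(slices)) stop("no training slices selected")
  d1 <- dim(slices[[1L]]$x)
  if (!identical(d1, c(net$cfg$height, net$cfg$width, net$cfg$in_channels)))
    stop("dataset slice shape ", paste(d1, collapse = "x"),
         " does not match network input ", net$cfg$height, "x",
         net$cfg$width, "x", net$cfg$in_channels)
  real_variant <- net$cfg$variant == "real_split"
  st <- adam_init(net)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  t_step <- 0L
  with_seed(tc$seed, {
    for (e in seq_len(tc$epochs) - 1L) {
      lr <- learning_rate(tc, e)
      ord <- sample(length(slices))
      tot <- 0
      for (i in ord) {
        sl <- slices[[i]]
        x <- sl$x; y <- sl$y
        if (real_variant) {
          x <- cx_to_real_split(x) + 0i
          y0 <- array(0, c(dim(y)[1:2], 2L * dim(y)[3L]))
          y0[, , seq_len(dim(y)[3L])] <- Re(y)
          y0[, , dim(y)[3L] + seq_len(dim(y)[3L])] <- Im(y)
          y <- y0 + 0i
        }
        cache <- new.env(parent = emptyenv())
        out <- net_forward(net, x, training = TRUE, cache = cache)
        # full-image loss: in-mask voxels carry the field information,
        # zero-target background voxels pin the prediction to zero there
        lg <- if (real_variant)
          mse_real_loss(out, y, grad = TRUE)
        else
          perp_l2_loss(out, y, lambda_l2 = tc$lambda_l2, grad = TRUE)
        tot <- tot + lg$loss
        grads <- net_backward(net, cache, lg$grad)
        if (is.finite(tc$clip_norm)) {
          gn <- sqrt(sum(vapply(names(net$params), function(nm)
            sum(Mod(grads[[nm]]$gw)^2) + sum(Mod(grads[[nm]]$gb)^2) +
              sum(grads[[nm]]$gmb^2), numeric(1))))
          if (gn > tc$clip_norm) {
            sc <- tc$clip_norm / gn
            for (nm in names(net$params)) {
              grads[[nm]]$gw <- grads[[nm]]$gw * sc
              grads[[nm]]$gb <- grads[[nm]]$gb * sc
              grads[[nm]]$gmb <- grads[[nm]]$gmb * sc
            }
          }
        }
        t_step <- t_step + 1L
        for (nm in names(net$params)) {
          p <- net$params[[nm]]; g <- grads[[nm]]; s <- st[[nm]]
          r <- .adam_step_cx(as.vector(p$w), g$gw, s$mw, s$vwr, s$vwi,
                             lr, t_step, 0.9, 0.999, 1e-8)
          w <- r$p; dim(w) <- dim(p$w)
          net$params[[nm]]$w <- w
          st[[nm]]$mw <- r$m; st[[nm]]$vwr <- r$vr; st[[nm]]$vwi <- r$vi
          r <- .adam_step_cx(p$b, g$gb, s$mb, s$vbr, s$vbi,
                             lr, t_step, 0.9, 0.999, 1e-8)
          net$params[[nm]]$b <- r$p
          st[[nm]]$mb <- r$m; st[[nm]]$vbr <- r$vr; st[[nm]]$vbi <- r$vi
          if (length(p$mb)) {
            # ModReLU biases take gradient-proportional (momentum SGD)
            # steps: Adam's normalized unit steps move b by O(lr) per
            # update regardless of its gradient, which clamps units dead
            # (|z| + b <= 0) long before the weights can adapt.
            mm <- 0.9 * s$mm + 0.1 * g$gmb
            net$params[[nm]]$mb <- p$mb - lr * mm
            st[[nm]]$mm <- mm
          }
        }
      }
      history <- rbind(history, data.frame(epoch = e, lr = lr,
                                           loss = tot / length(slices)))
      if (verbose)
        message(sprintf("epoch %4d  lr %.3e  loss %.6f", e, lr,
                        tot / length(slices)))
    }
  })
  net$trained <- TRUE
  net$history <- history
  net$train_info <- list(n_slices = length(slices), subjects = subjects,
                         orientations = orientations, tc = tc)
  net
}

#' Predict channel-wise B1+ maps from localizer slices
#'
#' Runs the trained network slice-wise (no dropout). Predictions are in
#' the same normalized units as the training targets.
#'
#' @param net A trained `ptx_network`.
#' @param loc Either a complex localizer array `(H, W, 9, S)` (or a single
#'   slice `(H, W, 9)`) or an orientation block of a library (a list with
#'   a `localizer` element), in normalized units.
#' @return Complex array `(H, W, 8, S)`; slice order preserved, and the
#'   orientation label carried over as attribute `orientation` when the
#'   input block has one.
#' @export
predict_b1 <- function(net, loc) {
  stopifnot(inherits(net, "ptx_network"))
  if (!isTRUE(net$trained))
    stop("network has not been trained; call train_model() first")
  orientation <- NULL
  if (is.list(loc) && !is.null(loc$localizer)) {
    orientation <- loc$meta$orientation
    loc <- loc$localizer
  }
  if (length(dim(loc)) == 3L) dim(loc) <- c(dim(loc), 1L)
  S <- dim(loc)[4L]
  real_variant <- net$cfg$variant == "real_split"
  n_tx <- if (real_variant) net$cfg$out_channels %/% 2L else net$cfg$out_channels
  out <- array(0i, c(dim(loc)[1L], dim(loc)[2L], n_tx, S))
  for (s in seq_len(S)) {
    x <- loc[, , , s, drop = TRUE]
    if (real_variant) x <- cx_to_real_split(x) + 0i
    y <- net_forward(net, x, training = FALSE)
    if (real_variant) y <- real_split_to_cx(Re(y))
    out[, , , s] <- y
  }
  if (!is.null(orientation)) attr(out, "orientation") <- orientation
  out
}

#' Scaled-down architecture/training profile
#'
#' Desk-scale twin of the full configuration used for tests and examples:
#' 64 x 48 grid (4 mm, same field of view), 8 base features, and a
#' compressed Adam schedule (lr 2e-3 decaying 4.5% per epoch, along-target
#' loss weight 10) — the full 1000-epoch schedule at lr 1e-4 cannot be
#' truncated to a few thousand steps, since Adam moves each weight by at
#' most about the learning rate per step. The simulator produces matching
#' libraries via `generate_library(grid = c(64, 48), spacing = 0.004)`.
#'
#' @param epochs Training epochs (default 45).
#' @param dropout_rate Dropout for the scaled profile (default 0.05).
#' @param seed Seed for both builder and trainer.
#' @return `list(cfg = network_config, tc = train_config)`.
#' @export
scaled_profile <- function(epochs = 45L, dropout_rate = 0.05, seed = 1L) {
  list(cfg = network_config(height = 64L, width = 48L, base_features = 8L,
                            dropout_rate = dropout_rate),
       tc = train_config(lr0 = 2e-3, lr_decay = 0.045, epochs = epochs,
                         lambda_l2 = 10, seed = seed))
}
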