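#' Brain/tissue mask from image magnitude
#'
#' Otsu threshold on the combined magnitude, keep the largest connected
#' component, fill holes. Deterministic. Accepts a localizer set (uses the
#' 9th combined-magnitude channel), a channel-wise B1+ set (uses the CP+
#' combined magnitude) or a plain magnitude image.
#'
#' @param x Matrix `(H, W)`, channelled array `(H, W, C[, S])`, or a
#'   library orientation block.
#' @param type Input interpretation; `"auto"` treats 9 channels as a
#'   localizer set and any other channelled complex array as B1+ maps.
#' @return Logical mask `(H, W)` or `(H, W, S)`.
#' @export
brain_mask <- function(x, type = c("auto", "localizer", "b1", "image")) {
  type <- match.arg(type)
  if (is.list(x) && !is.null(x$localizer)) { x <- x$localizer; type <- "localizer" }
  d <- dim(x)
  if (is.null(d)) stop("x must be a matrix or array")
  if (type == "auto")
    type <- if (length(d) == 2L) "image" else if (d[3L] == 9L) "localizer" else "b1"
  to_image <- function(sl) {  # (H, W, C) -> combined magnitude
    switch(type,
      image = Mod(sl),
      localizer = Mod(sl[, , dim(sl)[3L]]),
      b1 = Mod(combine_channels(sl, cp_plus_weights(dim(sl)[3L]))))
  }
  one <- function(img) {
    if (all(img == 0)) stop("all-zero image: mask would be empty")
    img <- img / max(img)
    th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    bw <- img > th
    lab <- EBImage::bwlabel(EBImage::Image(bw))
    tab <- tabulate(as.integer(lab[lab > 0]))
    keep <- EBImage::Image(lab == which.max(tab))
    mk <- EBImage::imageData(EBImage::fillHull(keep)) > 0
    matrix(as.logical(mk), nrow(mk), ncol(mk))
  }
  if (length(d) == 2L) return(one(Mod(x)))
  if (length(d) == 3L && type == "image") {
    out <- array(FALSE, d)
    for (s in seq_len(d[3L])) out[, , s] <- one(Mod(x[, , s]))
    return(out)
  }
  if (length(d) == 3L) return(one(to_image(x)))
  out <- array(FALSE, c(d[1L], d[2L], d[4L]))
  for (s in seq_len(d[4L])) out[, , s] <- one(to_image(x[, , , s, drop = TRUE]))
  out
}

# replicate a (H,W) or (H,W,S) mask over the channel axis of pred/gt
expand_mask <- function(mask, d) {
  if (is.null(mask)) return(rep(TRUE, prod(d)))
  mask <- as.logical(mask)
  dm <- dim(mask)
  if (length(d) <= 3L) return(rep(mask, length.out = prod(d)))
  # (H, W, S) mask against (H, W, C, S) data
  m <- array(rep(mask, d[3L]), c(d[1L], d[2L], if (length(dm) == 3L) dm[3L] else 1L, d[3L]))
  as.vector(aperm(m, c(1L, 2L, 4L, 3L)))
}

check_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(gt), collapse = "x"))
}

#' Mean relative magnitude error (%)
#'
#' Mean over masked voxels of `||P| - |T||` divided by the mask-mean
#' ground-truth magnitude, in percent. The mask-mean denominator keeps the
#' metric bounded near signal nulls; `per_voxel = TRUE` switches to the
#' per-voxel denominator `max(|T|, eps)`.
#'
#' @param pred,gt Complex arrays of identical shape (any of
#'   `(H, W)`, `(H, W, C)`, `(H, W, C, S)`).
#' @param mask Logical mask over the voxel grid, recycled over channels.
#' @param per_voxel Use per-voxel normalization instead.
#' @param eps Guard for the per-voxel variant.
#' @return Percent error (scalar).
#' @export
magnitude_rel_error <- function(pred, gt, mask = NULL, per_voxel = FALSE,
                                eps = 1e-8) {
  check_pair(pred, gt)
  sel <- expand_mask(mask, dim(pred))
  if (!any(sel)) stop("empty mask")
  dP <- Mod(pred)[sel]; dT <- Mod(gt)[sel]
  if (per_voxel) 100 * mean(abs(dP - dT) / pmax(dT, eps))
  else 100 * mean(abs(dP - dT)) / mean(dT)
}

#' Mean absolute phase difference (degrees)
#'
#' Circular (wrap-aware) phase error: mean over masked voxels of
#' `|angle(P * conj(T))|` in degrees, always in `[0, 180]`. Voxels with
#' zero ground-truth magnitude are excluded; their count is attached as
#' attribute `"excluded"`.
#'
#' @inheritParams magnitude_rel_error
#' @return Degrees (scalar) with attribute `excluded`.
#' @export
phase_abs_diff <- function(pred, gt, mask = NULL) {
  check_pair(pred, gt)
  sel <- expand_mask(mask, dim(pred))
  if (!any(sel)) stop("empty mask")
  P <- pred[sel]; T <- gt[sel]
  ok <- Mod(T) > 0
  val <- mean(abs(Arg(P[ok] * Conj(T[ok])))) * 180 / pi
  attr(val, "excluded") <- sum(!ok)
  val
}

#' Root-mean-squared error of B1+ maps
#'
#' `mode = "magnitude"`: RMS of `|P| - |T|`; `mode = "complex"`: RMS of
#' `|P - T|`. The complex RMSE always dominates the magnitude RMSE
#' (reverse triangle inequality).
#'
#' @inheritParams magnitude_rel_error
#' @param mode `"magnitude"` or `"complex"`.
#' @return Scalar RMSE in the units of the inputs.
#' @export
rmse_map <- function(pred, gt, mask = NULL, mode = c("magnitude", "complex")) {
  mode <- match.arg(mode)
  check_pair(pred, gt)
  sel <- expand_mask(mask, dim(pred))
  if (!any(sel)) stop("empty mask")
  if (mode == "magnitude") sqrt(mean((Mod(pred)[sel] - Mod(gt)[sel])^2))
  else sqrt(mean(Mod(pred[sel] - gt[sel])^2))
}

pad_symmetric <- function(m, p) {
  ri <- c(p:1, seq_len(nrow(m)), nrow(m):(nrow(m) - p + 1L))
  ci <- c(p:1, seq_len(ncol(m)), ncol(m):(ncol(m) - p + 1L))
  m[ri, ci]
}

# exact uniform (box) filter via integral image, symmetric boundary
box_filter <- function(m, win) {
  p <- (win - 1L) %/% 2L
  mp <- pad_symmetric(m, p)
  ii <- apply(apply(mp, 2L, cumsum), 1L, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  H <- nrow(m); W <- ncol(m)
  r1 <- seq_len(H); r2 <- r1 + win - 1L
  c1 <- seq_len(W); c2 <- c1 + win - 1L
  (ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
     ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / (win * win)
}

# uniform-window SSIM with sample-covariance normalization; the mean is
# taken over the valid region (a (win-1)/2 border is cropped)
ssim_core <- function(a, b, win = 7L, k1 = 0.01, k2 = 0.03,
                      data_range = NULL) {
  if (nrow(a) < win || ncol(a) < win)
    stop("image smaller than the SSIM window")
  if (is.null(data_range)) {
    lo <- min(a, b)
    data_range <- if (lo < 0) max(a, b) - lo else max(a, b)
    if (data_range == 0) data_range <- 1
  }
  C1 <- (k1 * data_range)^2; C2 <- (k2 * data_range)^2
  NP <- win * win; cn <- NP / (NP - 1)
  ux <- box_filter(a, win); uy <- box_filter(b, win)
  vx <- cn * (box_filter(a * a, win) - ux^2)
  vy <- cn * (box_filter(b * b, win) - uy^2)
  vxy <- cn * (box_filter(a * b, win) - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  p <- (win - 1L) %/% 2L
  mean(S[(p + 1L):(nrow(S) - p), (p + 1L):(ncol(S) - p)])
}

#' Unwrap a 2D phase map
#'
#' Deterministic scan-line (Itoh) unwrapping: the first column is
#' unwrapped top-down, then every row left-to-right anchored on the first
#' column. Exact for phase maps whose true gradients stay below pi per
#' voxel, which holds for the smooth transmit-field phases this package
#' works with.
#'
#' @param phi Matrix of wrapped phases (radians).
#' @return Matrix of unwrapped phases.
#' @export
unwrap_phase <- function(phi) {
  uv <- function(v) v - 2 * pi * c(0, cumsum(round(diff(v) / (2 * pi))))
  col1 <- uv(phi[, 1L])
  out <- t(apply(phi, 1L, uv))
  out - out[, 1L] + col1
}

#' Structural similarity of B1+ maps
#'
#' SSIM with a 7x7 uniform window and constants `k1 = 0.01, k2 = 0.03`
#' (sample-covariance normalization, border cropped to the valid region).
#' Modes: `"magnitude"` compares `|x|`; `"phase"` compares the unwrapped
#' phase maps; `"complex"` averages the SSIM of the real and of the
#' imaginary parts. The default data range is the maximum over both
#' compared images (their full range when values are negative).
#' Multi-channel / multi-slice arrays are scored per 2D plane and
#' averaged.
#'
#' @param pred,gt Arrays of identical shape (complex for the phase and
#'   complex modes).
#' @param mode `"magnitude"`, `"phase"` or `"complex"`.
#' @param win_size Odd window size (default 7).
#' @param k1,k2 SSIM stability constants.
#' @param data_range Optional fixed data range.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim_map <- function(pred, gt, mode = c("magnitude", "phase", "complex"),
                     win_size = 7L, k1 = 0.01, k2 = 0.03,
                     data_range = NULL) {
  mode <- match.arg(mode)
  check_pair(pred, gt)
  d <- dim(pred)
  if (is.null(d) || length(d) < 2L) stop("pred must be at least 2D")
  planes <- if (length(d) == 2L) 1L else prod(d[-(1:2)])
  dim(pred) <- c(d[1L], d[2L], planes); dim(gt) <- c(d[1L], d[2L], planes)
  vals <- vapply(seq_len(planes), function(i) {
    p <- pred[, , i]; g <- gt[, , i]
    switch(mode,
      magnitude = ssim_core(Mod(p), Mod(g), win_size, k1, k2, data_range),
      phase = ssim_core(unwrap_phase(Arg(p)), unwrap_phase(Arg(g)),
                        win_size, k1, k2, data_range),
      complex = (ssim_core(Re(p), Re(g), win_size, k1, k2, data_range) +
                   ssim_core(Im(p), Im(g), win_size, k1, k2, data_range)) / 2)
  }, numeric(1))
  mean(vals)
}

#' Masked voxelwise Pearson correlation
#'
#' Pearson correlation of the masked voxel vectors; in phase mode both
#' maps are unwrapped (per 2D plane) before masking to avoid wrap jumps.
#'
#' @inheritParams magnitude_rel_error
#' @param mode `"magnitude"` or `"phase"`.
#' @return Pearson rho, or `NA` with a warning for zero-variance input.
#' @export
pixelwise_correlation <- function(pred, gt, mask = NULL,
                                  mode = c("magnitude", "phase")) {
  mode <- match.arg(mode)
  check_pair(pred, gt)
  d <- dim(pred)
  tr <- function(x) {
    if (mode == "magnitude") return(Mod(x))
    planes <- if (length(d) == 2L) 1L else prod(d[-(1:2)])
    dim(x) <- c(d[1L], d[2L], planes)
    out <- array(0, dim(x))
    for (i in seq_len(planes)) out[, , i] <- unwrap_phase(Arg(x[, , i]))
    dim(out) <- d
    out
  }
  sel <- expand_mask(mask, d)
  if (sum(sel) < 3L) stop("need at least 3 masked voxels")
  a <- tr(pred)[sel]; b <- tr(gt)[sel]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance input: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Slice-wise quality report comparing predicted and reference B1+ maps
#'
#' Computes the full metric panel (relative magnitude error, circular
#' phase difference, magnitude/complex RMSE, magnitude/phase/complex SSIM,
#' magnitude/phase Pearson correlation, mask voxel count) per slice and
#' pooled over the stack, as a long data frame ready for CSV export.
#'
#' @param pred,gt Complex arrays `(H, W, C, S)` (or a single slice
#'   `(H, W, C)`).
#' @param mask Logical `(H, W, S)` brain mask.
#' @param subject,orientation Labels carried into the output.
#' @return `data.frame` with columns subject, slice, orientation, metric,
#'   mode, value; pooled rows have `slice = NA`.
#' @export
metrics_report <- function(pred, gt, mask, subject = NA_character_,
                           orientation = NA_character_) {
  check_pair(pred, gt)
  if (length(dim(pred)) == 3L) {
    dim(pred) <- c(dim(pred), 1L); dim(gt) <- dim(pred)
    dim(mask) <- c(dim(mask), 1L)
  }
  S <- dim(pred)[4L]
  rows <- list()
  add <- function(slice, metric, mode, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject, slice = slice, orientation = orientation,
      metric = metric, mode = mode, value = as.numeric(value))
  panel <- function(p, g, m, slice) {
    add(slice, "rel_error", "magnitude", magnitude_rel_error(p, g, m))
    add(slice, "phase_diff", "phase", phase_abs_diff(p, g, m))
    add(slice, "rmse", "magnitude", rmse_map(p, g, m, "magnitude"))
    add(slice, "rmse", "complex", rmse_map(p, g, m, "complex"))
    add(slice, "ssim", "magnitude", ssim_map(p, g, "magnitude"))
    add(slice, "ssim", "phase", ssim_map(p, g, "phase"))
    add(slice, "ssim", "complex", ssim_map(p, g, "complex"))
    add(slice, "pearson", "magnitude", pixelwise_correlation(p, g, m, "magnitude"))
    add(slice, "pearson", "phase", pixelwise_correlation(p, g, m, "phase"))
    add(slice, "mask_voxels", "count", sum(m))
  }
  for (s in seq_len(S))
    panel(pred[, , , s, drop = TRUE], gt[, , , s, drop = TRUE],
          mask[, , s], s)
  panel(pred, gt, mask, NA_integer_)
  do.call(rbind, rows)
}
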