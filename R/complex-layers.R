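#' Complex convolution kernel
#'
#' Bundles the learnable state of one complex convolutional layer: complex
#' weights indexed `(kh, kw, c_in, c_out)`, a complex bias per output
#' channel and the real-valued learnable ModReLU magnitude bias `b`.
#'
#' @param weights Complex array of dimension `(kh, kw, c_in, c_out)`.
#' @param bias Complex vector of length `c_out` (default zeros).
#' @param modrelu_bias Real vector of length `c_out` (default zeros; a zero
#'   bias makes ModReLU the identity on nonzero magnitudes).
#' @return An object of class `complex_kernel`.
#' @export
complex_kernel <- function(weights, bias = NULL, modrelu_bias = NULL) {
  if (!is.complex(weights)) weights <- weights + 0i
  d <- dim(weights)
  if (length(d) != 4L)
    stop("kernel weights must be a (kh, kw, c_in, c_out) array, got ",
         length(d), " dimensions")
  if (any(!is.finite(Re(weights))) || any(!is.finite(Im(weights))))
    stop("kernel weights must be finite")
  c_out <- d[4L]
  if (is.null(bias)) bias <- complex(c_out)
  if (is.null(modrelu_bias)) modrelu_bias <- numeric(c_out)
  if (length(bias) != c_out)
    stop("bias length ", length(bias), " != c_out ", c_out)
  if (length(modrelu_bias) != c_out || is.complex(modrelu_bias))
    stop("modrelu_bias must be a real vector of length c_out")
  structure(list(weights = weights, bias = as.complex(bias),
                 modrelu_bias = as.numeric(modrelu_bias)),
            class = "complex_kernel")
}

# coerce input to a (H, W, C) complex array, remembering original shape
as_cx_cube <- function(x) {
  if (!is.complex(x)) x <- x + 0i
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 1L) d <- c(d, 1L, 1L)
  if (length(d) != 3L) stop("expected a 2D or 3D array, got dim ", length(d))
  dim(x) <- d
  x
}

check_finite_cx <- function(x, what = "input") {
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop(what, " contains non-finite values")
  invisible(x)
}

#' Complex-valued 2D convolution
#'
#' "Same"-padded 2D convolution over a complex image stack using true
#' complex arithmetic: for input `x` and kernel `w`,
#' `y = conv(Re x, Re w) - conv(Im x, Im w) +
#'  i (conv(Re x, Im w) + conv(Im x, Re w))` plus a complex bias.
#'
#' @param x Complex array `(H, W, c_in)`.
#' @param k A [complex_kernel()] whose third weight dimension equals the
#'   channel count of `x`.
#' @param stride Integer stride, 1 or 2 (applied to both spatial axes).
#' @return Complex array `(H/stride, W/stride, c_out)` (same-padding
#'   arithmetic; odd sizes round up under stride 2).
#' @export
complex_conv2d <- function(x, k, stride = c(1L, 1L)) {
  stopifnot(inherits(k, "complex_kernel"))
  x <- as_cx_cube(x)
  check_finite_cx(x)
  s <- unique(as.integer(stride))
  if (length(s) != 1L || !s %in% c(1L, 2L))
    stop("stride must be (1,1) or (2,2)")
  d <- dim(k$weights)
  if (dim(x)[3L] != d[3L])
    stop("input channel count ", dim(x)[3L],
         " does not match kernel c_in ", d[3L])
  .cx_conv2d_fwd(x, as.vector(k$weights), k$bias, d[1L], d[2L], d[4L], s)
}

#' Complex-valued stride-2 transposed convolution
#'
#' Upsampling counterpart of [complex_conv2d()]: doubles both spatial
#' dimensions (stride fixed at 2, output padding 1) using the same complex
#' multiply-accumulate arithmetic applied to the transposed operator.
#'
#' @inheritParams complex_conv2d
#' @return Complex array `(2H, 2W, c_out)`.
#' @export
complex_transposed_conv2d <- function(x, k) {
  stopifnot(inherits(k, "complex_kernel"))
  x <- as_cx_cube(x)
  check_finite_cx(x)
  d <- dim(k$weights)
  if (dim(x)[3L] != d[3L])
    stop("input channel count ", dim(x)[3L],
         " does not match kernel c_in ", d[3L])
  .cx_tconv2d_fwd(x, as.vector(k$weights), k$bias, d[1L], d[2L], d[4L])
}

#' ModReLU complex activation
#'
#' Thresholds the magnitude of each complex entry while preserving its
#' phase: `ModReLU(z) = ReLU(|z| + b) exp(i angle(z))`, with `b` a real
#' learnable bias per channel. The phase of `z = 0` is undefined; the
#' output there is defined as 0 (the continuous limit).
#'
#' @param z Complex array; if `b` has length > 1 the last dimension of `z`
#'   is interpreted as the channel axis.
#' @param b Real bias, scalar or one value per channel.
#' @return Array of the same shape as `z`.
#' @export
modrelu <- function(z, b = 0) {
  d0 <- dim(z)
  if (!is.complex(z)) z <- z + 0i
  nb <- length(b)
  if (nb == 1L) {
    zz <- z; dim(zz) <- c(length(z), 1L, 1L)
    y <- .modrelu_fwd(zz, as.numeric(b))
  } else {
    nch <- if (is.null(d0)) length(z) else d0[length(d0)]
    if (nch != nb) stop("length(b) must be 1 or match the channel axis")
    zz <- z; dim(zz) <- c(length(z) / nb, 1L, nb)
    y <- .modrelu_fwd(zz, as.numeric(b))
  }
  dim(y) <- d0
  y
}

#' Complex Glorot-uniform initialization
#'
#' Draws a complex kernel whose real and imaginary parts are independent
#' uniform variates with half the Glorot variance each, so the complex
#' weight variance `E|w|^2` matches the Glorot target
#' `2 / (fan_in + fan_out)`. Deterministic for a fixed seed. Complex bias
#' and ModReLU bias are initialized to zero.
#'
#' @param shape Integer vector `(kh, kw, c_in, c_out)`.
#' @param seed Integer seed.
#' @return A [complex_kernel()].
#' @export
complex_glorot_init <- function(shape, seed) {
  shape <- as.integer(shape)
  if (length(shape) != 4L || any(shape <= 0L))
    stop("shape must be four positive integers (kh, kw, c_in, c_out)")
  fan_in <- shape[1L] * shape[2L] * shape[3L]
  fan_out <- shape[1L] * shape[2L] * shape[4L]
  # per-part uniform limit: Var(U(-a,a)) = a^2/3 = 1/(fan_in+fan_out)
  a <- sqrt(3 / (fan_in + fan_out))
  n <- prod(shape)
  w <- with_seed(seed, complex(real = runif(n, -a, a),
                               imaginary = runif(n, -a, a)))
  dim(w) <- shape
  complex_kernel(w)
}

#' Complex dropout
#'
#' A single Bernoulli mask zeroes the real and imaginary part of an entry
#' jointly; survivors are scaled by `1 / (1 - rate)` (inverted dropout).
#' Identity when `training = FALSE` or `rate = 0`.
#'
#' @param z Complex array.
#' @param rate Drop probability in `[0, 1)`.
#' @param training Logical; masking only happens during training.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (this is what the training loop does, so one training seed
#'   governs all masks).
#' @return Array of the same shape as `z`.
#' @export
complex_dropout <- function(z, rate, training = TRUE, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)")
  if (!training || rate == 0) return(z)
  draw <- function() runif(length(z)) >= rate
  keep <- if (is.null(seed)) draw() else with_seed(seed, draw())
  y <- z * (keep / (1 - rate))
  dim(y) <- dim(z)
  y
}

#' Perpendicular + L2 training loss for complex maps
#'
#' Decomposes the prediction against the target phasor. With
#' `P_perp = |Re(T) Im(P) - Im(T) Re(P)| / max(|T|, eps)` the length of the
#' component of the prediction perpendicular to the target and
#' `P_par = Re(P conj(T)) / max(|T|, eps)` its signed component along the
#' target, the loss is the mean over masked voxels of
#' `P_perp + lambda * (P_par - |T|)^2`. The perpendicular term penalizes
#' phase error symmetrically in over- and under-rotation; the quadratic
#' term penalizes the signed along-target (magnitude) error. Using the
#' signed parallel component rather than `|P|` keeps the loss
#' sign-discriminating (`P = -T` is penalized, not rewarded) and gives a
#' well-defined descent direction at `P = 0`; the loss is zero iff the
#' prediction equals the target on the mask. Voxels whose target vanishes
#' (`|T| < eps`, e.g. outside tissue in acquired maps) contribute the
#' continuous completion `lambda |P|^2`, which pins the prediction to zero
#' there.
#'
#' @param pred,target Complex arrays of identical shape.
#' @param mask Logical array broadcastable to the voxel grid (`NULL` means
#'   all voxels). For channelled stacks the mask is recycled over channels.
#' @param lambda_l2 Weight of the magnitude term (default 1).
#' @param eps Guard against division by vanishing target magnitude.
#' @param grad If `TRUE`, also return the gradient with respect to `pred`
#'   packed as `dL/dRe + i dL/dIm`.
#' @return The scalar loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
perp_l2_loss <- function(pred, target, mask = NULL, lambda_l2 = 1,
                         eps = 1e-8, grad = FALSE) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  if (is.null(mask)) {
    sel <- rep(TRUE, length(pred))
  } else {
    sel <- rep(as.logical(mask), length.out = length(pred))
  }
  if (!any(sel)) stop("mask selects no voxels")
  P <- pred[sel]; T <- target[sel]
  mT <- Mod(T)
  den <- pmax(mT, eps)
  zt <- mT < eps
  s <- Re(T) * Im(P) - Im(T) * Re(P)
  perp <- abs(s) / den
  par <- (Re(T) * Re(P) + Im(T) * Im(P)) / den
  l2 <- (par - mT)^2
  l2[zt] <- Mod(P[zt])^2
  loss <- mean(perp + lambda_l2 * l2)
  if (!grad) return(loss)
  n <- sum(sel)
  sg <- sign(s)
  gre <- -Im(T) * sg / den + 2 * lambda_l2 * (par - mT) * Re(T) / den
  gim <- Re(T) * sg / den + 2 * lambda_l2 * (par - mT) * Im(T) / den
  gre[zt] <- 2 * lambda_l2 * Re(P[zt])
  gim[zt] <- 2 * lambda_l2 * Im(P[zt])
  gfull <- complex(real = numeric(length(pred)),
                   imaginary = numeric(length(pred)))
  gfull[sel] <- complex(real = gre, imaginary = gim) / n
  dim(gfull) <- dim(pred)
  list(loss = loss, grad = gfull)
}
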