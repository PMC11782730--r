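#' Synthetic 8-element transceiver coil array
#'
#' Parametric model of a cylindrical loop array around the head: elements
#' equally spaced in azimuth on a cylinder, each producing a smooth
#' distance-falloff transmit field with an azimuthal geometric phase plus a
#' linear travelling-wave phase that mimics RF wavelength effects in tissue
#' at 7T. Small seeded per-element gain and azimuth perturbations emulate
#' inter-session variation.
#'
#' @param n_channels Number of elements (>= 2; default 8).
#' @param radius Cylinder radius in metres.
#' @param seed Integer seed for the jitter draws.
#' @param jitter If `FALSE` the array is perfectly symmetric.
#' @param loop_radius Element current-loop radius in metres; also sets the
#'   falloff length of the field magnitude.
#' @param element_length Axial extent of each element in metres; head
#'   arrays cover the head length, so fields stay strong over the whole
#'   axial field of view.
#' @param wave_number Travelling-wave phase coefficient in rad/m. The
#'   default effective wavelength of 25 cm is calibrated so that the
#'   CP+-mode coefficient of variation over the head phantoms falls in the
#'   25-29% band observed in vivo at 7T (the bare in-tissue wavelength of
#'   ~12 cm overstates interference for this simplified cylindrical
#'   geometry).
#' @return A `coil_array` object.
#' @export
make_coil_array <- function(n_channels = 8L, radius = 0.14, seed = 1L,
                            jitter = TRUE, loop_radius = 0.05,
                            element_length = 0.10,
                            wave_number = 2 * pi / 0.25) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L) stop("n_channels must be >= 2")
  if (radius <= 0 || radius > 1) stop("non-physical cylinder radius")
  az0 <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  gains <- rep(1, n_channels); daz <- numeric(n_channels)
  if (jitter) {
    r <- with_seed(seed, list(g = runif(n_channels, -0.1, 0.1),
                              a = runif(n_channels, -0.035, 0.035)))
    gains <- 1 + r$g; daz <- r$a
  }
  structure(list(n_channels = n_channels, radius = radius,
                 azimuths = az0 + daz, azimuths_nominal = az0,
                 gains = gains, loop_radius = loop_radius,
                 element_length = element_length,
                 wave_number = wave_number, seed = seed, jitter = jitter),
            class = "coil_array")
}

#' Evaluate coil fields at arbitrary 3D points
#'
#' Analytic per-channel field model. For element k at azimuth `t_k` on the
#' cylinder and a point `r` at distance `d` from the element:
#' magnitude `g_k * (a / (a + d))^2` (loop falloff with length `a`),
#' phase `t_k + kw * d` for the transmit field B1+ — the drive phase of the
#' element plus a travelling-wave term, smooth in the real and imaginary
#' parts everywhere (a physical complex field can only wind its phase
#' around nulls). Under the CP+ drive the wave terms interfere:
#' constructively at the centre (central brightening), destructively
#' off-centre, reproducing the 7T inhomogeneity pattern. The receive field
#' B1- of the transceive array is the copy of B1+ mirrored across the
#' element's own meridian plane with conjugated wave phase; by reciprocity
#' a loop receives most sensitively where it transmits most strongly, and
#' the element-distance magnitude model is symmetric under that mirror, so
#' `|B1-_k| = |B1+_k|` and the phases are wave-conjugated — the "receive
#' resembles transmit" property of a transceiver coil.
#'
#' @param coil A [make_coil_array()] object.
#' @param pts Numeric matrix `(N, 3)` of x, y, z positions in metres.
#' @param component `"transmit"` (B1+) or `"receive"` (B1-).
#' @return Complex matrix `(N, n_channels)`.
#' @export
coil_field <- function(coil, pts, component = c("transmit", "receive")) {
  component <- match.arg(component)
  pts <- as.matrix(pts)
  wsign <- if (component == "transmit") 1 else -1
  a <- coil$loop_radius
  half_len <- coil$element_length / 2
  out <- matrix(0i, nrow(pts), coil$n_channels)
  for (k in seq_len(coil$n_channels)) {
    tk <- coil$azimuths[k]
    ex <- coil$radius * cos(tk); ey <- coil$radius * sin(tk)
    # elements are axially extended (head-length loops): distance to the
    # vertical segment through the element, not to a point
    ez <- pmin(pmax(pts[, 3L], -half_len), half_len)
    d <- sqrt((pts[, 1L] - ex)^2 + (pts[, 2L] - ey)^2 + (pts[, 3L] - ez)^2)
    mag <- coil$gains[k] * (a / (a + d))^2
    ph <- tk + wsign * coil$wave_number * d
    out[, k] <- mag * exp(1i * ph)
  }
  out
}

#' Parametric head phantom
#'
#' A 3D ellipsoid "head" with seeded geometry jitter (semi-axes +/- 10%,
#' small centre offset) and a smooth nonnegative proton-density field
#' (unity plus a few random Gaussian bumps), zero outside the tissue mask.
#'
#' @param seed Integer seed; two different seeds essentially never produce
#'   identical geometry.
#' @param semi_axes Base semi-axes (x, y, z) in metres before jitter.
#' @return A `phantom_subject` object.
#' @export
make_phantom_subject <- function(seed, semi_axes = c(0.070, 0.090, 0.080)) {
  g <- with_seed(seed, {
    ax <- semi_axes * (1 + runif(3, -0.1, 0.1))
    ctr <- c(runif(2, -0.01, 0.01), runif(1, -0.005, 0.005))
    nb <- 6L
    bc <- t(replicate(nb, {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
      ctr + u * ax * 0.8
    }))
    list(ax = ax, ctr = ctr,
         bumps = list(centers = bc, widths = runif(nb, 0.02, 0.05),
                      amps = runif(nb, -0.25, 0.25)))
  })
  structure(list(semi_axes = g$ax, center = g$ctr, bumps = g$bumps,
                 seed = as.integer(seed)),
            class = "phantom_subject")
}

phantom_inside <- function(subject, pts) {
  u <- sweep(pts, 2L, subject$center)
  rowSums(sweep(u, 2L, subject$semi_axes, "/")^2) <= 1
}

phantom_pd <- function(subject, pts) {
  pd <- rep(1, nrow(pts))
  b <- subject$bumps
  for (i in seq_along(b$amps)) {
    d2 <- rowSums(sweep(pts, 2L, b$centers[i, ])^2)
    pd <- pd + b$amps[i] * exp(-d2 / (2 * b$widths[i]^2))
  }
  pd <- pmax(pd, 0.05)
  pd * phantom_inside(subject, pts)
}

orientation_axes <- function(orientation) {
  switch(orientation,
    transversal = list(row = 2L, col = 1L, normal = 3L),
    sagittal    = list(row = 3L, col = 2L, normal = 1L),
    coronal     = list(row = 3L, col = 1L, normal = 2L),
    stop("invalid orientation label '", orientation,
         "' (use transversal, sagittal or coronal)"))
}

# (H*W, 3) world positions of one slice of an oriented grid, row-major in
# the R array sense (row index fastest)
slice_points <- function(orientation, grid, spacing, position) {
  ax <- orientation_axes(orientation)
  H <- grid[1L]; W <- grid[2L]
  rc <- (seq_len(H) - (H + 1) / 2) * spacing
  cc <- (seq_len(W) - (W + 1) / 2) * spacing
  pts <- matrix(0, H * W, 3L)
  pts[, ax$row] <- rep(rc, times = W)
  pts[, ax$col] <- rep(cc, each = H)
  pts[, ax$normal] <- position
  pts
}

#' Default multi-slice positions for a phantom
#'
#' Whole-head stacks: slices span +/- 75% of the subject's semi-axis along
#' the slice normal at a fixed gap, so larger heads get more slices
#' (typically 12-18 at the default 8 mm gap).
#'
#' @param subject A [make_phantom_subject()] object.
#' @param orientation Slice orientation label.
#' @param n_slices Optional fixed slice count (overrides the gap rule).
#' @param gap Slice spacing in metres.
#' @return Numeric vector of slice positions (metres along the normal).
#' @export
slice_positions_for <- function(subject, orientation, n_slices = NULL,
                                gap = 0.008) {
  ax <- orientation_axes(orientation)
  a <- subject$semi_axes[ax$normal]
  c0 <- subject$center[ax$normal]
  if (is.null(n_slices)) n_slices <- max(4L, floor(1.5 * a / gap) + 1L)
  seq(c0 - 0.75 * a, c0 + 0.75 * a, length.out = n_slices)
}

#' Simulate ground-truth channel-wise B1+ maps
#'
#' Evaluates the analytic coil model on an oriented slice stack through
#' the phantom, producing the transmit fields (ground truth for network
#' training), the receive fields used for localizer synthesis, the tissue
#' mask and the proton density. Fully deterministic.
#'
#' @param subject A [make_phantom_subject()] phantom.
#' @param coil A [make_coil_array()] array.
#' @param orientation `"transversal"`, `"sagittal"` or `"coronal"`.
#' @param slice_positions Slice offsets along the normal (metres); default
#'   from [slice_positions_for()].
#' @param grid `(H, W)` matrix size; default 128 x 96.
#' @param spacing In-plane voxel size in metres (default 2 mm).
#' @return A `b1_sim` list: `b1plus`, `b1minus` (complex `(H, W, 8, S)`),
#'   `mask`, `pd` (`(H, W, S)`), plus grid metadata. Slices that miss the
#'   phantom entirely yield an empty stack with a warning.
#' @export
simulate_b1_fields <- function(subject, coil, orientation,
                               slice_positions = NULL, grid = c(128L, 96L),
                               spacing = 0.002) {
  if (is.null(slice_positions))
    slice_positions <- slice_positions_for(subject, orientation)
  H <- grid[1L]; W <- grid[2L]
  keep <- vapply(slice_positions, function(p) {
    any(phantom_inside(subject, slice_points(orientation, grid, spacing, p)))
  }, logical(1))
  if (!any(keep)) {
    warning("no slice intersects the phantom; returning empty stack")
    slice_positions <- numeric(0)
  } else slice_positions <- slice_positions[keep]
  S <- length(slice_positions)
  nc <- coil$n_channels
  b1p <- array(0i, c(H, W, nc, S)); b1m <- array(0i, c(H, W, nc, S))
  mask <- array(FALSE, c(H, W, S)); pd <- array(0, c(H, W, S))
  for (s in seq_len(S)) {
    pts <- slice_points(orientation, grid, spacing, slice_positions[s])
    inside <- phantom_inside(subject, pts)
    # like acquired B1+ maps, fields exist only where there is tissue
    b1p[, , , s] <- array(coil_field(coil, pts, "transmit") * inside,
                          c(H, W, nc))
    b1m[, , , s] <- array(coil_field(coil, pts, "receive") * inside,
                          c(H, W, nc))
    mask[, , s] <- matrix(inside, H, W)
    pd[, , s] <- matrix(phantom_pd(subject, pts), H, W)
  }
  structure(list(b1plus = b1p, b1minus = b1m, mask = mask, pd = pd,
                 orientation = orientation, slice_positions = slice_positions,
                 grid = as.integer(grid), spacing = spacing),
            class = "b1_sim")
}

#' Synthesize CP+-mode localizer images
#'
#' Gradient-echo-like localizer signal per receive channel j:
#' `S_j = PD * sin(FA_nom * |B1_CP+| / ref) * exp(i angle(B1_CP+)) * B1-_j`
#' plus complex Gaussian noise; the 9th channel is the root-sum-of-squares
#' magnitude of the 8 (noisy) receive channels. `ref` is the in-mask mean
#' combined transmit magnitude, so `FA_nom` is the mean achieved flip
#' angle.
#'
#' @param subject,coil The phantom and array the fields came from.
#' @param b1 A `b1_sim` stack from [simulate_b1_fields()].
#' @param mode_weights Complex transmit weights (default CP+ mode,
#'   [cp_plus_weights()]).
#' @param snr Image-domain signal-to-noise ratio: in-mask mean signal
#'   magnitude divided by the per-component noise standard deviation.
#'   `Inf` disables noise.
#' @param nominal_fa Nominal localizer flip angle in degrees.
#' @param seed Optional seed for the noise draw.
#' @return Complex localizer array `(H, W, 9, S)`.
#' @export
simulate_localizer <- function(subject, coil, b1, mode_weights = NULL,
                               snr = 30, nominal_fa = 8, seed = NULL) {
  stopifnot(inherits(b1, "b1_sim"))
  if (snr <= 0) stop("snr must be positive")
  nc <- coil$n_channels
  if (is.null(mode_weights)) mode_weights <- cp_plus_weights(nc)
  H <- dim(b1$b1plus)[1L]; W <- dim(b1$b1plus)[2L]; S <- dim(b1$b1plus)[4L]
  loc <- array(0i, c(H, W, nc + 1L, S))
  gen <- function() {
    for (s in seq_len(S)) {
      cp <- combine_channels(b1$b1plus[, , , s, drop = TRUE], mode_weights)
      msk <- b1$mask[, , s]
      ref <- mean(Mod(cp)[msk])
      fa <- nominal_fa * pi / 180 * Mod(cp) / ref
      base <- b1$pd[, , s] * sin(fa) * exp(1i * Arg(cp))
      sig <- array(0i, c(H, W, nc))
      for (j in seq_len(nc)) sig[, , j] <- base * b1$b1minus[, , j, s]
      if (is.finite(snr)) {
        sigma <- mean(Mod(sig)[rep(msk, nc)]) / snr
        n <- length(sig)
        sig <- sig + complex(real = rnorm(n, 0, sigma),
                             imaginary = rnorm(n, 0, sigma))
        dim(sig) <- c(H, W, nc)
      }
      loc[, , seq_len(nc), s] <- sig
      loc[, , nc + 1L, s] <- sqrt(apply(Mod(sig)^2, c(1, 2), sum))
    }
    loc
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a paired localizer/B1+ library
#'
#' Emulates the structure of an acquired multi-subject library: seeded
#' random head geometry per subject, whole-head multi-slice stacks in the
#' requested orientations, CP+-mode localizers with complex noise, and
#' ground-truth channel-wise B1+ maps with true tissue masks. All
#' randomness funnels through `seed`; the generating configuration is
#' stored in the output for provenance.
#'
#' @param n_subjects Number of synthetic subjects (default 15).
#' @param orientations Subset of transversal/sagittal/coronal (default
#'   all three; every subject gets every requested orientation).
#' @param slices_per_orientation Fixed slice count, or `NULL` for the
#'   head-size dependent default of [slice_positions_for()].
#' @param snr Localizer image SNR (see [simulate_localizer()]).
#' @param nominal_fa Localizer nominal flip angle (degrees).
#' @param seed Master seed.
#' @param grid,spacing Matrix size and voxel spacing; the scaled test
#'   profile uses `grid = c(64, 48), spacing = 0.004` (same field of view).
#' @param coil Optional [make_coil_array()]; by default one jittered array
#'   is drawn from `seed` and shared by all subjects (one scanner, one
#'   coil).
#' @return A library list with elements `schema`, `version`, `grid`,
#'   `seed`, `config` and `subjects[[id]]$orientations[[orientation]]`
#'   blocks holding `localizer`, `b1`, `mask` and `meta`.
#' @export
generate_library <- function(n_subjects = 15L, orientations =
                               c("transversal", "sagittal", "coronal"),
                             slices_per_orientation = NULL, snr = 30,
                             nominal_fa = 8, seed = 1L, grid = c(128L, 96L),
                             spacing = 0.002, coil = NULL) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  for (o in orientations) orientation_axes(o)  # validate labels
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                      n_subjects + 2L))
  if (is.null(coil)) coil <- make_coil_array(seed = seeds[n_subjects + 1L])
  subjects <- list()
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%02d", i)
    subject <- make_phantom_subject(seeds[i])
    blocks <- list()
    for (o in orientations) {
      pos <- slice_positions_for(subject, o, n_slices = slices_per_orientation)
      sim <- simulate_b1_fields(subject, coil, o, pos, grid = grid,
                                spacing = spacing)
      noise_seed <- (seeds[n_subjects + 2L] + 1000L * i +
                       match(o, c("transversal", "sagittal", "coronal"))) %%
        .Machine$integer.max
      locz <- simulate_localizer(subject, coil, sim, snr = snr,
                                 nominal_fa = nominal_fa, seed = noise_seed)
      blocks[[o]] <- list(
        localizer = locz, b1 = sim$b1plus, mask = sim$mask,
        meta = list(orientation = o, slice_positions = sim$slice_positions,
                    grid = as.integer(grid), spacing = spacing,
                    snr = snr, nominal_fa = nominal_fa,
                    noise_seed = noise_seed))
    }
    subjects[[id]] <- list(id = id, seed = seeds[i],
                           geometry = list(semi_axes = subject$semi_axes,
                                           center = subject$center),
                           orientations = blocks)
  }
  list(schema = "ptxmap-library", version = 1L,
       grid = list(size = as.integer(grid), spacing = spacing),
       seed = as.integer(seed),
       config = list(n_subjects = n_subjects, orientations = orientations,
                     slices_per_orientation = slices_per_orientation,
                     snr = snr, nominal_fa = nominal_fa,
                     coil = unclass(coil)),
       normalized = FALSE, subjects = subjects)
}
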