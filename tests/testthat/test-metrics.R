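test_that("brain mask recovers a bright ellipse and rejects empty images", {
  H <- 64; W <- 48
  rr <- outer((seq_len(H) - 32) / 20, rep(1, W)) ^ 2 +
    outer(rep(1, H), (seq_len(W) - 24) / 14) ^ 2
  img <- ifelse(rr <= 1, 1, 0)
  m <- brain_mask(img)
  expect_equal(m, rr <= 1)
  expect_error(brain_mask(matrix(0, 16, 16)), "all-zero")
})

test_that("brain mask on noisy phantom localizers matches the true mask", {
  ds <- study_library()
  dices <- c()
  for (id in names(ds$subjects)[1:3]) {
    ob <- ds$subjects[[id]]$orientations$transversal
    m <- brain_mask(ob)
    dices <- c(dices, 2 * sum(m & ob$mask) / (sum(m) + sum(ob$mask)))
  }
  expect_gt(min(dices), 0.98)
})

test_that("relative magnitude error has its closed forms and oracle", {
  set.seed(41)
  gt <- array(rcomplex(32 * 24 * 2), c(32, 24, 2))
  mask <- matrix(runif(32 * 24) < 0.5, 32, 24)
  expect_equal(magnitude_rel_error(gt, gt, mask), 0)
  expect_equal(magnitude_rel_error(1.1 * gt, gt, mask), 10, tolerance = 1e-9)
  # brute-force per-voxel evaluation on a random perturbation
  pred <- gt + array(rcomplex(32 * 24 * 2, sd = 0.1), dim(gt))
  sel <- rep(mask, 2)
  want <- 100 * mean(abs(Mod(pred)[sel] - Mod(gt)[sel])) / mean(Mod(gt)[sel])
  expect_equal(magnitude_rel_error(pred, gt, mask), want)
  expect_error(magnitude_rel_error(pred, gt, mask & FALSE), "empty mask")
})

test_that("phase difference is circular and in degrees", {
  gt <- array(exp(1i * 350 * pi / 180), c(4, 4))
  pred <- array(exp(1i * 10 * pi / 180), c(4, 4))
  expect_equal(as.numeric(phase_abs_diff(pred, gt)), 20, tolerance = 1e-9)
  expect_equal(as.numeric(phase_abs_diff(gt, gt)), 0)
  set.seed(8)
  z <- array(rcomplex(64), c(8, 8))
  expect_equal(as.numeric(phase_abs_diff(exp(1i * pi / 6) * z, z)), 30,
               tolerance = 1e-9)
  # zero-magnitude ground-truth voxels are excluded and counted
  z0 <- z; z0[1:3] <- 0
  expect_identical(attr(phase_abs_diff(z, z0), "excluded"), 3L)
})

test_that("RMSE modes satisfy the triangle relation", {
  set.seed(9)
  gt <- array(rcomplex(100), c(10, 10))
  expect_equal(rmse_map(gt, gt), 0)
  # single voxel T = 1, P = i
  expect_equal(rmse_map(array(1i, c(1, 1)), array(1 + 0i, c(1, 1)),
                        mode = "complex"), sqrt(2))
  expect_equal(rmse_map(array(1i, c(1, 1)), array(1 + 0i, c(1, 1)),
                        mode = "magnitude"), 0)
  for (i in 1:20) {
    pred <- gt + array(rcomplex(100, sd = 0.3), c(10, 10))
    expect_gte(rmse_map(pred, gt, mode = "complex"),
               rmse_map(pred, gt, mode = "magnitude") - 1e-12)
  }
})

test_that("SSIM is 1 on identical images and magnitude-invariant to sign", {
  set.seed(10)
  x <- array(rcomplex(64 * 48), c(64, 48))
  for (mode in c("magnitude", "phase", "complex"))
    expect_equal(ssim_map(x, x, mode), 1)
  expect_equal(ssim_map(x, -x, "magnitude"), 1)
  expect_error(ptxmap:::ssim_core(matrix(0, 3, 3), matrix(0, 3, 3)),
               "window")
})

test_that("SSIM matches the independent reference implementation", {
  # fixture pair scored once with scikit-image structural_similarity
  # (win_size = 7, uniform window, data_range = max over both images);
  # the reference value is frozen below
  set.seed(4242)
  H <- 40; W <- 32
  base <- outer(sin(seq(0, 3, length.out = H)), cos(seq(0, 2, length.out = W)))
  a <- abs(base + matrix(rnorm(H * W, 0, 0.2), H, W)) + 0.1
  b <- abs(base + matrix(rnorm(H * W, 0, 0.2), H, W)) + 0.1
  expect_equal(ptxmap:::ssim_core(a, b, 7), 0.150140484853, tolerance = 1e-6)
})

test_that("phase unwrapping restores smooth ramps", {
  ramp <- outer(seq(0, 6 * pi, length.out = 32),
                seq(0, 3 * pi, length.out = 24), "+")
  wrapped <- Arg(exp(1i * ramp))
  un <- unwrap_phase(wrapped)
  # equal up to the global 2 pi k offset of the anchor voxel
  expect_lt(max(abs((un - un[1, 1]) - (ramp - ramp[1, 1]))), 1e-9)
})

test_that("pixelwise correlation is affine-invariant and sign-aware", {
  set.seed(12)
  gt <- array(rcomplex(200), c(20, 10))
  mask <- matrix(TRUE, 20, 10)
  expect_equal(pixelwise_correlation(gt, gt, mask), 1)
  expect_equal(pixelwise_correlation(2.5 * gt + 0, gt, mask, "magnitude"), 1)
  # magnitudes flipped within their range correlate at -1
  m <- Mod(gt)
  anti <- (max(m) + min(m) - m) * exp(1i * Arg(gt))
  expect_equal(pixelwise_correlation(anti, gt, mask, "magnitude"), -1,
               tolerance = 1e-9)
  expect_warning(
    expect_true(is.na(pixelwise_correlation(gt * 0 + 1, gt, mask))),
    "zero-variance")
})

test_that("metrics are mask-restricted: padding the mask changes values", {
  ds <- study_library()
  ob <- ds$subjects$S01$orientations$transversal
  gt <- ob$b1[, , , 1]
  set.seed(13)
  pred <- gt + array(rcomplex(length(gt), sd = 0.02), dim(gt))
  m <- ob$mask[, , 1]
  grown <- m | !m  # all voxels, includes zero-field background
  expect_false(isTRUE(all.equal(magnitude_rel_error(pred, gt, m),
                                magnitude_rel_error(pred, gt, grown))))
  expect_false(isTRUE(all.equal(rmse_map(pred, gt, m),
                                rmse_map(pred, gt, grown))))
})

test_that("the slice-wise report carries the full panel in long form", {
  ds <- study_library()
  ob <- ds$subjects$S02$orientations$sagittal
  set.seed(14)
  pred <- ob$b1 + array(rcomplex(length(ob$b1), sd = 0.01), dim(ob$b1))
  rep <- metrics_report(pred, ob$b1, ob$mask, subject = "S02",
                        orientation = "sagittal")
  expect_setequal(unique(rep$metric),
                  c("rel_error", "phase_diff", "rmse", "ssim", "pearson",
                    "mask_voxels"))
  S <- dim(ob$b1)[4]
  expect_identical(sum(is.na(rep$slice)), 10L)  # pooled block
  expect_identical(nrow(rep), 10L * (S + 1L))
  ss <- rep$value[rep$metric == "ssim"]
  expect_true(all(ss >= -1 & ss <= 1))
  expect_true(all(rep$value[rep$metric == "rel_error"] >= 0))
  pd <- rep$value[rep$metric == "phase_diff"]
  expect_true(all(pd >= 0 & pd <= 180))
})
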