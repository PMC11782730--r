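test_that("channel combination implements the weighted voxelwise sum", {
  b1 <- array(0i, c(1, 1, 2))
  b1[1, 1, ] <- c(1 + 0i, 0 + 1i)
  expect_equal(combine_channels(b1, c(1, 1))[1, 1], 1 + 1i)
  expect_true(all(combine_channels(b1, c(0, 0)) == 0))
  # conjugate-phase weights align all channels: MOS = sum of magnitudes
  set.seed(20)
  v <- rcomplex(8)
  b2 <- array(v, c(1, 1, 8))
  w <- exp(-1i * Arg(v))
  expect_equal(Mod(combine_channels(b2, w)[1, 1]), sum(Mod(v)),
               tolerance = 1e-12)
  expect_error(combine_channels(b2, w[1:3]), "channel count mismatch")
  expect_equal(Mod(cp_plus_weights(8)), rep(1, 8))
})

test_that("coefficient of variation has its closed forms", {
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)  # pop sd 1, mean 2
  expect_equal(coefficient_of_variation(rep(4.2, 100)), 0)
  x <- runif(50, 1, 2)
  expect_equal(coefficient_of_variation(7 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
  expect_warning(expect_true(is.na(coefficient_of_variation(c(-1, 1)))),
                 "zero-mean")
})

test_that("a single-channel shim cannot change the CV", {
  ds <- study_library()
  ob <- ds$subjects$S01$orientations$transversal
  b1 <- ob$b1[, , 1, 1, drop = FALSE]
  dim(b1) <- c(dim(b1)[1:2], 1L)
  sh <- design_phase_shim(b1, ob$mask[, , 1], efficiency_target = 1)
  expect_equal(sh$cv, sh$cv_cp)
  expect_equal(Mod(sh$weights), 1)
})

test_that("two-channel phase shim matches a 1-degree grid search", {
  set.seed(22)
  # small masked instance with genuine interference structure
  H <- 8; W <- 8
  b1 <- array(rcomplex(H * W * 2, sd = 0.5), c(H, W, 2))
  b1[, , 1] <- b1[, , 1] + 1
  mask <- matrix(TRUE, H, W)
  Bm <- cbind(as.vector(b1[, , 1]), as.vector(b1[, , 2]))
  cv_eff <- function(phi) {
    m <- Mod(Bm %*% exp(1i * c(0, phi)))
    c(cv = sqrt(mean((m - mean(m))^2)) / mean(m),
      eff = mean(m) / mean(rowSums(Mod(Bm))))
  }
  grid <- seq(-pi, pi, by = pi / 180)
  gv <- vapply(grid, cv_eff, numeric(2))
  # a target in the middle of the achievable efficiency range
  tgt <- round(mean(range(gv["eff", ])), 2)
  sh <- design_phase_shim(b1, mask, efficiency_target = tgt, seed = 2,
                          n_starts = 12)
  expect_lte(abs(sh$efficiency - tgt), 0.01)
  # grid oracle over the method's own penalized objective
  pen <- gv["cv", ] + sh$penalty_weight * (gv["eff", ] - tgt)^2
  best_phi <- grid[which.min(pen)]
  got_phi <- Arg(sh$weights[2] / sh$weights[1])
  dphi <- abs(Arg(exp(1i * (got_phi - best_phi))))
  expect_lt(dphi, pi / 180 + 1e-9)
})

test_that("the STA forward model is linear with analytic single-pulse limits", {
  ds <- study_library()
  ob <- ds$subjects$S03$orientations$transversal
  pos <- block_positions(ob)
  pulse <- structure(list(
    k_points = matrix(0, 1, 3), weights = matrix(0.5 + 0.2i, 1, 8),
    n_points = 1L, subpulse_dur = 1e-4, blip_dur = 5e-5, target_fa = 10,
    gamma = ptxmap:::GAMMA_H, b1_unit = "uT per unit drive weight",
    reg = 0, cost = NA, predicted_cv = NA), class = "kt_pulse")
  fa <- sta_forward(pulse, ob$b1, pos)
  expect_identical(dim(fa$fa), c(64L, 48L, dim(ob$b1)[4]))
  # zero weights -> no excitation
  p0 <- pulse; p0$weights[] <- 0
  expect_true(all(sta_forward(p0, ob$b1, pos)$fa == 0))
  # doubling the weights doubles the flip angle
  p2 <- pulse; p2$weights <- 2 * pulse$weights
  expect_equal(sta_forward(p2, ob$b1, pos)$fa, 2 * fa$fa, tolerance = 1e-12)
  # uniform unit field, one channel, k = 0: FA = gamma tau |w|
  b1u <- array(0i, c(4, 4, 1, 1)); b1u[] <- 1
  posu <- matrix(0, 16, 3)
  p1 <- pulse; p1$weights <- matrix(0.3 - 0.4i, 1, 1)
  fau <- sta_forward(p1, b1u, posu)
  expect_equal(as.vector(fau$fa),
               rep(ptxmap:::GAMMA_H * 1e-4 * 1e-6 * 0.5 * 180 / pi, 16),
               tolerance = 1e-12)
})

test_that("hard-pulse Bloch simulation matches the analytic rotation", {
  # single on-resonance hard pulse over a uniform field
  b1u <- array(0i, c(2, 2, 1, 1)); b1u[] <- 1  # 1 uT per unit weight
  posu <- matrix(0, 4, 3)
  wmag <- 40  # ~61 deg with gamma tau 1e-4 s
  pulse <- structure(list(
    k_points = matrix(0, 1, 3), weights = matrix(wmag * exp(1i * 0.7), 1, 1),
    n_points = 1L, subpulse_dur = 1e-4, blip_dur = 5e-5, target_fa = 60,
    gamma = ptxmap:::GAMMA_H, b1_unit = "uT per unit drive weight",
    reg = 0, cost = NA, predicted_cv = NA), class = "kt_pulse")
  fa <- bloch_simulate_fa(pulse, b1u, posu)
  want <- ptxmap:::GAMMA_H * wmag * 1e-6 * 1e-4 * 180 / pi
  expect_equal(as.vector(fa$fa), rep(want, 4), tolerance = 1e-9)
  # zero pulse leaves the magnetization untouched
  p0 <- pulse; p0$weights[] <- 0
  expect_true(all(bloch_simulate_fa(p0, b1u, posu)$fa == 0))
})

test_that("kt-point design beats the static shim and respects regularization", {
  ds <- study_library()
  ob <- ds$subjects$S03$orientations$transversal
  pos <- block_positions(ob)
  p4 <- design_ktpoints(ob$b1, ob$mask, pos, n_points = 4, target_fa = 10,
                        greedy_iters = 8)
  p1 <- design_ktpoints(ob$b1, ob$mask, pos, n_points = 1, target_fa = 10)
  expect_identical(p4$k_points[1, ], c(0, 0, 0))  # DC point first
  fa4 <- coefficient_of_variation(sta_forward(p4, ob$b1, pos), ob$mask)
  fa1 <- coefficient_of_variation(sta_forward(p1, ob$b1, pos), ob$mask)
  expect_lt(fa4, fa1)
  # energy regularization: more Tikhonov weight, no more RF power
  pows <- vapply(c(1e-3, 1e-2, 1e-1, 1), function(r) {
    p <- design_ktpoints(ob$b1, ob$mask, pos, n_points = 2, target_fa = 10,
                         reg = r, greedy_iters = 8)
    sum(Mod(p$weights)^2)
  }, numeric(1))
  expect_true(all(diff(pows) <= 1e-9))
})

test_that("tiny kt-point instances match exhaustive candidate search", {
  set.seed(30)
  # 2 channels, 2x2 voxels, one slice
  b1 <- array(rcomplex(8, sd = 0.4), c(2, 2, 2, 1))
  b1[, , 1, ] <- b1[, , 1, , drop = FALSE] + 1
  mask <- array(TRUE, c(2, 2, 1))
  pos <- matrix(rnorm(12, 0, 0.05), 4, 3)
  got <- design_ktpoints(b1, mask, pos, n_points = 2, target_fa = 5,
                         reg = 1e-2, candidate_dk = 20, greedy_iters = 60)
  # exhaustive: k0 fixed + each of the 26 nonzero candidates, fully solved
  cands <- as.matrix(expand.grid(c(-1, 0, 1) * 20, c(-1, 0, 1) * 20,
                                 c(-1, 0, 1) * 20))
  dimnames(cands) <- NULL
  Bm <- rbind(cbind(as.vector(b1[, , 1, 1]), as.vector(b1[, , 2, 1])))
  best <- Inf
  for (ci in seq_len(nrow(cands))) {
    if (all(cands[ci, ] == 0)) next
    kset <- rbind(c(0, 0, 0), cands[ci, ])
    A <- ptxmap:::sta_matrix(Bm, pos, kset, 1e-4)
    lambda <- 1e-2 * mean(Re(diag(Conj(t(A)) %*% A)))
    w_cp <- cp_plus_weights(2)
    A1 <- ptxmap:::sta_matrix(Bm, pos, matrix(0, 1, 3), 1e-4)
    alpha <- (5 * pi / 180) / mean(Mod(A1 %*% w_cp))
    w0 <- ptxmap:::mls_solve(A1, 5 * pi / 180, alpha * w_cp, lambda,
                             iters = 60)$w
    r <- ptxmap:::mls_solve(A, 5 * pi / 180, c(w0, 0i, 0i), lambda,
                            iters = 60)
    best <- min(best, r$cost)
  }
  # the design's final solve continues from the best candidate, and each
  # variable-exchange step is monotone, so it can only be at least as good
  expect_lte(got$cost, best + 1e-9)
})

test_that("pulse JSON serialization round-trips", {
  ds <- study_library()
  ob <- ds$subjects$S03$orientations$transversal
  pos <- block_positions(ob)
  p <- design_ktpoints(ob$b1, ob$mask, pos, n_points = 2, target_fa = 10,
                       greedy_iters = 6)
  f <- tempfile(fileext = ".json")
  write_pulse_json(p, f)
  p2 <- read_pulse_json(f)
  expect_equal(p2$k_points, p$k_points)
  expect_equal(p2$weights, p$weights, tolerance = 1e-12)
  expect_equal(p2$target_fa, p$target_fa)
  fa1 <- sta_forward(p, ob$b1, pos)
  fa2 <- sta_forward(p2, ob$b1, pos)
  expect_equal(fa1$fa, fa2$fa, tolerance = 1e-9)
})
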