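test_that("default architecture honors the printed shape contract", {
  cfg <- network_config()
  expect_identical(encoder_features(cfg), c(16L, 32L, 64L, 128L))
  net <- build_cx_unet(cfg, seed = 1)
  x <- array(0i, c(128, 96, 9))
  cache <- new.env(parent = emptyenv())
  y <- ptxmap:::net_forward(net, x, cache = cache)
  expect_identical(dim(y), c(128L, 96L, 8L))
  expect_true(all(is.finite(Re(y)) & is.finite(Im(y))))
  # stride-2 cascade: 128x96 -> ... -> 8x6 at the bottleneck
  expect_identical(dim(cache$bot1$x)[1:2], c(8L, 6L))
  # encoder stage channel widths double from 16
  for (s in 1:4)
    expect_identical(dim(cache[[sprintf("enc%d_1", s)]]$z)[3],
                     encoder_features(cfg)[s])
  expect_error(network_config(height = 100), "divisible")
})

test_that("real split baseline maps 17 channels to 16 and round-trips data", {
  net <- build_real_unet(network_config(), seed = 1)
  expect_identical(net$cfg$in_channels, 17L)
  expect_identical(net$cfg$out_channels, 16L)
  expect_identical(net$cfg$variant, "real_split")
  # all weights real
  expect_true(all(vapply(net$params, function(p) all(Im(p$w) == 0),
                         logical(1))))

  set.seed(6)
  x <- array(rcomplex(8 * 8 * 9), c(8, 8, 9))
  x[, , 9] <- Mod(x[, , 9])
  split <- cx_to_real_split(x)
  expect_identical(dim(split), c(8L, 8L, 17L))
  back <- real_split_to_cx(split[, , 1:16])
  expect_equal(back, x[, , 1:8], tolerance = 1e-15)
})

test_that("whole-network backward matches finite differences", {
  set.seed(21)
  cfg <- tiny_cfg()
  net <- build_cx_unet(cfg, seed = 2)
  x <- array(rcomplex(16 * 16 * 3, sd = 0.5), c(16, 16, 3))
  target <- array(rcomplex(16 * 16 * 2, sd = 0.5), c(16, 16, 2))
  lossf <- function(net) {
    out <- ptxmap:::net_forward(net, x)
    perp_l2_loss(out, target)
  }
  cache <- new.env(parent = emptyenv())
  out <- ptxmap:::net_forward(net, x, cache = cache)
  lg <- perp_l2_loss(out, target, grad = TRUE)
  grads <- ptxmap:::net_backward(net, cache, lg$grad)
  h <- 1e-6
  for (nm in c("enc1_1", "down2", "up1", "head2_1", "bot1")) {
    for (i in sample(length(net$params[[nm]]$w), 2)) {
      for (part in c(1, 1i)) {
        np <- net; np$params[[nm]]$w[i] <- np$params[[nm]]$w[i] + part * h
        nm2 <- net; nm2$params[[nm]]$w[i] <- nm2$params[[nm]]$w[i] - part * h
        num <- (lossf(np) - lossf(nm2)) / (2 * h)
        ana <- if (part == 1) Re(grads[[nm]]$gw[i]) else Im(grads[[nm]]$gw[i])
        expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
      }
    }
    # ModReLU magnitude bias
    g <- grads[[nm]]$gmb[1]
    np <- net; np$params[[nm]]$mb[1] <- np$params[[nm]]$mb[1] + h
    nm2 <- net; nm2$params[[nm]]$mb[1] <- nm2$params[[nm]]$mb[1] - h
    num <- (lossf(np) - lossf(nm2)) / (2 * h)
    expect_lt(abs(num - g), 1e-4 * max(1, abs(num)))
  }
})

test_that("full per-channel decoder variant preserves the output contract", {
  cfg <- network_config(height = 16L, width = 16L, in_channels = 3L,
                        out_channels = 2L, n_stages = 2L, base_features = 2L,
                        convs_per_stage = 1L, head_convs = 2L,
                        dropout_rate = 0, full_split_decoder = TRUE)
  net <- build_cx_unet(cfg, seed = 3)
  expect_true(any(grepl("^tx2_up", names(net$params))))
  y <- ptxmap:::net_forward(net, array(rcomplex(16 * 16 * 3), c(16, 16, 3)))
  expect_identical(dim(y), c(16L, 16L, 2L))
})

test_that("subject folds are disjoint, exhaustive and reproducible", {
  ids <- sprintf("S%02d", 1:15)
  f1 <- make_subject_folds(ids, 5, seed = 3)
  expect_length(f1, 5)
  for (f in f1) {
    expect_length(f$test, 3)
    expect_length(intersect(f$test, f$train), 0)
    expect_setequal(c(f$test, f$train), ids)
  }
  # every subject held out exactly once
  expect_setequal(unlist(lapply(f1, `[[`, "test")), ids)
  expect_identical(f1, make_subject_folds(ids, 5, seed = 3))
  expect_false(identical(lapply(f1, `[[`, "test"),
                         lapply(make_subject_folds(ids, 5, seed = 4),
                                `[[`, "test")))
  expect_error(make_subject_folds(ids, 1, seed = 1), "k must be")
  expect_error(make_subject_folds(ids, 16, seed = 1), "k must be")
  # near-equal split when not divisible
  f2 <- make_subject_folds(ids[1:14], 5, seed = 1)
  expect_setequal(vapply(f2, function(f) length(f$test), integer(1)),
                  c(3L, 3L, 3L, 3L, 2L))
})

test_that("normalization scales to the 99th percentile and round-trips", {
  ds <- mini_library()
  nd <- normalize_dataset(ds)
  for (id in names(nd$dataset$subjects)) {
    mags <- c()
    for (ob in nd$dataset$subjects[[id]]$orientations)
      for (s in seq_len(dim(ob$b1)[4])) {
        cp <- combine_channels(ob$b1[, , , s], cp_plus_weights(8))
        mags <- c(mags, Mod(cp)[ob$mask[, , s]])
      }
    expect_equal(quantile(mags, 0.99, names = FALSE), 1, tolerance = 1e-10)
  }
  # denormalization restores the originals
  id <- names(ds$subjects)[1]
  back <- denormalize_b1(nd$dataset$subjects[[id]]$orientations[[1]]$b1,
                         nd$scales, id)
  expect_equal(back, ds$subjects[[id]]$orientations[[1]]$b1,
               tolerance = 1e-6)
  # a globally rescaled subject normalizes to identical data
  ds2 <- ds
  for (o in names(ds2$subjects[[id]]$orientations)) {
    ds2$subjects[[id]]$orientations[[o]]$b1 <-
      ds2$subjects[[id]]$orientations[[o]]$b1 * 3.7
    ds2$subjects[[id]]$orientations[[o]]$localizer <-
      ds2$subjects[[id]]$orientations[[o]]$localizer * 2.1
  }
  nd2 <- normalize_dataset(ds2)
  expect_equal(nd2$dataset$subjects[[id]]$orientations[[1]]$b1,
               nd$dataset$subjects[[id]]$orientations[[1]]$b1,
               tolerance = 1e-10)
  expect_error(normalize_dataset(nd$dataset), "already normalized")
})

test_that("the Adam schedule follows the stated exponential decay", {
  tc <- train_config()
  expect_equal(learning_rate(tc, 0), 1e-4)
  e <- c(1, 10, 100, 999)
  expect_equal(learning_rate(tc, e), 1e-4 * (1 - 0.0019)^e)
  lr <- learning_rate(tc, 0:999)
  expect_true(all(diff(lr) < 0))
  expect_error(train_config(batch_size = 2), "batch_size")
})

test_that("training reduces the loss and is bit-reproducible", {
  ds <- mini_library()
  cfg <- network_config(height = 32L, width = 32L, base_features = 4L,
                        dropout_rate = 0.05)
  tc <- train_config(epochs = 5L, seed = 9)
  net1 <- train_model(build_cx_unet(cfg, seed = 4), ds, tc)
  expect_lt(tail(net1$history$loss, 1), net1$history$loss[1])
  net2 <- train_model(build_cx_unet(cfg, seed = 4), ds, tc)
  expect_identical(net1$history, net2$history)
  expect_identical(net1$params, net2$params)

  # prediction contract: N slices in -> N slice-sets out, finite, labelled
  nd <- normalize_dataset(ds)$dataset
  ob <- nd$subjects$S01$orientations$sagittal
  pred <- predict_b1(net1, ob)
  expect_identical(dim(pred), c(32L, 32L, 8L, dim(ob$localizer)[4]))
  expect_true(all(is.finite(Re(pred))))
  expect_identical(attr(pred, "orientation"), "sagittal")
  expect_error(predict_b1(build_cx_unet(cfg), ob), "train")
})
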