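# Shared fixtures. Heavy objects (the synthetic library and the trained
# networks used by the end-to-end checks) are built once per test run and
# memoised in this environment.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

rcomplex <- function(n, sd = 1) {
  complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd))
}

# brute-force same-padding complex convolution (independent oracle)
brute_conv2d <- function(x, w, b, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  Ho <- (H + 2 * ph - kh) %/% stride + 1
  Wo <- (W + 2 * pw - kw) %/% stride + 1
  y <- array(0i, c(Ho, Wo, Co))
  for (co in 1:Co) for (oi in 1:Ho) for (oj in 1:Wo) {
    acc <- b[co]
    for (ci in 1:Ci) for (dh in 1:kh) for (dw in 1:kw) {
      i <- stride * (oi - 1) + dh - ph; j <- stride * (oj - 1) + dw - pw
      if (i >= 1 && i <= H && j >= 1 && j <= W)
        acc <- acc + x[i, j, ci] * w[dh, dw, ci, co]
    }
    y[oi, oj, co] <- acc
  }
  y
}

# tiny architecture for gradient checks: 16x16, 2 stages
tiny_cfg <- function() {
  network_config(height = 16L, width = 16L, in_channels = 3L,
                 out_channels = 2L, n_stages = 2L, base_features = 2L,
                 convs_per_stage = 1L, head_convs = 2L, dropout_rate = 0,
                 precision = "double")
}

# small 3-subject library for fast I/O and training-contract tests
mini_library <- function() {
  memo("mini_library", function()
    generate_library(n_subjects = 2, slices_per_orientation = 2, seed = 5,
                     grid = c(32L, 32L), spacing = 0.008))
}

# The scaled-down study conditions: 15 synthetic subjects, three
# orientations, 64x48 grid (4 mm, same field of view as the full 2 mm
# 128x96 profile), 3 slices per orientation, localizer SNR 30.
study_library <- function() {
  memo("study_library", function() {
    ds <- generate_library(n_subjects = 15, slices_per_orientation = 3,
                           seed = 11, grid = c(64L, 48L), spacing = 0.004)
    normalize_dataset(ds)$dataset
  })
}

study_folds <- function() {
  make_subject_folds(names(study_library()$subjects), 5, seed = 11)
}

# Network trained on all orientations of the 12 training subjects of
# fold 1 (the parameter-recovery and pulse-design checks share it).
trained_all <- function() {
  memo("trained_all", function() {
    nd <- study_library()
    cfg <- network_config(height = 64L, width = 48L, base_features = 8L,
                          dropout_rate = 0.05)
    net <- build_cx_unet(cfg, seed = 1)
    train_model(net, nd,
                train_config(lr0 = 2e-3, lr_decay = 0.045, epochs = 45L,
                             lambda_l2 = 10, seed = 1),
                subjects = study_folds()[[1]]$train)
  })
}

# Network trained on transversal slices only (orientation-transfer check).
trained_tra <- function() {
  memo("trained_tra", function() {
    nd <- study_library()
    cfg <- network_config(height = 64L, width = 48L, base_features = 8L,
                          dropout_rate = 0.05)
    net <- build_cx_unet(cfg, seed = 1)
    train_model(net, nd,
                train_config(lr0 = 2e-3, lr_decay = 0.045, epochs = 30L,
                             lambda_l2 = 10, seed = 1),
                subjects = study_folds()[[1]]$train,
                orientations = "transversal")
  })
}

heldout_metric <- function(net, orientations = NULL, metric = "ssim") {
  nd <- study_library()
  vals <- c()
  for (id in study_folds()[[1]]$test) {
    for (o in names(nd$subjects[[id]]$orientations)) {
      if (!is.null(orientations) && !(o %in% orientations)) next
      ob <- nd$subjects[[id]]$orientations[[o]]
      pred <- predict_b1(net, ob)
      vals <- c(vals, switch(metric,
        ssim = ssim_map(pred, ob$b1, "complex"),
        rel_error = magnitude_rel_error(pred, ob$b1, ob$mask)))
    }
  }
  mean(vals)
}
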