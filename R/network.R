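#' Network architecture configuration
#'
#' Describes the complex encoder-decoder used for localizer-to-B1+ mapping.
#' The default is the full-scale architecture: 128 x 96 input with 9
#' channels (8 complex receive channels + root-sum-of-squares magnitude),
#' 8 complex output channels (one per transmit channel), four
#' encoder/decoder stages whose feature maps double per stage starting at
#' 16, two 3x3 stride-1 convolutions per stage, stride-2 (up-)convolutions
#' for resampling, U-Net skip connections by channel concatenation, dropout
#' at stage ends, and per-transmit-channel head pipelines of four
#' convolutions with decreasing feature maps (16, 8, 4, 1).
#'
#' @param height,width Spatial input size; both must be divisible by
#'   `2^n_stages` so the bottleneck size is exact (128 x 96 -> 8 x 6).
#' @param in_channels,out_channels Channel counts (9 -> 8 for the complex
#'   variant; 17 -> 16 for the real split baseline).
#' @param n_stages Number of encoder (and decoder) stages.
#' @param base_features Feature maps in the first stage; doubled per stage.
#' @param convs_per_stage Stride-1 convolutions per stage.
#' @param head_convs Convolutions per transmit-channel head.
#' @param dropout_rate Dropout probability at stage ends (the source
#'   architecture uses dropout but does not print the rate; 0.1 default).
#' @param precision `"single"` (default) or `"double"`: floating-point
#'   precision of the convolution arithmetic. Single precision roughly
#'   doubles training throughput on one core; gradient-verification work
#'   uses double.
#' @param input_gain Fixed scalar applied to the input before the first
#'   convolution. Normalized localizers have in-mask RMS around 0.2; the
#'   default gain of 5 brings first-layer activations to unit scale, which
#'   keeps the learnable ModReLU magnitude biases (steps of order the
#'   learning rate) from clamping units dead early in training.
#' @param variant `"complex"` (complex weights + ModReLU) or `"real_split"`
#'   (real weights + ReLU on real/imaginary-split channels).
#' @param full_split_decoder If `TRUE`, the whole decoder (not only the
#'   head) is duplicated per transmit channel.
#' @return A `network_config` list.
#' @export
network_config <- function(height = 128L, width = 96L, in_channels = 9L,
                           out_channels = 8L, n_stages = 4L,
                           base_features = 16L, convs_per_stage = 2L,
                           head_convs = 4L, dropout_rate = 0.1,
                           input_gain = 5,
                           precision = c("single", "double"),
                           variant = c("complex", "real_split"),
                           full_split_decoder = FALSE) {
  variant <- match.arg(variant)
  precision <- match.arg(precision)
  cfg <- list(height = as.integer(height), width = as.integer(width),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              n_stages = as.integer(n_stages),
              base_features = as.integer(base_features),
              convs_per_stage = as.integer(convs_per_stage),
              head_convs = as.integer(head_convs),
              dropout_rate = dropout_rate, input_gain = input_gain,
              precision = precision, variant = variant,
              full_split_decoder = isTRUE(full_split_decoder))
  if (cfg$height %% 2^cfg$n_stages != 0L || cfg$width %% 2^cfg$n_stages != 0L)
    stop("height and width must be divisible by 2^n_stages (",
         2^cfg$n_stages, "); got ", cfg$height, " x ", cfg$width)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  class(cfg) <- "network_config"
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: %dx%dx%d -> %dx%dx%d, %s variant\n",
              x$height, x$width, x$in_channels, x$height, x$width,
              x$out_channels, x$variant))
  cat(sprintf("  stages: %d, features %s, bottleneck %dx%d\n", x$n_stages,
              paste(encoder_features(x), collapse = "/"),
              x$height %/% 2^x$n_stages, x$width %/% 2^x$n_stages))
  invisible(x)
}

#' Encoder feature-map progression of a configuration
#' @param cfg A [network_config()].
#' @return Integer vector, `base_features * 2^(stage - 1)` per stage.
#' @export
encoder_features <- function(cfg)
  as.integer(cfg$base_features * 2^(0:(cfg$n_stages - 1L)))

head_features <- function(cfg) {
  f <- pmax(1L, cfg$base_features %/% 2L^(0:(cfg$head_convs - 2L)))
  c(f, 1L)
}

# Flat ordered table of learnable layers: name, type (conv/tconv), cin,
# cout, stride, activation. The forward/backward walkers consume it only
# for parameter shapes; the topology itself is coded explicitly.
layer_plan <- function(cfg) {
  act_main <- if (cfg$variant == "complex") "modrelu" else "relu"
  feats <- encoder_features(cfg)
  S <- cfg$n_stages
  plan <- list()
  add <- function(name, type, cin, cout, stride = 1L, act = act_main)
    plan[[name]] <<- list(name = name, type = type, cin = cin, cout = cout,
                          stride = stride, act = act)
  cin <- cfg$in_channels
  for (s in seq_len(S)) {
    for (j in seq_len(cfg$convs_per_stage)) {
      add(sprintf("enc%d_%d", s, j), "conv", cin, feats[s]); cin <- feats[s]
    }
    nxt <- if (s < S) feats[s + 1L] else feats[S]
    add(sprintf("down%d", s), "conv", cin, nxt, stride = 2L); cin <- nxt
  }
  for (j in seq_len(cfg$convs_per_stage)) {
    add(sprintf("bot%d", j), "conv", cin, feats[S]); cin <- feats[S]
  }
  dec_prefixes <- if (cfg$full_split_decoder)
    sprintf("tx%d_", seq_len(cfg$out_channels)) else ""
  for (pre in dec_prefixes) {
    dcin <- feats[S]
    for (s in rev(seq_len(S))) {
      add(paste0(pre, sprintf("up%d", s)), "tconv", dcin, feats[s])
      dcin <- 2L * feats[s]  # concat with encoder skip
      for (j in seq_len(cfg$convs_per_stage)) {
        add(paste0(pre, sprintf("dec%d_%d", s, j)), "conv", dcin, feats[s])
        dcin <- feats[s]
      }
    }
  }
  hf <- head_features(cfg)
  for (t in seq_len(cfg$out_channels)) {
    hcin <- feats[1L]
    for (j in seq_len(cfg$head_convs)) {
      act <- if (j == cfg$head_convs) "none" else act_main
      add(sprintf("head%d_%d", t, j), "conv", hcin, hf[j], act = act)
      hcin <- hf[j]
    }
  }
  plan
}

glorot_draw <- function(shape, real_only = FALSE) {
  fan_in <- shape[1L] * shape[2L] * shape[3L]
  fan_out <- shape[1L] * shape[2L] * shape[4L]
  n <- prod(shape)
  if (real_only) {
    a <- sqrt(6 / (fan_in + fan_out))  # full Glorot variance in Re
    w <- complex(real = runif(n, -a, a), imaginary = numeric(n))
  } else {
    a <- sqrt(3 / (fan_in + fan_out))
    w <- complex(real = runif(n, -a, a), imaginary = runif(n, -a, a))
  }
  dim(w) <- shape
  w
}

#' Build the complex-valued B1+ mapping network
#'
#' Instantiates the encoder-decoder of [network_config()] with complex
#' Glorot-uniform weights, zero complex biases and zero ModReLU biases
#' (magnitude-identity at initialization). Deterministic for a fixed seed.
#'
#' @param cfg A [network_config()] with `variant = "complex"`.
#' @param seed Integer seed for weight initialization.
#' @return A `ptx_network` object (untrained).
#' @export
build_cx_unet <- function(cfg = network_config(), seed = 1L) {
  if (cfg$variant != "complex") stop("cfg$variant must be 'complex'")
  build_net(cfg, seed)
}

#' Build the real-valued split-channel baseline network
#'
#' Same topology with real arithmetic and ReLU activations. Complex data
#' enters as separated real and imaginary channels: 8 real + 8 imaginary
#' localizer channels + 1 magnitude = 17 input channels, and 16 output
#' channels holding real/imaginary pairs of the 8 transmit maps. See
#' [cx_to_real_split()] / [real_split_to_cx()] for the lossless channel
#' conversion.
#'
#' @param cfg Optional base [network_config()]; its spatial size and stage
#'   layout are kept, channels are overridden to 17 -> 16.
#' @param seed Integer seed.
#' @param feature_multiplier Scales `base_features` to realize baselines of
#'   different parameter counts.
#' @return A `ptx_network` object.
#' @export
build_real_unet <- function(cfg = network_config(), seed = 1L,
                            feature_multiplier = 1) {
  n_tx <- cfg$out_channels
  cfg <- network_config(
    height = cfg$height, width = cfg$width,
    in_channels = 2L * (cfg$in_channels - 1L) + 1L,
    out_channels = 2L * n_tx, n_stages = cfg$n_stages,
    base_features = as.integer(round(cfg$base_features * feature_multiplier)),
    convs_per_stage = cfg$convs_per_stage, head_convs = cfg$head_convs,
    dropout_rate = cfg$dropout_rate, input_gain = cfg$input_gain,
    precision = cfg$precision, variant = "real_split",
    full_split_decoder = cfg$full_split_decoder)
  build_net(cfg, seed)
}

build_net <- function(cfg, seed) {
  plan <- layer_plan(cfg)
  real_only <- cfg$variant == "real_split"
  params <- with_seed(seed, lapply(plan, function(ly) {
    kh <- 3L
    list(w = glorot_draw(c(kh, kh, ly$cin, ly$cout), real_only),
         b = complex(ly$cout), mb = numeric(ly$cout))
  }))
  structure(list(cfg = cfg, plan = plan, params = params, seed = seed,
                 trained = FALSE, norm = NULL, history = NULL),
            class = "ptx_network")
}

#' @export
print.ptx_network <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    2 * length(p$w) + 2 * length(p$b) + length(p$mb), numeric(1)))
  cat(sprintf("ptx_network (%s): %d layers, %s real parameters, %s\n",
              x$cfg$variant, length(x$plan), format(np, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1L], da[2L], da[3L] + db[3L]))
}

layer_fwd <- function(ly, p, x, cache = NULL, f32 = FALSE) {
  d <- dim(p$w)
  z <- if (ly$type == "conv") {
    if (f32) .cx_conv2d_fwd_f32(x, as.vector(p$w), p$b, d[1L], d[2L],
                                d[4L], ly$stride)
    else .cx_conv2d_fwd(x, as.vector(p$w), p$b, d[1L], d[2L], d[4L],
                        ly$stride)
  } else {
    if (f32) .cx_tconv2d_fwd_f32(x, as.vector(p$w), p$b, d[1L], d[2L],
                                 d[4L])
    else .cx_tconv2d_fwd(x, as.vector(p$w), p$b, d[1L], d[2L], d[4L])
  }
  a <- switch(ly$act,
    modrelu = .modrelu_fwd(z, p$mb),
    relu = {
      y <- complex(real = pmax(Re(z), 0), imaginary = numeric(length(z)))
      dim(y) <- dim(z); y
    },
    none = z)
  if (!is.null(cache)) cache[[ly$name]] <- list(x = x, z = z)
  a
}

layer_bwd <- function(ly, p, ca, ga, grads, f32 = FALSE) {
  d <- dim(p$w)
  gz <- switch(ly$act,
    modrelu = {
      r <- .modrelu_bwd(ca$z, p$mb, ga)
      grads[[ly$name]]$gmb <- grads[[ly$name]]$gmb + r$gb
      r$gz
    },
    relu = {
      y <- complex(real = Re(ga) * (Re(ca$z) > 0),
                   imaginary = numeric(length(ga)))
      dim(y) <- dim(ga); y
    },
    none = ga)
  r <- if (ly$type == "conv") {
    if (f32) .cx_conv2d_bwd_f32(ca$x, as.vector(p$w), gz, d[1L], d[2L],
                                ly$stride)
    else .cx_conv2d_bwd(ca$x, as.vector(p$w), gz, d[1L], d[2L], ly$stride)
  } else {
    if (f32) .cx_tconv2d_bwd_f32(ca$x, as.vector(p$w), gz, d[1L], d[2L])
    else .cx_tconv2d_bwd(ca$x, as.vector(p$w), gz, d[1L], d[2L])
  }
  grads[[ly$name]]$gw <- grads[[ly$name]]$gw + r$gw
  grads[[ly$name]]$gb <- grads[[ly$name]]$gb + r$gb
  grads$.gx <- r$gx
  grads
}

apply_dropout_fwd <- function(x, rate, training, cache, name) {
  if (!training || rate == 0) return(x)
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  cache[[name]] <- list(mask = keep)
  y <- x * keep
  dim(y) <- dim(x)
  y
}

# Forward pass. `training` enables dropout (draws from the current RNG
# stream); `cache` (an environment) is filled when gradients are needed.
net_forward <- function(net, x, training = FALSE, cache = NULL) {
  cfg <- net$cfg; plan <- net$plan; par <- net$params
  f32 <- identical(cfg$precision, "single")
  S <- cfg$n_stages
  x <- as_cx_cube(x)
  if (!identical(dim(x), c(cfg$height, cfg$width, cfg$in_channels)))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match configured ", cfg$height, "x", cfg$width, "x",
         cfg$in_channels)
  gain <- if (is.null(cfg$input_gain)) 1 else cfg$input_gain
  a <- x * gain
  dim(a) <- dim(x)
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    for (j in seq_len(cfg$convs_per_stage)) {
      nm <- sprintf("enc%d_%d", s, j)
      a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
    }
    a <- apply_dropout_fwd(a, cfg$dropout_rate, training, cache,
                           sprintf("dropenc%d", s))
    skips[[s]] <- a
    nm <- sprintf("down%d", s)
    a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
  }
  for (j in seq_len(cfg$convs_per_stage)) {
    nm <- sprintf("bot%d", j)
    a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
  }
  a <- apply_dropout_fwd(a, cfg$dropout_rate, training, cache, "dropbot")
  bott <- a
  decode <- function(pre, a) {
    for (s in rev(seq_len(S))) {
      nm <- paste0(pre, sprintf("up%d", s))
      a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
      a <- concat_ch(a, skips[[s]])
      for (j in seq_len(cfg$convs_per_stage)) {
        nm <- paste0(pre, sprintf("dec%d_%d", s, j))
        a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
      }
      a <- apply_dropout_fwd(a, cfg$dropout_rate, training, cache,
                             paste0(pre, sprintf("dropdec%d", s)))
    }
    a
  }
  run_head <- function(t, a) {
    for (j in seq_len(cfg$head_convs)) {
      nm <- sprintf("head%d_%d", t, j)
      a <- layer_fwd(plan[[nm]], par[[nm]], a, cache, f32)
    }
    a
  }
  out <- array(0i, c(cfg$height, cfg$width, cfg$out_channels))
  if (cfg$full_split_decoder) {
    for (t in seq_len(cfg$out_channels))
      out[, , t] <- run_head(t, decode(sprintf("tx%d_", t), bott))
  } else {
    trunk <- decode("", bott)
    if (!is.null(cache)) cache$.trunk_dim <- dim(trunk)
    for (t in seq_len(cfg$out_channels)) out[, , t] <- run_head(t, trunk)
  }
  if (!is.null(cache)) {
    cache$.skip_dims <- lapply(skips, dim)
    cache$.bott_dim <- dim(bott)
  }
  out
}

zero_grads <- function(net) {
  g <- lapply(net$params, function(p)
    list(gw = complex(length(p$w)), gb = complex(length(p$b)),
         gmb = numeric(length(p$mb))))
  g$.gx <- NULL
  g
}

# Backward pass through the cached forward. `gout` is the loss gradient at
# the network output, packed dL/dRe + i dL/dIm. Returns the grads list.
net_backward <- function(net, cache, gout, grads = NULL) {
  cfg <- net$cfg; plan <- net$plan; par <- net$params
  f32 <- identical(cfg$precision, "single")
  S <- cfg$n_stages
  if (is.null(grads)) grads <- zero_grads(net)
  drop_bwd <- function(g, name) {
    ca <- cache[[name]]
    if (is.null(ca)) return(g)
    y <- g * ca$mask; dim(y) <- dim(g); y
  }
  head_bwd <- function(t, g) {
    for (j in rev(seq_len(cfg$head_convs))) {
      nm <- sprintf("head%d_%d", t, j)
      grads <<- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], g, grads, f32)
      g <- grads$.gx
    }
    g
  }
  gskips <- vector("list", S)
  decode_bwd <- function(pre, g) {
    for (s in seq_len(S)) {
      g <- drop_bwd(g, paste0(pre, sprintf("dropdec%d", s)))
      for (j in rev(seq_len(cfg$convs_per_stage))) {
        nm <- paste0(pre, sprintf("dec%d_%d", s, j))
        grads <<- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], g, grads, f32)
        g <- grads$.gx
      }
      nc <- cache$.skip_dims[[s]][3L]
      gcat <- g
      gup <- gcat[, , seq_len(dim(gcat)[3L] - nc), drop = FALSE]
      gsk <- gcat[, , dim(gcat)[3L] - nc + seq_len(nc), drop = FALSE]
      gskips[[s]] <<- if (is.null(gskips[[s]])) gsk else gskips[[s]] + gsk
      nm <- paste0(pre, sprintf("up%d", s))
      grads <<- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], gup, grads, f32)
      g <- grads$.gx
    }
    g
  }
  gb <- NULL
  if (cfg$full_split_decoder) {
    for (t in seq_len(cfg$out_channels)) {
      g <- head_bwd(t, gout[, , t, drop = FALSE])
      gt <- decode_bwd(sprintf("tx%d_", t), g)
      gb <- if (is.null(gb)) gt else gb + gt
    }
  } else {
    gtr <- NULL
    for (t in seq_len(cfg$out_channels)) {
      g <- head_bwd(t, gout[, , t, drop = FALSE])
      gtr <- if (is.null(gtr)) g else gtr + g
    }
    dim(gtr) <- cache$.trunk_dim
    gb <- decode_bwd("", gtr)
  }
  dim(gb) <- cache$.bott_dim
  g <- drop_bwd(gb, "dropbot")
  for (j in rev(seq_len(cfg$convs_per_stage))) {
    nm <- sprintf("bot%d", j)
    grads <- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], g, grads, f32)
    g <- grads$.gx
  }
  for (s in rev(seq_len(S))) {
    nm <- sprintf("down%d", s)
    grads <- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], g, grads, f32)
    g <- grads$.gx
    g <- g + gskips[[s]]
    g <- drop_bwd(g, sprintf("dropenc%d", s))
    for (j in rev(seq_len(cfg$convs_per_stage))) {
      nm <- sprintf("enc%d_%d", s, j)
      grads <- layer_bwd(plan[[nm]], par[[nm]], cache[[nm]], g, grads, f32)
      g <- grads$.gx
    }
  }
  grads$.gx <- g
  grads
}

#' Split a complex multi-channel image into real channels
#'
#' Converts the 9-channel complex localizer input into the 17-channel real
#' representation of the real-valued baseline (8 real parts, 8 imaginary
#' parts, 1 magnitude), and analogously for any `(H, W, C)` complex array
#' whose last channel is a real magnitude image.
#'
#' @param x Complex array `(H, W, C)`; the last channel is passed through
#'   as-is (it is the real combined-magnitude image).
#' @return Real-valued array `(H, W, 2 * (C - 1) + 1)`.
#' @seealso [real_split_to_cx()] for the inverse of the paired part.
#' @export
cx_to_real_split <- function(x) {
  x <- as_cx_cube(x)
  C <- dim(x)[3L]
  out <- array(0, c(dim(x)[1L], dim(x)[2L], 2L * (C - 1L) + 1L))
  out[, , seq_len(C - 1L)] <- Re(x[, , seq_len(C - 1L)])
  out[, , (C - 1L) + seq_len(C - 1L)] <- Im(x[, , seq_len(C - 1L)])
  out[, , 2L * (C - 1L) + 1L] <- Re(x[, , C])
  out
}

#' Recombine split real/imaginary channels into complex maps
#'
#' @param y Real array `(H, W, 2 * n)` holding `n` real parts followed by
#'   `n` imaginary parts.
#' @return Complex array `(H, W, n)`.
#' @export
real_split_to_cx <- function(y) {
  n <- dim(y)[3L] %/% 2L
  z <- complex(real = as.vector(y[, , seq_len(n)]),
               imaginary = as.vector(y[, , n + seq_len(n)]))
  dim(z) <- c(dim(y)[1L], dim(y)[2L], n)
  z
}
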