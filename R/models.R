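#' Describe a generator architecture
#'
#' Builds a validated descriptor for one of the four generator families:
#' `"unet"` (stride-2 encoder/decoder with skip connections), `"resnet6"` /
#' `"resnet9"` (encode - 6 or 9 residual blocks - decode) and `"resunet"`
#' (the U-net with `n_res_blocks` residual blocks inserted at every
#' resolution level).
#'
#' @param family One of `"unet"`, `"resnet6"`, `"resnet9"`, `"resunet"`.
#' @param in_channels Conditioning channels: 3 for the multi-channel landmark
#'   encoding, 1 for the fused or vessel-only baselines.
#' @param out_channels Output image channels (3 for RGB fundus images).
#' @param base_width Feature channels at the first level; widths double per
#'   level, capped at `8 * base_width`.
#' @param depth Down/up-sampling levels.  Defaults to `log2(size) - 1` for the
#'   U-net families when built (bottleneck at 2x2) and 2 for the ResNets;
#'   leave `NULL` to accept the default at build time.
#' @param n_res_blocks Residual blocks per resolution level (`resunet` only),
#'   one of 1, 2, 3.
#' @param norm Use batch normalization (within-sample statistics).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(family = c("unet", "resnet6", "resnet9", "resunet"),
                           in_channels = 3L, out_channels = 3L,
                           base_width = 32L, depth = NULL,
                           n_res_blocks = 1L, norm = TRUE) {
  family <- match.arg(family)
  if (!in_channels %in% c(1L, 3L))
    stop("in_channels must be 1 or 3", call. = FALSE)
  if (base_width < 1L) stop("base_width must be positive", call. = FALSE)
  if (family == "resunet" && !n_res_blocks %in% 1:3)
    stop("n_res_blocks must be 1, 2 or 3 for resunet", call. = FALSE)
  structure(list(family = family, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 depth = if (!is.null(depth)) as.integer(depth),
                 n_res_blocks = as.integer(n_res_blocks), norm = norm),
            class = "generator_spec")
}

#' Describe the patch discriminator
#'
#' A fully convolutional stack of stride-2 conv / batch-norm / leaky-ReLU
#' layers ending in a sigmoid, emitting a spatial map of patch-level
#' real/fake likelihoods in (0, 1).
#'
#' @param in_channels Total input channels: conditioning channels plus the 3
#'   channels of the candidate image.
#' @param n_layers Number of stride-2 convolution layers.
#' @param base_width Feature channels after the first convolution; widths
#'   double per layer, capped at `8 * base_width`.
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(in_channels = 6L, n_layers = 4L,
                               base_width = 64L) {
  if (n_layers < 1L) stop("n_layers must be positive", call. = FALSE)
  if (base_width < 1L) stop("base_width must be positive", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 n_layers = as.integer(n_layers),
                 base_width = as.integer(base_width)),
            class = "discriminator_spec")
}

unet_depth_for <- function(size) max(1L, as.integer(log2(size)) - 1L)

gen_depth <- function(spec, size) {
  if (!is.null(spec$depth)) return(spec$depth)
  if (spec$family %in% c("resnet6", "resnet9")) 2L else unet_depth_for(size)
}

check_divisible <- function(size, depth, what = "input") {
  if (size %% (2^depth) != 0)
    stop(sprintf(
      "%s size %d is not divisible by 2^%d; pick a size that is a multiple of %d",
      what, size, depth, 2^depth), call. = FALSE)
}

# Recursive U-net skip block.  Each level halves then restores resolution;
# a non-outermost level returns concat(input, upsampled-output) so the level
# above sees both the skip and the decoded features.  `n_res` residual blocks
# are inserted after the down-convolution and (non-outermost) up-convolution,
# which is how the residual U-net family augments the plain U-net.
unet_level <- function(in_ch, inner_ch, sub, up_out, outermost, n_res, init) {
  e <- new_block("unet_level")
  down <- list(layer_conv(in_ch, inner_ch, 4L, 2L, 1L, init = init))
  if (!outermost) down <- c(down, list(layer_norm(inner_ch, init = init)))
  down <- c(down, list(layer_lrelu(0.2)))
  if (n_res > 0)
    down <- c(down, lapply(seq_len(n_res),
                           function(i) residual_block(inner_ch, init)))
  down <- seq_block(down)

  up_in <- if (is.null(sub)) inner_ch else 2L * inner_ch
  up <- list(layer_upsample2(),
             layer_conv(up_in, up_out, 3L, 1L, 1L, init = init))
  if (!outermost) {
    up <- c(up, list(layer_norm(up_out, init = init), layer_relu()))
    if (n_res > 0)
      up <- c(up, lapply(seq_len(n_res),
                         function(i) residual_block(up_out, init)))
  }
  up <- seq_block(up)

  e$children <- c(list(down), if (!is.null(sub)) list(sub), list(up))
  e$forward <- function(x, training = TRUE) {
    d <- down$forward(x, training)
    s <- if (is.null(sub)) d else sub$forward(d, training)
    u <- up$forward(s, training)
    if (outermost) u else concat_channels(x, u)
  }
  e$backward <- function(dy) {
    if (outermost) {
      du <- dy
      dx_skip <- 0
    } else {
      dy <- as_hwc(dy)
      dx_skip <- dy[, , seq_len(in_ch), drop = FALSE]
      du <- dy[, , (in_ch + 1L):dim(dy)[3], drop = FALSE]
    }
    ds <- up$backward(du)
    dd <- if (is.null(sub)) ds else sub$backward(ds)
    dx <- down$backward(dd)
    dx + dx_skip
  }
  e
}

build_unet <- function(spec, size, n_res, init) {
  depth <- gen_depth(spec, size)
  check_divisible(size, depth)
  widths <- pmin(spec$base_width * 2^(seq_len(depth) - 1L), 8L * spec$base_width)
  block <- NULL
  for (lev in seq(depth, 1L)) {
    outermost <- lev == 1L
    in_ch <- if (outermost) spec$in_channels else widths[lev - 1L]
    up_out <- if (outermost) spec$out_channels else widths[lev - 1L]
    block <- unet_level(in_ch, widths[lev], block, up_out, outermost,
                        n_res, init)
  }
  seq_block(block, layer_tanh())
}

build_resnet <- function(spec, n_blocks, init) {
  w <- spec$base_width
  layers <- list(
    layer_conv(spec$in_channels, w, 7L, 1L, 3L, init = init),
    layer_norm(w, init = init), layer_relu(),
    layer_conv(w, 2L * w, 4L, 2L, 1L, init = init),
    layer_norm(2L * w, init = init), layer_relu(),
    layer_conv(2L * w, 4L * w, 4L, 2L, 1L, init = init),
    layer_norm(4L * w, init = init), layer_relu()
  )
  layers <- c(layers, lapply(seq_len(n_blocks),
                             function(i) residual_block(4L * w, init)))
  layers <- c(layers, list(
    layer_upsample2(), layer_conv(4L * w, 2L * w, 3L, 1L, 1L, init = init),
    layer_norm(2L * w, init = init), layer_relu(),
    layer_upsample2(), layer_conv(2L * w, w, 3L, 1L, 1L, init = init),
    layer_norm(w, init = init), layer_relu(),
    layer_conv(w, spec$out_channels, 7L, 1L, 3L, init = init),
    layer_tanh()
  ))
  seq_block(layers)
}

#' Build a generator network
#'
#' Materializes the architecture described by a [generator_spec()] into a
#' network whose `$forward()` maps a conditioning image (`H x W x in_channels`,
#' model-scale values in \[-1, 1\]) to an RGB image of identical spatial size
#' with values in \[-1, 1\] (tanh output).
#'
#' @param spec A [generator_spec()].
#' @param size Input image side length in pixels; must be divisible by
#'   `2^depth` for the architecture's depth.
#' @param init `"gaussian"` (zero-mean, sd 0.02) or `"zeros"`.  Weight draws
#'   use the current R random-number state.
#' @return A network block; apply with `model$forward(x, training)`.
#' @export
build_generator <- function(spec, size = 256L, init = c("gaussian", "zeros")) {
  stopifnot(inherits(spec, "generator_spec"))
  init <- match.arg(init)
  model <- switch(spec$family,
    unet = build_unet(spec, size, 0L, init),
    resunet = build_unet(spec, size, spec$n_res_blocks, init),
    resnet6 = { check_divisible(size, 2L); build_resnet(spec, 6L, init) },
    resnet9 = { check_divisible(size, 2L); build_resnet(spec, 9L, init) })
  model$spec <- spec
  model$size <- as.integer(size)
  model
}

#' Build the patch discriminator
#'
#' The discriminator consumes the channel-concatenation of the conditioning
#' input and a candidate image and emits a spatial probability map, every
#' value strictly inside (0, 1).
#'
#' @param spec A [discriminator_spec()].
#' @param init `"gaussian"` or `"zeros"`; at all-zero parameters the output
#'   map is uniformly 0.5.
#' @return A network block; apply with `model$forward(concat, training)` or
#'   [discriminate()].
#' @export
build_discriminator <- function(spec, init = c("gaussian", "zeros")) {
  stopifnot(inherits(spec, "discriminator_spec"))
  init <- match.arg(init)
  bw <- spec$base_width
  widths <- pmin(bw * 2^(seq_len(spec$n_layers) - 1L), 8L * bw)
  layers <- list(layer_conv(spec$in_channels, widths[1L], 4L, 2L, 1L,
                            init = init),
                 layer_lrelu(0.2))
  if (spec$n_layers > 1L)
    for (i in 2:spec$n_layers)
      layers <- c(layers, list(
        layer_conv(widths[i - 1L], widths[i], 4L, 2L, 1L, init = init),
        layer_norm(widths[i], init = init),
        layer_lrelu(0.2)))
  layers <- c(layers, list(layer_conv(widths[spec$n_layers], 1L, 3L, 1L, 1L,
                                      init = init),
                           layer_sigmoid()))
  model <- seq_block(layers)
  model$spec <- spec
  model
}

#' Apply a discriminator to a (conditioning, image) pair
#'
#' @param model A network from [build_discriminator()].
#' @param conditioning Conditioning image array (`H x W x C`).
#' @param image Candidate RGB image array (`H x W x 3`), model scale.
#' @param training Use within-sample normalization statistics (`TRUE`) or the
#'   accumulated running statistics (`FALSE`).
#' @return Patch probability map (`h x w x 1`), values in (0, 1).
#' @export
discriminate <- function(model, conditioning, image, training = FALSE) {
  x <- concat_channels(conditioning, image)
  if (dim(x)[3] != model$spec$in_channels)
    stop(sprintf("discriminator expects %d channels (conditioning + image), got %d",
                 model$spec$in_channels, dim(x)[3]), call. = FALSE)
  model$forward(x, training)
}

#' Residual block forward rule
#'
#' Computes the defining identity-shortcut mapping of a residual unit,
#' `x_out = x + F(x)`, for an arbitrary residual function `F`.
#'
#' @param x Input feature map (any numeric array).
#' @param f Residual function; `f(x)` must return an array of the same shape.
#' @return `x + f(x)`, elementwise.
#' @export
residual_block_forward <- function(x, f) {
  fx <- f(x)
  if (!identical(dim(fx), dim(x)) || length(fx) != length(x))
    stop("residual branch output shape must match its input", call. = FALSE)
  x + fx
}
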