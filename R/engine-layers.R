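#' @useDynLib mcmlfundus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-hand network engine.
#
# Feature maps are numeric arrays with dim = c(H, W, C).  Every layer or
# composite block is an environment exposing:
#   $forward(x, training)  -- pushes whatever it needs onto an internal cache
#                             stack and returns the output map
#   $backward(dy)          -- pops the cache (LIFO), accumulates parameter
#                             gradients, returns the input gradient
#   $par / $grad           -- named lists of parameter / gradient arrays
#                             (NULL for parameter-free layers)
#   $children              -- nested blocks, for recursive parameter walks
#
# The LIFO cache stack is what lets one set of weights be run forward several
# times before the matching backwards (needed for cycle-consistent training,
# where each generator is traversed twice per update).
# ---------------------------------------------------------------------------

new_block <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$cache <- list()
  e$par <- NULL
  e$grad <- NULL
  e$children <- NULL
  e$frozen <- FALSE
  class(e) <- c(paste0("mcml_", type), "mcml_block")
  e
}

cache_push <- function(e, v) e$cache[[length(e$cache) + 1L]] <- v
cache_pop <- function(e) {
  n <- length(e$cache)
  if (n == 0L) stop("backward called without a matching forward", call. = FALSE)
  v <- e$cache[[n]]
  e$cache[[n]] <- NULL
  v
}

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# -- convolution ------------------------------------------------------------

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                       init = c("gaussian", "zeros"), init_sd = 0.02) {
  init <- match.arg(init)
  e <- new_block("conv")
  w <- if (init == "gaussian") stats::rnorm(k * k * in_ch * out_ch, 0, init_sd)
       else numeric(k * k * in_ch * out_ch)
  e$par <- list(W = array(w, dim = c(k, k, in_ch * out_ch)),
                b = numeric(out_ch))
  e$grad <- list(W = array(0, dim = c(k, k, in_ch * out_ch)),
                 b = numeric(out_ch))
  e$meta <- list(in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = as.integer(stride), pad = as.integer(pad))
  e$forward <- function(x, training = TRUE) {
    x <- as_hwc(x)
    if (dim(x)[3] != e$meta$in_ch)
      stop(sprintf("conv expects %d input channels, got %d",
                   e$meta$in_ch, dim(x)[3]), call. = FALSE)
    cache_push(e, x)
    .conv2d_fw(x, e$par$W, e$par$b, e$meta$k, e$meta$out_ch,
               e$meta$stride, e$meta$pad)
  }
  e$backward <- function(dy) {
    x <- cache_pop(e)
    r <- .conv2d_bw(x, e$par$W, as_hwc(dy), e$meta$k, e$meta$stride, e$meta$pad)
    e$grad$W <- e$grad$W + r$dw
    e$grad$b <- e$grad$b + r$db
    r$dx
  }
  e
}

# -- normalization ----------------------------------------------------------

# Batch normalization operating on the within-sample spatial statistics
# (instance-style; exact for the batch-size-1 recipe used throughout).
# Running means/variances accumulate during training and are used verbatim
# in inference mode, so synthesis is deterministic.
layer_norm <- function(ch, eps = 1e-5, momentum = 0.1,
                       init = c("gaussian", "zeros")) {
  init <- match.arg(init)
  e <- new_block("norm")
  e$par <- list(gamma = if (init == "zeros") numeric(ch) else rep(1, ch),
                beta = numeric(ch))
  e$grad <- list(gamma = numeric(ch), beta = numeric(ch))
  e$buffers <- list(mean = numeric(ch), var = rep(1, ch))
  e$meta <- list(ch = ch, eps = eps, momentum = momentum)
  e$forward <- function(x, training = TRUE) {
    x <- as_hwc(x)
    d <- dim(x)
    n <- d[1] * d[2]
    xm <- x; dim(xm) <- c(n, d[3])
    if (training) {
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      v[v < 0] <- 0
      e$buffers$mean <- (1 - e$meta$momentum) * e$buffers$mean + e$meta$momentum * mu
      e$buffers$var <- (1 - e$meta$momentum) * e$buffers$var + e$meta$momentum * v
    } else {
      mu <- e$buffers$mean
      v <- e$buffers$var
    }
    istd <- 1 / sqrt(v + e$meta$eps)
    xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
    ym <- sweep(sweep(xhat, 2, e$par$gamma, "*"), 2, e$par$beta, "+")
    cache_push(e, list(xhat = xhat, istd = istd, d = d, training = training))
    dim(ym) <- d
    ym
  }
  e$backward <- function(dy) {
    cc <- cache_pop(e)
    d <- cc$d
    n <- d[1] * d[2]
    dym <- as_hwc(dy); dim(dym) <- c(n, d[3])
    e$grad$gamma <- e$grad$gamma + colSums(dym * cc$xhat)
    e$grad$beta <- e$grad$beta + colSums(dym)
    dxhat <- sweep(dym, 2, e$par$gamma, "*")
    if (cc$training) {
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * cc$xhat)
      dxm <- sweep(sweep(dxhat, 2, s1, "-") - sweep(cc$xhat, 2, s2, "*"),
                   2, cc$istd, "*")
    } else {
      dxm <- sweep(dxhat, 2, cc$istd, "*")
    }
    dim(dxm) <- d
    dxm
  }
  e
}

# -- activations ------------------------------------------------------------

layer_relu <- function() {
  e <- new_block("relu")
  e$forward <- function(x, training = TRUE) {
    y <- pmax(x, 0); cache_push(e, x > 0); y
  }
  e$backward <- function(dy) dy * cache_pop(e)
  e
}

layer_lrelu <- function(alpha = 0.2) {
  e <- new_block("lrelu")
  e$forward <- function(x, training = TRUE) {
    pos <- x > 0
    cache_push(e, pos)
    ifelse_arr(pos, x, alpha * x)
  }
  e$backward <- function(dy) {
    pos <- cache_pop(e)
    ifelse_arr(pos, dy, alpha * dy)
  }
  e
}

ifelse_arr <- function(mask, a, b) {
  out <- b
  out[mask] <- a[mask]
  out
}

layer_tanh <- function() {
  e <- new_block("tanh")
  e$forward <- function(x, training = TRUE) {
    y <- tanh(x); cache_push(e, y); y
  }
  e$backward <- function(dy) {
    y <- cache_pop(e)
    dy * (1 - y^2)
  }
  e
}

# Sigmoid clamped away from {0,1} so downstream log-losses stay finite;
# the clamp width is far below any tested tolerance.
layer_sigmoid <- function(clamp_eps = 1e-6) {
  e <- new_block("sigmoid")
  e$forward <- function(x, training = TRUE) {
    p <- 1 / (1 + exp(-x))
    p <- pmin(pmax(p, clamp_eps), 1 - clamp_eps)
    cache_push(e, p)
    p
  }
  e$backward <- function(dy) {
    p <- cache_pop(e)
    dy * p * (1 - p)
  }
  e
}

layer_upsample2 <- function() {
  e <- new_block("upsample")
  e$forward <- function(x, training = TRUE) .upsample2_fw(as_hwc(x))
  e$backward <- function(dy) .upsample2_bw(as_hwc(dy))
  e
}

# -- composites -------------------------------------------------------------

seq_block <- function(...) {
  e <- new_block("seq")
  e$children <- list(...)
  if (length(e$children) == 1L && is.list(e$children[[1]]) &&
      !is.environment(e$children[[1]]))
    e$children <- e$children[[1]]
  e$forward <- function(x, training = TRUE) {
    for (ch in e$children) x <- ch$forward(x, training)
    x
  }
  e$backward <- function(dy) {
    for (ch in rev(e$children)) dy <- ch$backward(dy)
    dy
  }
  e
}

# y = x + F(x): the residual unit, F = (conv - norm - ReLU) x 2.
residual_block <- function(ch, init = "gaussian") {
  e <- new_block("residual")
  body <- seq_block(
    layer_conv(ch, ch, 3L, 1L, 1L, init = init),
    layer_norm(ch, init = init),
    layer_relu(),
    layer_conv(ch, ch, 3L, 1L, 1L, init = init),
    layer_norm(ch, init = init),
    layer_relu()
  )
  e$children <- list(body)
  e$forward <- function(x, training = TRUE) x + body$forward(x, training)
  e$backward <- function(dy) dy + body$backward(dy)
  e
}

concat_channels <- function(a, b) {
  a <- as_hwc(a); b <- as_hwc(b)
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# -- parameter walks --------------------------------------------------------

param_layers <- function(block) {
  out <- list()
  walk <- function(b) {
    if (!is.null(b$par)) out[[length(out) + 1L]] <<- b
    for (ch in b$children) walk(ch)
  }
  walk(block)
  out
}

zero_grads <- function(block) {
  for (l in param_layers(block))
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  invisible(block)
}

clear_caches <- function(block) {
  walk <- function(b) {
    b$cache <- list()
    for (ch in b$children) walk(ch)
  }
  walk(block)
  invisible(block)
}

#' Count trainable parameters of a built network
#'
#' Totals the scalar entries of every weight, bias and normalization
#' parameter across a model built by [build_generator()] or
#' [build_discriminator()].  Layers frozen with [freeze_parameters()] are
#' excluded.
#'
#' @param model A network block as returned by the builders.
#' @return A single non-negative integer count.
#' @export
count_parameters <- function(model) {
  tot <- 0
  for (l in param_layers(model))
    if (!isTRUE(l$frozen)) tot <- tot + sum(vapply(l$par, length, 1L))
  as.integer(tot)
}

#' Freeze all parameters of a network
#'
#' Marks every parameter-bearing layer as non-trainable: the optimizer skips
#' it and [count_parameters()] reports zero.
#'
#' @param model A network block.
#' @return The model, invisibly.
#' @export
freeze_parameters <- function(model) {
  for (l in param_layers(model)) l$frozen <- TRUE
  invisible(model)
}

set_parameters_zero <- function(model) {
  for (l in param_layers(model))
    for (nm in names(l$par)) l$par[[nm]][] <- 0
  invisible(model)
}

# -- Adam -------------------------------------------------------------------

adam_new <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$state <- list()
  e
}

adam_step <- function(opt, model, grad_scale = 1) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  layers <- param_layers(model)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (isTRUE(l$frozen)) next
    key <- as.character(i)
    if (is.null(opt$state[[key]]))
      opt$state[[key]] <- lapply(l$par, function(p) {
        z <- p; z[] <- 0; list(m = z, v = z)
      })
    for (nm in names(l$par)) {
      g <- l$grad[[nm]] * grad_scale
      st <- opt$state[[key]][[nm]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      opt$state[[key]][[nm]] <- st
      l$par[[nm]] <- l$par[[nm]] -
        opt$lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    }
  }
  invisible(opt)
}
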