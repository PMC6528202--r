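# Training loops for paired (Pix2pix-style) and unpaired (cycle-consistent)
# adversarial translation, under the fixed recipe: Adam with learning rate
# 2e-4, beta1 = 0.5, batch size 1, no dropout, constant learning rate.

#' Assemble a training configuration
#'
#' Validates the full training recipe and pins the defaults used throughout:
#' learning rate 2e-4, Adam beta1 0.5 / beta2 0.999, 200 epochs, batch size
#' 1, L1 weight 0.5 for paired training and cycle weight 10 for unpaired.
#'
#' @param mode `"pix2pix"` (paired) or `"cyclegan"` (unpaired).
#' @param input_encoding Conditioning mode: `"mcml"`, `"fused_one_channel"`
#'   or `"vessel_only"`; its channel count must match the generator's
#'   `in_channels`.
#' @param generator A [generator_spec()].
#' @param discriminator A [discriminator_spec()], or `NULL` to derive one
#'   from the encoding (conditioning channels + 3 image channels for paired
#'   mode; image channels only for unpaired).
#' @param learning_rate Positive Adam step size.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param epochs Number of passes over the dataset (>= 1).
#' @param batch_size Samples per parameter update (>= 1).
#' @param lambda_weight L1 / cycle weight; `NULL` picks the mode default.
#' @param mse_warmup_iters Iterations of MSE-only generator initialization
#'   before adversarial training begins (default 0).
#' @param seed Integer seed governing all randomness (init, shuffling).
#' @param image_size Training resolution in pixels.
#' @param disc_base_width Discriminator base width when the spec is derived.
#' @param checkpoint_every Write a checkpoint every this many epochs into
#'   `checkpoint_dir` (0 = only at the end when a dir is given).
#' @param checkpoint_dir Optional checkpoint directory.
#' @param verbose Print per-epoch mean losses.
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("pix2pix", "cyclegan"),
                         input_encoding = c("mcml", "fused_one_channel",
                                            "vessel_only"),
                         generator = generator_spec("resunet"),
                         discriminator = NULL,
                         learning_rate = 2e-4,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         epochs = 200L, batch_size = 1L,
                         lambda_weight = NULL,
                         mse_warmup_iters = 0L,
                         seed = 0L, image_size = 256L,
                         disc_base_width = 64L,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  input_encoding <- match.arg(input_encoding)
  stopifnot(inherits(generator, "generator_spec"))
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (mse_warmup_iters < 0) stop("mse_warmup_iters must be >= 0", call. = FALSE)
  cond_ch <- encoding_channels(input_encoding)
  if (generator$in_channels != cond_ch)
    stop(sprintf(
      "encoding '%s' has %d channel(s) but the generator expects %d",
      input_encoding, cond_ch, generator$in_channels), call. = FALSE)
  if (is.null(lambda_weight))
    lambda_weight <- if (mode == "pix2pix") 0.5 else 10
  if (is.null(discriminator)) {
    d_in <- if (mode == "pix2pix") cond_ch + 3L else 3L
    n_lay <- max(2L, min(4L, as.integer(log2(image_size)) - 3L))
    discriminator <- discriminator_spec(in_channels = d_in,
                                        n_layers = n_lay,
                                        base_width = disc_base_width)
  }
  structure(list(mode = mode, input_encoding = input_encoding,
                 generator = generator, discriminator = discriminator,
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_weight = lambda_weight,
                 mse_warmup_iters = as.integer(mse_warmup_iters),
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "train_config")
}

resolve_dataset <- function(dataset, config) {
  if (is.character(dataset))
    dataset <- load_paired_dataset(dataset, config$input_encoding,
                                   config$image_size)
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  d <- dim(as_hwc(dataset[[1]]$cond))
  if (d[3] != config$generator$in_channels)
    stop(sprintf("dataset conditioning has %d channel(s), generator expects %d",
                 d[3], config$generator$in_channels), call. = FALSE)
  dataset
}

# Gradient of -mean(log p) over a probability map (non-saturating G target
# and the real-label half of the discriminator loss).
grad_neglogp <- function(p) -1 / (length(p) * p)
# Gradient of -mean(log(1 - p)) (fake-label half).
grad_neglog1mp <- function(p) 1 / (length(p) * (1 - p))

new_history <- function() {
  tibble::tibble(iteration = integer(), epoch = integer(),
                 adv_g = numeric(), adv_d = numeric(), l1 = numeric(),
                 cycle = numeric(), total_g = numeric(), total_d = numeric())
}

train_result <- function(kind, models, history, config, checkpoint = NULL,
                         wall_time = NA_real_) {
  final <- dplyr::summarise(
    dplyr::filter(history, .data$epoch == max(.data$epoch)),
    dplyr::across(c("adv_g", "adv_d", "l1", "cycle", "total_g", "total_d"),
                  mean))
  structure(c(models,
              list(kind = kind, history = history, config = config,
                   final_losses = final, checkpoint = checkpoint,
                   wall_time = wall_time)),
            class = c(paste0("mcml_", kind), "mcml_train_result"))
}

maybe_checkpoint <- function(result_models, config, epoch, force = FALSE) {
  dir <- config$checkpoint_dir
  if (is.null(dir)) return(NULL)
  want <- force || (config$checkpoint_every > 0 &&
                    epoch %% config$checkpoint_every == 0)
  if (!want) return(NULL)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("checkpoint_epoch%04d.rds", epoch))
  save_checkpoint(result_models$generator %||% result_models$generator_ab,
                  config, path, epoch = epoch)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a paired mask-to-image translation model
#'
#' Alternates one discriminator update and one generator update per batch.
#' The discriminator sees (conditioning, real) as real and (conditioning,
#' generated) as fake; the generator minimizes the non-saturating
#' adversarial term plus `lambda_weight` times the global L1 to the target.
#' All randomness (weight init, shuffling) derives from `config$seed`, so
#' identical inputs reproduce identical loss histories.
#'
#' @param dataset A dataset directory in the standard layout, or a list of
#'   samples as returned by [load_paired_dataset()].
#' @param config A [train_config()] with `mode = "pix2pix"`.
#' @return An `mcml_train_result` holding the trained `generator`,
#'   `discriminator`, the per-iteration loss `history` tibble and the final
#'   per-epoch mean losses.
#' @export
train_pix2pix <- function(dataset, config) {
  stopifnot(inherits(config, "train_config"), config$mode == "pix2pix")
  dataset <- resolve_dataset(dataset, config)
  n <- length(dataset)
  t0 <- Sys.time()

  set.seed(config$seed)
  g <- build_generator(config$generator, config$image_size)
  d <- build_discriminator(config$discriminator)
  opt_g <- adam_new(config$learning_rate, config$adam_beta1, config$adam_beta2)
  opt_d <- adam_new(config$learning_rate, config$adam_beta1, config$adam_beta2)

  lambda <- config$lambda_weight
  history <- vector("list", config$epochs)
  iter <- 0L
  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(n)
    rows <- vector("list", length(order))
    bcount <- 0L
    for (bi in seq_along(order)) {
      s <- dataset[[order[bi]]]
      iter <- iter + 1L
      bcount <- bcount + 1L

      fake <- g$forward(s$cond, TRUE)

      if (iter <= config$mse_warmup_iters) {
        # MSE-only generator initialization
        g$backward(2 * (fake - s$real) / length(fake))
        l1v <- l1_loss(fake, s$real)
        rows[[bi]] <- tibble::tibble(iteration = iter, epoch = epoch,
                                     adv_g = NA_real_, adv_d = NA_real_,
                                     l1 = l1v, cycle = NA_real_,
                                     total_g = mean((fake - s$real)^2),
                                     total_d = NA_real_)
      } else {
        # --- discriminator step ---
        p_real <- discriminate(d, s$cond, s$real, TRUE)
        d$backward(grad_neglogp(p_real))
        p_fake_d <- discriminate(d, s$cond, fake, TRUE)
        d$backward(grad_neglog1mp(p_fake_d))
        adv_d <- discriminator_loss(p_real, p_fake_d)

        # --- generator step ---
        p_fake_g <- discriminate(d, s$cond, fake, TRUE)
        dcat <- d$backward(grad_neglogp(p_fake_g))
        cond_ch <- dim(as_hwc(s$cond))[3]
        dfake <- dcat[, , cond_ch + 1:3, drop = FALSE]
        dfake <- dfake + lambda * sign(fake - s$real) / length(fake)
        g$backward(dfake)

        lb <- pix2pix_generator_loss(p_fake_g, fake, s$real, lambda)
        rows[[bi]] <- tibble::tibble(iteration = iter, epoch = epoch,
                                     adv_g = lb$adv_g, adv_d = adv_d,
                                     l1 = lb$l1, cycle = NA_real_,
                                     total_g = lb$total_g, total_d = adv_d)
      }

      if (bcount == config$batch_size || bi == length(order)) {
        scale <- 1 / bcount
        if (iter > config$mse_warmup_iters) {
          adam_step(opt_d, d, scale)
        }
        adam_step(opt_g, g, scale)
        zero_grads(d); zero_grads(g)
        bcount <- 0L
      }
    }
    history[[epoch]] <- dplyr::bind_rows(rows)
    if (isTRUE(config$verbose))
      message(sprintf("epoch %d/%d  L1 %.4f", epoch, config$epochs,
                      mean(history[[epoch]]$l1)))
    maybe_checkpoint(list(generator = g), config, epoch)
  }

  history <- dplyr::bind_rows(history)
  ckpt <- maybe_checkpoint(list(generator = g), config, config$epochs,
                           force = !is.null(config$checkpoint_dir))
  train_result("pix2pix", list(generator = g, discriminator = d),
               history, config, checkpoint = ckpt,
               wall_time = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
}

#' Train an unpaired translation model with cycle consistency
#'
#' Maintains two generators (`G1:` A to B, `G2:` B to A) and two
#' discriminators (D1 on domain A, D2 on domain B).  Per batch both
#' discriminators are updated, then both generators jointly with the two
#' non-saturating adversarial terms plus `lambda_weight` times the
#' two-directional cycle-consistency L1.  Each epoch permutes both domains
#' independently under the seed and runs `max(|A|, |B|)` iterations,
#' wrapping the smaller domain.
#'
#' @param dataset_a Mask-encoding domain: directory or list of samples
#'   (their `cond` arrays are used).
#' @param dataset_b Image domain: directory (its `fundus/` images) or list
#'   of samples (their `real` arrays are used).
#' @param config A [train_config()] with `mode = "cyclegan"`.  Domain A
#'   images must have `generator$in_channels` channels; for cycle training
#'   the two domains must share a channel count, so the MCML encoding (3
#'   channels) is the natural pairing with RGB images.
#' @return An `mcml_train_result` with `generator_ab`, `generator_ba`,
#'   `discriminator_a`, `discriminator_b` and the loss `history`.
#' @export
train_cyclegan <- function(dataset_a, dataset_b, config) {
  stopifnot(inherits(config, "train_config"), config$mode == "cyclegan")
  if (is.character(dataset_a))
    dataset_a <- load_paired_dataset(dataset_a, config$input_encoding,
                                     config$image_size)
  if (is.character(dataset_b))
    dataset_b <- load_paired_dataset(dataset_b, config$input_encoding,
                                     config$image_size)
  xs_a <- lapply(dataset_a, function(s) as_hwc(if (is.list(s)) s$cond else s))
  xs_b <- lapply(dataset_b, function(s) as_hwc(if (is.list(s)) s$real else s))
  if (length(xs_a) == 0 || length(xs_b) == 0)
    stop("both domains must be non-empty", call. = FALSE)
  ch_a <- dim(xs_a[[1]])[3]; ch_b <- dim(xs_b[[1]])[3]
  if (ch_a != ch_b)
    stop(sprintf(
      "cycle training needs equal channel counts in both domains (A: %d, B: %d)",
      ch_a, ch_b), call. = FALSE)
  t0 <- Sys.time()

  set.seed(config$seed)
  spec_ab <- config$generator
  spec_ba <- config$generator
  spec_ba$in_channels <- ch_b
  spec_ba$out_channels <- ch_a
  g1 <- build_generator(spec_ab, config$image_size)   # A -> B
  g2 <- build_generator(spec_ba, config$image_size)   # B -> A
  dspec_a <- discriminator_spec(ch_a, config$discriminator$n_layers,
                                config$discriminator$base_width)
  dspec_b <- discriminator_spec(ch_b, config$discriminator$n_layers,
                                config$discriminator$base_width)
  d1 <- build_discriminator(dspec_a)                  # domain A
  d2 <- build_discriminator(dspec_b)                  # domain B
  opts <- lapply(1:4, function(i)
    adam_new(config$learning_rate, config$adam_beta1, config$adam_beta2))

  lambda <- config$lambda_weight
  n_iter <- max(length(xs_a), length(xs_b))
  history <- vector("list", config$epochs)
  iter <- 0L
  for (epoch in seq_len(config$epochs)) {
    ia <- rep_len(sample.int(length(xs_a)), n_iter)
    ib <- rep_len(sample.int(length(xs_b)), n_iter)
    rows <- vector("list", n_iter)
    for (t in seq_len(n_iter)) {
      iter <- iter + 1L
      a <- xs_a[[ia[t]]]; b <- xs_b[[ib[t]]]

      # --- discriminator steps (generators fixed) ---
      b_fake <- g1$forward(a, TRUE)
      a_fake <- g2$forward(b, TRUE)
      clear_caches(g1); clear_caches(g2)

      zero_grads(d2)
      p_real_b <- d2$forward(b, TRUE); d2$backward(grad_neglogp(p_real_b))
      p_fake_b <- d2$forward(b_fake, TRUE)
      d2$backward(grad_neglog1mp(p_fake_b))
      adv_d2 <- discriminator_loss(p_real_b, p_fake_b)
      adam_step(opts[[3]], d2)

      zero_grads(d1)
      p_real_a <- d1$forward(a, TRUE); d1$backward(grad_neglogp(p_real_a))
      p_fake_a <- d1$forward(a_fake, TRUE)
      d1$backward(grad_neglog1mp(p_fake_a))
      adv_d1 <- discriminator_loss(p_real_a, p_fake_a)
      adam_step(opts[[4]], d1)

      # --- joint generator step ---
      zero_grads(g1); zero_grads(g2); zero_grads(d1); zero_grads(d2)
      b_fake <- g1$forward(a, TRUE)
      a_cyc <- g2$forward(b_fake, TRUE)
      a_fake <- g2$forward(b, TRUE)
      b_cyc <- g1$forward(a_fake, TRUE)

      p_b <- d2$forward(b_fake, TRUE)
      db_fake_adv <- d2$backward(grad_neglogp(p_b))
      p_a <- d1$forward(a_fake, TRUE)
      da_fake_adv <- d1$backward(grad_neglogp(p_a))

      da_cyc <- lambda * sign(a_cyc - a) / length(a_cyc)
      db_cyc <- lambda * sign(b_cyc - b) / length(b_cyc)

      # LIFO over the four generator forwards
      da_fake_from_cyc <- g1$backward(db_cyc)
      g2$backward(da_fake_adv + da_fake_from_cyc)
      db_fake_from_cyc <- g2$backward(da_cyc)
      g1$backward(db_fake_adv + db_fake_from_cyc)

      adam_step(opts[[1]], g1)
      adam_step(opts[[2]], g2)
      zero_grads(g1); zero_grads(g2); zero_grads(d1); zero_grads(d2)

      adv_g <- generator_adversarial_loss(p_b) + generator_adversarial_loss(p_a)
      cyc <- cycle_consistency_loss(a, a_cyc, b, b_cyc)
      rows[[t]] <- tibble::tibble(iteration = iter, epoch = epoch,
                                  adv_g = adv_g, adv_d = adv_d1 + adv_d2,
                                  l1 = NA_real_, cycle = cyc,
                                  total_g = adv_g + lambda * cyc,
                                  total_d = adv_d1 + adv_d2)
    }
    history[[epoch]] <- dplyr::bind_rows(rows)
    if (isTRUE(config$verbose))
      message(sprintf("epoch %d/%d  cycle %.4f", epoch, config$epochs,
                      mean(history[[epoch]]$cycle)))
  }

  history <- dplyr::bind_rows(history)
  train_result("cyclegan",
               list(generator_ab = g1, generator_ba = g2,
                    discriminator_a = d1, discriminator_b = d2),
               history, config,
               wall_time = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
}

#' Synthesize fundus images from conditioning inputs
#'
#' Runs the trained generator in inference mode (accumulated normalization
#' statistics, no stochastic layers), so repeated calls on the same input
#' are bit-identical.  Output is denormalized to quantized 8-bit RGB.
#'
#' @param model An `mcml_train_result`, a generator network, or a checkpoint
#'   path written by [save_checkpoint()].
#' @param conditioning One conditioning array or a list of them, on the
#'   model \[-1, 1\] scale (see [encode_conditioning()]).
#' @return One `H x W x 3` 8-bit image, or a list of them in input order.
#' @export
synthesize <- function(model, conditioning) {
  g <- if (inherits(model, "mcml_train_result"))
         model$generator %||% model$generator_ab
       else if (is.character(model)) load_checkpoint(model)$generator
       else model
  one <- function(x) {
    x <- as_hwc(x)
    if (dim(x)[3] != g$spec$in_channels)
      stop(sprintf("conditioning has %d channel(s), generator expects %d",
                   dim(x)[3], g$spec$in_channels), call. = FALSE)
    y <- g$forward(x, training = FALSE)
    clear_caches(g)
    denormalize_image(y)
  }
  if (is.list(conditioning) && !is.array(conditioning))
    lapply(conditioning, one)
  else one(conditioning)
}

get_parameters <- function(model) {
  lapply(param_layers(model), function(l)
    list(par = l$par,
         buffers = if (!is.null(l$buffers)) l$buffers))
}

set_parameters <- function(model, params) {
  layers <- param_layers(model)
  stopifnot(length(layers) == length(params))
  for (i in seq_along(layers)) {
    layers[[i]]$par <- params[[i]]$par
    if (!is.null(params[[i]]$buffers)) layers[[i]]$buffers <- params[[i]]$buffers
  }
  invisible(model)
}

#' Save / load a generator checkpoint
#'
#' Checkpoints carry the generator weights and normalization statistics, the
#' architecture spec, the training configuration and a format version, so a
#' saved generator can be rebuilt and run exactly.
#'
#' @param generator A built generator network.
#' @param config The [train_config()] used to train it.
#' @param path Checkpoint file path (RDS).
#' @param epoch Training epoch the checkpoint was taken at.
#' @return `save_checkpoint()`: the path, invisibly.  `load_checkpoint()`:
#'   list with the rebuilt `generator`, `config` and `epoch`.
#' @export
save_checkpoint <- function(generator, config, path, epoch = NA_integer_) {
  saveRDS(list(format = "mcmlfundus-checkpoint-1",
               spec = generator$spec, size = generator$size,
               params = get_parameters(generator),
               config = config, epoch = epoch,
               package_version = as.character(
                 utils::packageVersion("mcmlfundus"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "mcmlfundus-checkpoint-1"))
    stop("not a recognized checkpoint file: ", path, call. = FALSE)
  g <- build_generator(ck$spec, ck$size, init = "zeros")
  set_parameters(g, ck$params)
  list(generator = g, config = ck$config, epoch = ck$epoch)
}
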