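test_that("training configuration rejects inconsistent setups early", {
  expect_error(
    train_config(input_encoding = "mcml",
                 generator = generator_spec("unet", in_channels = 1)),
    "channel")
  expect_error(
    train_config(input_encoding = "vessel_only",
                 generator = generator_spec("unet", in_channels = 3)),
    "channel")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(epochs = 0), "epochs")

  # mode-dependent default loss weights
  expect_equal(train_config(generator = generator_spec("unet"))$lambda_weight,
               0.5)
  expect_equal(train_config(
    mode = "cyclegan", generator = generator_spec("unet"))$lambda_weight, 10)

  cfg <- small_train_config()
  expect_error(train_pix2pix(list(), cfg), "empty")
})

test_that("loss history bookkeeping matches epochs x samples", {
  d <- tiny_dataset(n = 4, size = 32, seed = 1)
  cfg <- small_train_config(epochs = 1)
  r <- train_pix2pix(d, cfg)
  expect_equal(nrow(r$history), 4)
  expect_equal(unique(r$history$epoch), 1L)
  expect_equal(r$history$iteration, 1:4)
  expect_true(all(is.finite(r$history$l1)))
  expect_true(all(r$history$adv_d >= 0))
  expect_equal(nrow(tidy(r)), 4)
  expect_equal(glance(r)$iterations, 4)
  unlink(d, recursive = TRUE)
})

test_that("identical config and seed reproduce identical loss histories", {
  d <- tiny_dataset(n = 2, size = 32, seed = 2)
  cfg <- small_train_config(epochs = 2, seed = 5)
  h1 <- train_pix2pix(d, cfg)$history
  h2 <- train_pix2pix(d, cfg)$history
  expect_identical(h1, h2)
  h3 <- train_pix2pix(d, small_train_config(epochs = 2, seed = 6))$history
  expect_false(identical(h1$l1, h3$l1))
  unlink(d, recursive = TRUE)
})

test_that("single-pair training drives L1 down for every generator family", {
  d <- tiny_dataset(n = 1, size = 32, seed = 3)
  for (fam in c("unet", "resnet6", "resnet9", "resunet")) {
    for (seed in 0:1) {
      cfg <- small_train_config(family = fam, epochs = 40, seed = seed)
      h <- train_pix2pix(d, cfg)$history
      first <- mean(h$l1[h$epoch == 1])
      last <- mean(h$l1[h$epoch == max(h$epoch)])
      expect_lt(last, first)
    }
  }
  unlink(d, recursive = TRUE)
})

test_that("a discriminator alone learns to beat chance on real vs fake", {
  d <- tiny_dataset(n = 2, size = 32, seed = 4)
  ds <- load_paired_dataset(d, "mcml")
  set.seed(0)
  g <- build_generator(generator_spec("unet", base_width = 4), 32)
  freeze_parameters(g)                      # frozen random generator
  disc <- build_discriminator(discriminator_spec(6, 3, 8))
  opt <- mcmlfundus:::adam_new()
  losses <- numeric(0)
  for (it in 1:200) {
    s <- ds[[(it %% length(ds)) + 1]]
    fake <- g$forward(s$cond, TRUE)
    mcmlfundus:::clear_caches(g)
    p_real <- discriminate(disc, s$cond, s$real, TRUE)
    disc$backward(mcmlfundus:::grad_neglogp(p_real))
    p_fake <- discriminate(disc, s$cond, fake, TRUE)
    disc$backward(mcmlfundus:::grad_neglog1mp(p_fake))
    losses[it] <- discriminator_loss(p_real, p_fake)
    mcmlfundus:::adam_step(opt, disc)
    mcmlfundus:::zero_grads(disc)
  }
  expect_lt(min(losses), log(2))
  unlink(d, recursive = TRUE)
})

test_that("unpaired training iterates over the larger domain per epoch", {
  d <- tiny_dataset(n = 5, size = 32, seed = 5)
  ds <- load_paired_dataset(d, "mcml")
  a <- ds[1:3]                       # |A| = 3 mask encodings
  b <- lapply(ds, function(s) s$real)  # |B| = 5 images
  cfg <- train_config(mode = "cyclegan", input_encoding = "mcml",
                      generator = generator_spec("resnet6", base_width = 4),
                      epochs = 1, image_size = 32, seed = 0,
                      disc_base_width = 4)
  r <- train_cyclegan(a, b, cfg)
  expect_equal(nrow(r$history), 5)
  expect_true(all(is.finite(r$history$cycle)))

  h2 <- train_cyclegan(a, b, cfg)$history
  expect_identical(r$history, h2)
  unlink(d, recursive = TRUE)
})

test_that("cycle term decreases when both domains coincide", {
  d <- tiny_dataset(n = 3, size = 32, seed = 6)
  ds <- load_paired_dataset(d, "mcml")
  imgs <- lapply(ds, function(s) s$real)   # A = B = images
  cfg <- train_config(mode = "cyclegan", input_encoding = "mcml",
                      generator = generator_spec("resnet6", base_width = 4),
                      epochs = 10, image_size = 32, seed = 0,
                      disc_base_width = 4, lambda_weight = 10)
  h <- train_cyclegan(imgs, imgs, cfg)$history
  first <- mean(h$cycle[h$epoch <= 2])
  last <- mean(h$cycle[h$epoch >= max(h$epoch) - 1])
  expect_lt(last, first)
  unlink(d, recursive = TRUE)
})

test_that("synthesis is deterministic, shaped, and range-safe", {
  d <- tiny_dataset(n = 1, size = 32, seed = 7)
  cfg <- small_train_config(epochs = 1)
  r <- train_pix2pix(d, cfg)
  cond <- load_paired_dataset(d, "mcml")[[1]]$cond
  y1 <- synthesize(r, cond)
  y2 <- synthesize(r, cond)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(32, 32, 3))
  expect_true(all(y1 >= 0 & y1 <= 255))

  zero <- synthesize(r, array(0, c(32, 32, 3)))
  expect_true(all(is.finite(zero)) && all(zero >= 0 & zero <= 255))

  expect_error(synthesize(r, array(0, c(32, 32, 1))), "channel")
  unlink(d, recursive = TRUE)
})

test_that("checkpoints round-trip the generator exactly", {
  d <- tiny_dataset(n = 1, size = 32, seed = 8)
  cfg <- small_train_config(epochs = 1)
  r <- train_pix2pix(d, cfg)
  cond <- load_paired_dataset(d, "mcml")[[1]]$cond
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(r$generator, cfg, ck, epoch = 1)
  reloaded <- load_checkpoint(ck)
  expect_identical(synthesize(reloaded$generator, cond), synthesize(r, cond))
  expect_error(suppressWarnings(load_checkpoint(tempfile())))
  unlink(c(d, ck), recursive = TRUE)
})

test_that("MSE warmup precedes adversarial updates when requested", {
  d <- tiny_dataset(n = 2, size = 32, seed = 9)
  cfg <- small_train_config(epochs = 2, mse_warmup_iters = 2)
  h <- train_pix2pix(d, cfg)$history
  expect_true(all(is.na(h$adv_g[1:2])))
  expect_true(all(is.finite(h$adv_g[3:4])))
  unlink(d, recursive = TRUE)
})
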