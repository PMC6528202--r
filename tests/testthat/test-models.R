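families <- c("unet", "resnet6", "resnet9", "resunet")

test_that("every generator family preserves spatial shape", {
  set.seed(0)
  for (fam in families) {
    for (size in c(32, 64)) {
      spec <- generator_spec(fam, base_width = 4)
      g <- build_generator(spec, size)
      x <- array(runif(size * size * 3, -1, 1), c(size, size, 3))
      y <- g$forward(x, TRUE)
      expect_equal(dim(y), c(size, size, 3),
                   info = sprintf("%s at %d", fam, size))
      expect_true(all(y >= -1 & y <= 1))
    }
  }
})

test_that("indivisible input sizes are rejected with a clear message", {
  spec <- generator_spec("unet", base_width = 4)
  expect_error(build_generator(spec, 100), "divisible")
  expect_error(build_generator(generator_spec("resnet6"), 33), "divisible")
})

test_that("residual blocks reduce to the identity at zero weights", {
  set.seed(1)
  rb <- mcmlfundus:::residual_block(4, init = "zeros")
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_identical(rb$forward(x, TRUE), x)

  # explicit forward rule
  x2 <- array(rnorm(24), c(2, 3, 4))
  expect_identical(residual_block_forward(x2, function(z) z * 0), x2)
  b <- array(5, c(2, 3, 4))
  expect_equal(residual_block_forward(x2 * 0, function(z) b), b)
  f <- function(z) 2 * z + 1
  expect_equal(residual_block_forward(x2, f), x2 + f(x2))
  expect_error(residual_block_forward(x2, function(z) z[, , 1:2]), "shape")
})

test_that("residual variants strictly add parameters", {
  set.seed(0)
  unet <- build_generator(generator_spec("unet", base_width = 4), 32)
  res1 <- build_generator(generator_spec("resunet", base_width = 4,
                                         n_res_blocks = 1), 32)
  res2 <- build_generator(generator_spec("resunet", base_width = 4,
                                         n_res_blocks = 2), 32)
  expect_gt(count_parameters(res1), count_parameters(unet))
  expect_gt(count_parameters(res2), count_parameters(res1))
  r6 <- build_generator(generator_spec("resnet6", base_width = 4), 32)
  r9 <- build_generator(generator_spec("resnet9", base_width = 4), 32)
  expect_gt(count_parameters(r9), count_parameters(r6))
})

test_that("parameter counting is exact, additive, and respects freezing", {
  conv <- mcmlfundus:::layer_conv(1, 1, 3)
  expect_identical(count_parameters(conv), 10L)   # 9 weights + 1 bias

  set.seed(2)
  g <- build_generator(generator_spec("resnet6", base_width = 4), 32)
  child_sum <- sum(vapply(g$children, count_parameters, integer(1)))
  expect_identical(count_parameters(g), child_sum)

  freeze_parameters(g)
  expect_identical(count_parameters(g), 0L)
})

test_that("discriminator outputs are patch probabilities in (0,1)", {
  set.seed(3)
  spec <- discriminator_spec(in_channels = 6, n_layers = 3, base_width = 4)
  d <- build_discriminator(spec)
  cond <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  img <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  p <- discriminate(d, cond, img, TRUE)
  expect_true(all(p > 0 & p < 1))

  # fully convolutional: doubling the input doubles the output map
  cond2 <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  img2 <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  p2 <- discriminate(d, cond2, img2, TRUE)
  expect_equal(dim(p2)[1:2], 2 * dim(p)[1:2])

  # zero-initialized network sits exactly at chance
  d0 <- build_discriminator(spec, init = "zeros")
  p0 <- discriminate(d0, cond, img, TRUE)
  expect_true(all(p0 == 0.5))

  expect_error(discriminate(d, cond[, , 1, drop = FALSE], img), "channels")
})

test_that("one backward pass reaches every trainable parameter", {
  set.seed(4)
  nets <- c(lapply(families, function(f)
    build_generator(generator_spec(f, base_width = 4), 32)),
    list(build_discriminator(discriminator_spec(3, 3, 4))))
  for (net in nets) {
    x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
    y <- net$forward(x, TRUE)
    net$backward(array(rnorm(length(y)), dim(y)))
    for (l in mcmlfundus:::param_layers(net)) {
      for (nm in names(l$grad)) {
        expect_true(all(is.finite(l$grad[[nm]])))
        expect_gt(sum(abs(l$grad[[nm]])), 0)
      }
    }
  }
})

test_that("generator and discriminator specs validate their fields", {
  expect_error(generator_spec("resunet", n_res_blocks = 4), "n_res_blocks")
  expect_error(generator_spec("unet", in_channels = 2), "in_channels")
  expect_error(discriminator_spec(n_layers = 0), "n_layers")
})
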