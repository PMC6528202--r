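test_that("binarize thresholds exactly and is idempotent", {
  expect_equal(binarize(matrix(0, 8, 8)), matrix(0, 8, 8))
  m <- matrix(c(0, 255), 8, 8)
  expect_equal(binarize(m), (m > 127) * 1)
  expect_equal(binarize(binarize(m) * 255), binarize(m))

  set.seed(11)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  for (t in c(0, 50, 127, 254)) {
    got <- binarize(img, t)
    # brute-force pixel scan
    expect_equal(sum(got), sum(img > t))
    expect_true(all(got[img > t] == 1) && all(got[img <= t] == 0))
  }
  expect_error(binarize(array(0, c(4, 4, 3))), "single-channel")
})

test_that("multi-channel composition is lossless and order-pinned", {
  expect_equal(unclass(compose_mcml(matrix(0, 4, 4), matrix(0, 4, 4),
                                    matrix(0, 4, 4)))[, , 1:3],
               array(0, c(4, 4, 3)), ignore_attr = TRUE)
  v <- matrix(0, 4, 4); v[2, 2] <- 1
  d <- matrix(0, 4, 4); d[2, 2] <- 1
  k <- matrix(0, 4, 4)
  x <- compose_mcml(v, d, k)
  expect_equal(as.numeric(x[2, 2, ]), c(1, 1, 0))

  set.seed(7)
  for (i in 1:10) {
    v <- matrix(rbinom(64, 1, 0.4), 8, 8)
    d <- matrix(rbinom(64, 1, 0.4), 8, 8)
    k <- matrix(rbinom(64, 1, 0.4), 8, 8) * d
    got <- mcml_channels(compose_mcml(v, d, k))
    expect_identical(got$vessel, v + 0)
    expect_identical(got$disc, d + 0)
    expect_identical(got$cup, k + 0)
  }
  expect_error(compose_mcml(matrix(0, 4, 4), matrix(0, 5, 5),
                            matrix(0, 4, 4)), "dimensions")
  expect_error(compose_mcml(landmark_mask(matrix(0, 4, 4), "disc"),
                            matrix(0, 4, 4), matrix(0, 4, 4)), "role")
})

test_that("one-channel fusion encodes by level and loses disc overlap", {
  expect_equal(fuse_one_channel(matrix(0, 4, 4), matrix(0, 4, 4)),
               matrix(0, 4, 4))
  v <- matrix(0, 8, 8); v[1, ] <- 1
  d <- matrix(0, 8, 8); d[5:7, 5:7] <- 1
  f <- fuse_one_channel(v, d)
  expect_setequal(unique(as.numeric(f)), c(0, 128, 255))

  # vessel crossing the disc: disc recovery by intensity alone is wrong
  # exactly at the overlap pixels
  v2 <- matrix(0, 8, 8); v2[5, ] <- 1
  f2 <- fuse_one_channel(v2, d)
  disc_recovered <- (f2 == 128) * 1
  wrong <- which(disc_recovered != d)
  expect_identical(sort(wrong), sort(which(v2 == 1 & d == 1)))

  # constructive witness of non-invertibility: two distinct (vessel, disc)
  # pairs with identical fused output
  va <- matrix(0, 6, 6); va[3, 3] <- 1
  da <- matrix(0, 6, 6); da[3, 3] <- 1
  expect_identical(fuse_one_channel(va, da), fuse_one_channel(va, da * 0))
})

test_that("vessel-only conditioning is a value-preserving pass-through", {
  expect_equal(vessel_only(matrix(0, 4, 4)), matrix(0, 4, 4))
  set.seed(3)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(vessel_only(m), m + 0)
  expect_equal((normalize_mask(m) + 1) / 2, m + 0)
})

test_that("model-scale mapping is invertible on 8-bit data", {
  imgs <- list(matrix(0:255, 16, 16), round(random_image(9, 7, 3)))
  set.seed(5)
  for (img in imgs)
    expect_equal(denormalize_image(normalize_image(img)), img,
                 ignore_attr = TRUE)
})

test_that("encodings keep the spatial grid and advertised channel count", {
  v <- matrix(rbinom(100, 1, 0.3), 10, 10)
  d <- matrix(rbinom(100, 1, 0.2), 10, 10)
  k <- d * matrix(rbinom(100, 1, 0.5), 10, 10)
  for (enc in c("mcml", "fused_one_channel", "vessel_only")) {
    x <- encode_conditioning(v, d, k, enc)
    expect_equal(dim(x)[1:2], c(10, 10))
    expect_equal(dim(x)[3], encoding_channels(enc))
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("resizing behaves per method: identity, binary, constant", {
  m <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  expect_equal(resize_image(m, c(64, 64), "nearest"), m + 0)
  small <- resize_image(m, c(32, 32), "nearest")
  expect_true(all(small %in% c(0, 1)))
  expect_equal(dim(small), c(32, 32))

  const <- array(77, c(20, 30, 3))
  for (meth in c("nearest", "bicubic")) {
    out <- resize_image(const, c(13, 17), meth)
    expect_equal(out, array(77, c(13, 17, 3)), tolerance = 1e-10)
  }
  img <- random_image(32, 32, 3)
  rp <- resize_pair(img, m[1:32, 1:32], c(16, 16))
  expect_true(all(rp$mask %in% c(0, 1)))
  expect_equal(dim(rp$image), c(16, 16, 3))
  expect_error(resize_image(img, c(0, 4)), "positive")
})
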