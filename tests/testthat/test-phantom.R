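test_that("phantom generation is a pure function of its parameters", {
  p <- phantom_params(image_size = 64, seed = 42)
  s1 <- generate_phantom(p)
  s2 <- generate_phantom(p)
  expect_identical(s1$vessel, s2$vessel)
  expect_identical(s1$fundus, s2$fundus)
  # a different seed changes the vessel tree
  s3 <- generate_phantom(phantom_params(image_size = 64, seed = 43))
  expect_false(identical(s1$vessel, s3$vessel))
})

test_that("depth-1 zero-jitter vessel tree is a single connected stroke", {
  p <- phantom_params(image_size = 64, vessel_depth = 1, vessel_n_roots = 1,
                      branch_angle_jitter = 0, seed = 3)
  m <- generate_vessel_tree(p)
  expect_true(all(m %in% c(0, 1)))
  expect_gt(sum(m), 0)
  expect_identical(count_components(m), 1L)
})

test_that("full vessel trees are connected and of moderate density", {
  fracs <- vapply(1:25, function(s)
    mean(generate_vessel_tree(phantom_params(seed = s))), numeric(1))
  expect_true(all(fracs >= 0.02 & fracs <= 0.20))
  m <- generate_vessel_tree(phantom_params(image_size = 96, seed = 5))
  expect_identical(count_components(m), 1L)
})

test_that("disc and cup are concentric with the requested size ratio", {
  p <- phantom_params(image_size = 128, disc_radius = 40, cdr = 0.5,
                      disc_center = c(64, 64))
  dc <- generate_disc_cup(p)
  expect_true(all(dc$cup <= dc$disc))
  expect_equal(estimate_cdr(dc$disc, dc$cup), 0.5, tolerance = 0.03)

  # rasterized area ratio tracks cdr^2 for a range of ratios
  for (cdr in c(0.3, 0.45, 0.6, 0.75)) {
    p <- phantom_params(image_size = 160, disc_radius = 50, cdr = cdr,
                        disc_center = c(80, 80), fundus_radius_frac = 1)
    dc <- generate_disc_cup(p)
    expect_equal(sum(dc$cup) / sum(dc$disc), cdr^2, tolerance = 0.05)
  }
})

test_that("cup stays inside the disc even at extreme cup-to-disc ratio", {
  p <- phantom_params(image_size = 256, disc_radius = 100, cdr = 0.99,
                      disc_center = c(128, 128), fundus_radius_frac = 1)
  dc <- generate_disc_cup(p)
  expect_true(all(dc$cup <= dc$disc))
  expect_gt(sum(dc$cup), 0)
})

test_that("cdr recovery is within 5% relative error for disc_radius >= 20", {
  for (cdr in c(0.35, 0.5, 0.65)) {
    for (rad in c(20, 35, 60)) {
      p <- phantom_params(image_size = 192, disc_radius = rad, cdr = cdr,
                          disc_center = c(96, 96), fundus_radius_frac = 1)
      dc <- generate_disc_cup(p)
      expect_lt(abs(estimate_cdr(dc$disc, dc$cup) - cdr) / cdr, 0.05)
    }
  }
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(image_size = 16), "image_size")
  expect_error(phantom_params(cdr = 0), "cdr")
  expect_error(phantom_params(cdr = 1), "cdr")
  expect_error(phantom_params(vessel_root_width = 0), "vessel_root_width")
  expect_error(phantom_params(disc_radius = 200, image_size = 64), "disc")
  expect_error(phantom_params(width_decay = 1.5), "width_decay")
})

test_that("rendering enforces the cup > disc rim > fundus field ordering", {
  p <- phantom_params(image_size = 96, noise_sigma = 0, seed = 1)
  s <- generate_phantom(p)
  luma <- apply(s$fundus, 1:2, mean)
  geo_inside <- s$disc == 0 & s$vessel == 0 &
    apply(s$fundus, 1:2, max) > 20      # fundus field, off-landmark
  cup_mean <- mean(luma[s$cup > 0 & s$vessel == 0])
  ring_mean <- mean(luma[s$disc > 0 & s$cup == 0 & s$vessel == 0])
  field_mean <- mean(luma[geo_inside])
  expect_gt(cup_mean, ring_mean)
  expect_gt(ring_mean, field_mean)

  # vessels are dark in the green channel, and visible inside the disc
  green <- s$fundus[, , 2]
  expect_lt(mean(green[s$vessel > 0]), mean(green[geo_inside]))
  if (any(s$vessel > 0 & s$disc > 0))
    expect_lt(mean(green[s$vessel > 0 & s$disc > 0]),
              mean(green[s$disc > 0 & s$vessel == 0]))
})

test_that("rendering validates its mask inputs", {
  p <- phantom_params(image_size = 64)
  ok <- generate_phantom(p)
  bad <- ok$vessel[1:32, 1:32]
  expect_error(render_fundus(bad, ok$disc, ok$cup, p), "dimensions")
  nonbin <- ok$vessel; nonbin[1, 1] <- 0.5
  expect_error(render_fundus(nonbin, ok$disc, ok$cup, p), "binary")
  outside <- matrix(0, 64, 64); outside[1, 1] <- 1   # cup pixel off-disc
  expect_error(render_fundus(ok$vessel, ok$disc * 0, outside, p),
               "contained")
})

test_that("dataset generation is byte-reproducible and samples vary", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_dataset(4, d1, phantom_params(image_size = 48), seed = 9)
  generate_dataset(4, d2, phantom_params(image_size = 48), seed = 9)
  expect_identical(dir_fingerprint(d1), dir_fingerprint(d2))
  expect_equal(nrow(m1), 4)
  ds <- load_paired_dataset(d1, "mcml")
  # independent vessel trees by default
  expect_false(identical(ds[[1]]$masks$vessel, ds[[2]]$masks$vessel))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("shared-vessel datasets fix the vessel tree while discs vary", {
  d <- tempfile()
  generate_dataset(3, d, phantom_params(image_size = 48),
                   shared_vessel = TRUE, seed = 2)
  ds <- load_paired_dataset(d, "mcml")
  expect_identical(ds[[1]]$masks$vessel, ds[[2]]$masks$vessel)
  expect_identical(ds[[2]]$masks$vessel, ds[[3]]$masks$vessel)
  expect_false(identical(ds[[1]]$masks$disc, ds[[2]]$masks$disc))
  unlink(d, recursive = TRUE)
})

test_that("generated samples satisfy the containment invariants", {
  for (seed in 1:3) {
    p <- phantom_params(image_size = 80, seed = seed)
    s <- generate_phantom(p)
    geo_r <- p$fundus_radius_frac * p$image_size / 2
    ctr <- (p$image_size - 1) / 2
    rr <- matrix(seq_len(80) - 1, 80, 80); cc <- t(rr)
    outside <- (rr - ctr)^2 + (cc - ctr)^2 > geo_r^2 * 1.001
    expect_true(all(s$cup <= s$disc))
    expect_true(all(s$vessel[outside] == 0))
    expect_true(all(s$disc[outside] == 0))
  }
})
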