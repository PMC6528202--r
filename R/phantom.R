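# Procedural fundus phantom: a dark branching vessel tree on a circular
# fundus field, a bright optic disc containing a brighter optic cup with a
# controllable cup-to-disc ratio, illumination falloff and pixel noise —
# with exact ground-truth masks for all three landmarks.

#' Parameters of the fundus phantom generator
#'
#' All geometry is in pixel units on a square `image_size` x `image_size`
#' canvas, row-major, 0-based `(row, col)` coordinates.  Identical parameter
#' sets (including `seed`) generate bit-identical samples.
#'
#' @param image_size Side length in pixels (>= 32).
#' @param fundus_radius_frac Radius of the circular fundus field as a
#'   fraction of half the image width, in (0, 1].
#' @param disc_center Optic-disc center `(row, col)` in pixels; the disc must
#'   lie fully inside the fundus circle.  Default: slightly temporal-superior
#'   of the image center.
#' @param disc_radius Optic-disc radius in pixels.
#' @param cdr Cup-to-disc radius ratio, strictly in (0, 1); the cup radius is
#'   `round(cdr * disc_radius)`, at least 1 px.
#' @param disc_axis_ratio Row/column axis ratio of disc and cup (1 = circles).
#' @param vessel_depth Maximum recursion depth of vessel branching (>= 1).
#' @param vessel_root_width Stroke width of the root vessel segments, pixels.
#' @param vessel_n_roots Number of root branches leaving the disc (>= 1).
#' @param branch_angle_jitter Random perturbation of branching angles, degrees.
#' @param width_decay Multiplicative stroke-width factor per branching level,
#'   in (0, 1).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise, in
#'   8-bit intensity units.
#' @param seed Non-negative integer seed; the sole source of randomness.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(image_size = 256L,
                           fundus_radius_frac = 0.95,
                           disc_center = NULL,
                           disc_radius = NULL,
                           cdr = 0.4,
                           disc_axis_ratio = 1,
                           vessel_depth = 6L,
                           vessel_root_width = NULL,
                           vessel_n_roots = 3L,
                           branch_angle_jitter = 12,
                           width_decay = 0.8,
                           noise_sigma = 5,
                           seed = 0L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stop("image_size must be an integer >= 32", call. = FALSE)
  if (fundus_radius_frac <= 0 || fundus_radius_frac > 1)
    stop("fundus_radius_frac must be in (0, 1]", call. = FALSE)
  if (is.null(disc_radius)) disc_radius <- round(0.12 * image_size)
  if (disc_radius < 1) stop("disc_radius must be positive", call. = FALSE)
  if (is.null(disc_center))
    disc_center <- c(0.45, 0.62) * image_size
  if (cdr <= 0 || cdr >= 1)
    stop("cdr must lie strictly in (0, 1)", call. = FALSE)
  if (width_decay <= 0 || width_decay >= 1)
    stop("width_decay must lie in (0, 1)", call. = FALSE)
  if (is.null(vessel_root_width)) vessel_root_width <- max(2, image_size / 85)
  if (vessel_root_width <= 0)
    stop("vessel_root_width must be positive", call. = FALSE)
  if (vessel_depth < 1L) stop("vessel_depth must be >= 1", call. = FALSE)
  if (vessel_n_roots < 1L) stop("vessel_n_roots must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  if (seed < 0) stop("seed must be non-negative", call. = FALSE)

  p <- structure(list(
    image_size = image_size,
    fundus_radius_frac = fundus_radius_frac,
    disc_center = as.numeric(disc_center),
    disc_radius = as.numeric(disc_radius),
    cdr = cdr,
    disc_axis_ratio = disc_axis_ratio,
    vessel_depth = as.integer(vessel_depth),
    vessel_root_width = as.numeric(vessel_root_width),
    vessel_n_roots = as.integer(vessel_n_roots),
    branch_angle_jitter = branch_angle_jitter,
    width_decay = width_decay,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "phantom_params")

  ctr <- (image_size - 1) / 2
  rf <- fundus_radius_frac * image_size / 2
  d <- sqrt(sum((p$disc_center - ctr)^2))
  if (d + disc_radius * max(1, disc_axis_ratio) > rf)
    stop("optic disc does not fit inside the fundus circle", call. = FALSE)
  p
}

fundus_geometry <- function(params) {
  ctr <- (params$image_size - 1) / 2
  list(center = c(ctr, ctr),
       radius = params$fundus_radius_frac * params$image_size / 2)
}

# Deterministic sub-seed derivation; keeps every derived seed < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

inside_circle_mask <- function(size, center, radius) {
  r <- matrix(seq_len(size) - 1, size, size)
  c <- t(r)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Stamp a thick line segment into a 0/1 matrix: pixels whose distance to the
# segment is at most width/2 (+ half-pixel raster allowance).
draw_segment <- function(mask, p0, p1, width) {
  size <- nrow(mask)
  hw <- width / 2 + 0.35
  r0 <- max(1, floor(min(p0[1], p1[1]) - hw) + 1)
  r1 <- min(size, ceiling(max(p0[1], p1[1]) + hw) + 1)
  c0 <- max(1, floor(min(p0[2], p1[2]) - hw) + 1)
  c1 <- min(size, ceiling(max(p0[2], p1[2]) + hw) + 1)
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- matrix((r0:r1) - 1, r1 - r0 + 1, c1 - c0 + 1)
  cc <- matrix((c0:c1) - 1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (rr - p0[1])^2 + (cc - p0[2])^2
  } else {
    t <- ((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (rr - (p0[1] + t * v[1]))^2 + (cc - (p0[2] + t * v[2]))^2
  }
  sub <- mask[r0:r1, c0:c1]
  sub[d2 <= hw^2] <- 1
  mask[r0:r1, c0:c1] <- sub
  mask
}

#' Generate the branching vessel-tree mask
#'
#' Grows a connected binary vessel tree: root trunks run from the optic-disc
#' center to `vessel_n_roots` points on the disc boundary, then branch
#' recursively outward with per-level angle jitter and stroke-width decay.
#' All strokes are clipped to the fundus circle.  The tree is a pure function
#' of `params` (including its seed).
#'
#' @param params A [phantom_params()] object.
#' @return Binary matrix (`image_size` square) with values 0/1.
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  size <- params$image_size
  geo <- fundus_geometry(params)
  mask <- matrix(0, size, size)

  with_seed(derive_seed(params$seed, "vessel"), {
    root_angles <- stats::runif(1, 0, 2 * pi) +
      seq(0, 2 * pi, length.out = params$vessel_n_roots + 1)[-(params$vessel_n_roots + 1)]
    base_len <- 0.14 * size
    jit <- params$branch_angle_jitter * pi / 180

    grow <- function(p0, angle, depth, width, len) {
      p1 <- p0 + len * c(sin(angle), cos(angle))
      mask <<- draw_segment(mask, p0, p1, width)
      if (depth >= params$vessel_depth) return(invisible())
      spread <- 24 * pi / 180 + jit * stats::runif(1, -1, 1)
      for (s in c(-1, 1)) {
        a <- angle + s * (spread + jit * stats::runif(1, -0.5, 0.5))
        l <- len * stats::runif(1, 0.85, 1.1)
        grow(p1, a, depth + 1, width * params$width_decay, l)
      }
      invisible()
    }

    for (a in root_angles) {
      boundary <- params$disc_center +
        params$disc_radius * c(sin(a), cos(a))
      if (params$vessel_n_roots > 1L)
        mask <- draw_segment(mask, params$disc_center, boundary,
                             params$vessel_root_width)
      jangle <- a + jit * stats::runif(1, -1, 1)
      grow(boundary, jangle, 1L, params$vessel_root_width,
           base_len * stats::runif(1, 0.9, 1.15))
    }
  })

  mask[!inside_circle_mask(size, geo$center, geo$radius)] <- 0
  mask
}

ellipse_mask <- function(size, center, radius, axis_ratio) {
  r <- matrix(seq_len(size) - 1, size, size)
  c <- t(r)
  ((r - center[1]) / (radius * axis_ratio))^2 +
    ((c - center[2]) / radius)^2 <= 1
}

#' Generate concentric optic-disc and optic-cup masks
#'
#' Filled concentric ellipses (circles by default) at `disc_center`:
#' the disc of `disc_radius` and the cup of `round(cdr * disc_radius)`
#' (at least 1 px).  The cup is contained in the disc by construction, so
#' the cup-to-disc ratio of the rasterized masks recovers `cdr`.
#'
#' @param params A [phantom_params()] object.
#' @return List with binary matrices `disc` and `cup`.
#' @export
generate_disc_cup <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  size <- params$image_size
  cup_radius <- max(1, round(params$cdr * params$disc_radius))
  disc <- ellipse_mask(size, params$disc_center, params$disc_radius,
                       params$disc_axis_ratio) * 1
  cup <- ellipse_mask(size, params$disc_center, cup_radius,
                      params$disc_axis_ratio) * 1
  cup <- cup * disc   # containment exact even at cdr -> 1
  list(disc = disc, cup = cup)
}

#' Estimate the cup-to-disc ratio from masks
#'
#' Equivalent-radius ratio: the square root of the cup/disc pixel-area ratio.
#'
#' @param disc,cup Binary disc and cup masks.
#' @return Scalar CDR estimate.
#' @export
estimate_cdr <- function(disc, cup) {
  a_d <- sum(disc > 0)
  if (a_d == 0) stop("empty disc mask", call. = FALSE)
  sqrt(sum(cup > 0) / a_d)
}

# Painted-layer colors (8-bit RGB).  Flat per-region values make the
# cup > disc rim > fundus field intensity ordering exact at zero noise.
phantom_palette <- function() {
  list(outside = c(8, 5, 5),
       base = c(196, 108, 58),
       disc = c(233, 188, 118),
       cup = c(251, 224, 158),
       vessel = c(108, 32, 30))
}

#' Render a pseudo-fundus RGB image from landmark masks
#'
#' Layered painting, in order: dark background outside the fundus circle; a
#' reddish-orange base field with a radial vignette; a brightened disc; a
#' further-brightened cup; dark-red vessel strokes on top (visible inside
#' the disc); finally additive Gaussian noise (sd `noise_sigma`) clipped to
#' \[0, 255\] and quantized to 8 bits.  Deterministic given `params$seed`.
#'
#' @param vessel,disc,cup Binary masks of identical dimension; `cup` must be
#'   contained in `disc`.
#' @param params A [phantom_params()] object.
#' @return Numeric array `H x W x 3` of 8-bit values in \[0, 255\].
#' @export
render_fundus <- function(vessel, disc, cup, params) {
  stopifnot(inherits(params, "phantom_params"))
  size <- params$image_size
  for (m in list(vessel, disc, cup)) {
    if (!all(dim(m) == c(size, size)))
      stop("mask dimensions do not match image_size", call. = FALSE)
    if (!all(m %in% c(0, 1)))
      stop("masks must be binary (values 0/1)", call. = FALSE)
  }
  if (any(cup > 0 & disc == 0))
    stop("cup mask must be contained in the disc mask", call. = FALSE)

  geo <- fundus_geometry(params)
  inside <- inside_circle_mask(size, geo$center, geo$radius)
  r <- matrix(seq_len(size) - 1, size, size)
  c <- t(r)
  dist2 <- (r - geo$center[1])^2 + (c - geo$center[2])^2
  vignette <- 1 - 0.40 * pmin(dist2 / geo$radius^2, 1)

  pal <- phantom_palette()
  img <- array(0, dim = c(size, size, 3))
  for (k in 1:3) {
    plane <- matrix(pal$outside[k], size, size)
    plane[inside] <- (pal$base[k] * vignette)[inside]
    plane[disc > 0] <- pal$disc[k]
    plane[cup > 0] <- pal$cup[k]
    plane[vessel > 0 & inside] <- pal$vessel[k]
    img[, , k] <- plane
  }

  if (params$noise_sigma > 0) {
    noise <- with_seed(derive_seed(params$seed, "noise"),
                       array(stats::rnorm(size * size * 3, 0,
                                          params$noise_sigma),
                             dim = c(size, size, 3)))
    img <- img + noise
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  round(img)
}

#' Generate one phantom sample
#'
#' Convenience wrapper producing the three landmark masks and the rendered
#' pseudo-fundus image for a single parameter set.
#'
#' @param params A [phantom_params()] object.
#' @return A `phantom_sample`: list with `vessel`, `disc`, `cup` binary masks,
#'   `fundus` RGB array and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  vessel <- generate_vessel_tree(params)
  dc <- generate_disc_cup(params)
  structure(list(vessel = vessel, disc = dc$disc, cup = dc$cup,
                 fundus = render_fundus(vessel, dc$disc, dc$cup, params),
                 params = params),
            class = "phantom_sample")
}

sample_params <- function(base, randomize, seed, index) {
  p <- unclass(base)
  geo <- fundus_geometry(base)
  with_seed(derive_seed(seed, "sample", index), {
    if (isTRUE(randomize$disc_radius))
      p$disc_radius <- base$disc_radius * stats::runif(1, 0.8, 1.2)
    if (isTRUE(randomize$cdr))
      p$cdr <- stats::runif(1, 0.30, 0.70)
    if (isTRUE(randomize$disc_center)) {
      repeat {
        cand <- geo$center +
          stats::runif(2, -0.35, 0.35) * base$image_size / 2
        if (sqrt(sum((cand - geo$center)^2)) +
            p$disc_radius * max(1, p$disc_axis_ratio) <= geo$radius) break
      }
      p$disc_center <- cand
    }
  })
  p$seed <- derive_seed(seed, "per-sample", index)
  do.call(phantom_params, p)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` samples in the standard dataset layout
#' (`masks/vessel|disc|cup/<id>.png`, `fundus/<id>.png`) plus a
#' `manifest.yaml` recording every per-sample parameter.  Fully reproducible
#' from `(base_params, randomize, shared_vessel, seed)`.
#'
#' With `shared_vessel = TRUE` every sample reuses the identical vessel tree
#' while disc/cup geometry still varies — the construction used to probe
#' whether vessel-only conditioning can carry disc information at all.
#'
#' @param n Number of samples (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param base_params A [phantom_params()]; per-sample seeds are derived from
#'   `seed`, not from `base_params$seed`.
#' @param randomize Named list of logical flags: which of `disc_center`,
#'   `disc_radius`, `cdr` vary per sample.
#' @param shared_vessel Reuse one vessel tree across all samples.
#' @param seed Dataset-level seed.
#' @return A tibble manifest (one row per sample), invisibly; also written as
#'   `manifest.yaml`.
#' @export
generate_dataset <- function(n, out_dir,
                             base_params = phantom_params(),
                             randomize = list(disc_center = TRUE,
                                              disc_radius = TRUE,
                                              cdr = TRUE),
                             shared_vessel = FALSE,
                             seed = 0L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  for (d in c("masks/vessel", "masks/disc", "masks/cup", "fundus"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  # A shared vessel tree is grown once from the *base* disc geometry so it
  # stays identical while per-sample disc/cup geometry varies.
  shared_v <- if (isTRUE(shared_vessel)) {
    pv <- unclass(base_params)
    pv$seed <- derive_seed(seed, "shared-vessel")
    generate_vessel_tree(do.call(phantom_params, pv))
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("phantom_%03d", i)
    p <- sample_params(base_params, randomize, seed, i)
    s <- if (is.null(shared_v)) generate_phantom(p) else {
      dc <- generate_disc_cup(p)
      list(vessel = shared_v, disc = dc$disc, cup = dc$cup,
           fundus = render_fundus(shared_v, dc$disc, dc$cup, p),
           params = p)
    }
    write_mask_png(s$vessel, file.path(out_dir, "masks/vessel",
                                       paste0(id, ".png")))
    write_mask_png(s$disc, file.path(out_dir, "masks/disc",
                                     paste0(id, ".png")))
    write_mask_png(s$cup, file.path(out_dir, "masks/cup",
                                    paste0(id, ".png")))
    write_image_png(s$fundus, file.path(out_dir, "fundus",
                                        paste0(id, ".png")))
    rows[[i]] <- tibble::tibble(
      id = id, seed = p$seed, image_size = p$image_size,
      disc_row = p$disc_center[1], disc_col = p$disc_center[2],
      disc_radius = p$disc_radius, cdr = p$cdr,
      vessel_depth = p$vessel_depth, noise_sigma = p$noise_sigma)
  }
  manifest <- dplyr::bind_rows(rows)
  yaml::write_yaml(list(
    generator = "mcmlfundus-phantom",
    version = as.character(utils::packageVersion("mcmlfundus")),
    dataset_seed = as.integer(seed),
    shared_vessel = isTRUE(shared_vessel),
    samples = lapply(seq_len(n), function(i) as.list(manifest[i, ]))),
    file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
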