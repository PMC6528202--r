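# Landmark-mask handling and the three conditioning encodings compared in
# this package: multi-channel landmarks (vessel/disc/cup in separate
# channels), one-channel disc+vessel fusion, and vessel-only.

MASK_ROLES <- c("vessel", "disc", "cup")

#' Create a landmark mask
#'
#' @param pixels Binary matrix (values 0/1, or logical).
#' @param role One of `"vessel"`, `"disc"`, `"cup"`.
#' @return A `landmark_mask` object.
#' @export
landmark_mask <- function(pixels, role = c("vessel", "disc", "cup")) {
  role <- match.arg(role)
  if (!is.matrix(pixels)) stop("mask pixels must be a matrix", call. = FALSE)
  pixels <- (pixels > 0) * 1
  structure(list(pixels = pixels, role = role), class = "landmark_mask")
}

mask_pixels <- function(m) {
  if (inherits(m, "landmark_mask")) m$pixels else (as.matrix(m) > 0) * 1
}

#' Threshold a grayscale image into a binary mask
#'
#' A pixel is foreground iff its intensity exceeds `threshold`.  Idempotent
#' on already-binary `{0, 255}` input at the default midpoint threshold.
#'
#' @param image Single-channel matrix with 8-bit intensities in \[0, 255\].
#' @param threshold Intensity threshold in \[0, 255\].
#' @return Binary matrix with values 0/1.
#' @export
binarize <- function(image, threshold = 127) {
  if (!is.null(dim(image)) && length(dim(image)) == 3L) {
    if (dim(image)[3] != 1L)
      stop("binarize expects a single-channel image", call. = FALSE)
    image <- image[, , 1]
  }
  if (!is.matrix(image))
    stop("binarize expects a single-channel image", call. = FALSE)
  if (threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255]", call. = FALSE)
  (image > threshold) * 1
}

check_same_dim <- function(...) {
  ms <- list(...)
  d <- dim(ms[[1]])
  for (m in ms[-1])
    if (!all(dim(m) == d))
      stop("mask dimensions differ", call. = FALSE)
  invisible(d)
}

#' Compose the multi-channel landmark conditioning input
#'
#' Stacks the vessel, disc and cup masks into a 3-channel image in the fixed
#' channel order (vessel, disc, cup).  Overlapping landmarks are preserved
#' independently per channel, so the composition is lossless: splitting the
#' channels recovers the input masks exactly.
#'
#' @param vessel,disc,cup [landmark_mask()] objects (or binary matrices) of
#'   identical dimension.  When `landmark_mask` objects are given their roles
#'   are checked.
#' @return An `mcml_input`: `H x W x 3` array in `{0, 1}` with a
#'   `channel_semantics` attribute.
#' @export
compose_mcml <- function(vessel, disc, cup) {
  for (pair in list(list(vessel, "vessel"), list(disc, "disc"),
                    list(cup, "cup")))
    if (inherits(pair[[1]], "landmark_mask") && pair[[1]]$role != pair[[2]])
      stop(sprintf("mask in %s position has role '%s'",
                   pair[[2]], pair[[1]]$role), call. = FALSE)
  v <- mask_pixels(vessel); d <- mask_pixels(disc); k <- mask_pixels(cup)
  dm <- check_same_dim(v, d, k)
  out <- array(0, dim = c(dm, 3L))
  out[, , 1] <- v; out[, , 2] <- d; out[, , 3] <- k
  attr(out, "channel_semantics") <- MASK_ROLES
  class(out) <- c("mcml_input", class(out))
  out
}

#' Split a multi-channel landmark input back into masks
#'
#' Exact inverse of [compose_mcml()].
#'
#' @param x An `mcml_input` (or any `H x W x 3` array in `{0, 1}`).
#' @return Named list of binary matrices `vessel`, `disc`, `cup`.
#' @export
mcml_channels <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  list(vessel = x[, , 1] + 0, disc = x[, , 2] + 0, cup = x[, , 3] + 0)
}

# Intensity levels of the one-channel fusion baseline (8-bit scale).
FUSED_DISC_LEVEL <- 128
FUSED_VESSEL_LEVEL <- 255

#' Fuse disc and vessel masks into one channel
#'
#' Baseline encoding: the disc is painted at intensity 128 and the vessel at
#' 255 on top of it.  A vessel pixel inside the disc is therefore
#' indistinguishable from a vessel pixel outside it — the encoding loses the
#' disc membership of vessel pixels by construction, which is exactly the
#' deficiency the multi-channel encoding removes.
#'
#' @param vessel,disc Masks of identical dimension.
#' @return Single-channel matrix with values in `{0, 128, 255}`.
#' @export
fuse_one_channel <- function(vessel, disc) {
  v <- mask_pixels(vessel); d <- mask_pixels(disc)
  check_same_dim(v, d)
  out <- d * FUSED_DISC_LEVEL
  out[v > 0] <- FUSED_VESSEL_LEVEL
  out
}

#' Vessel-only conditioning
#'
#' Pass-through of the vessel mask as the single-channel baseline encoding.
#'
#' @param vessel A vessel mask.
#' @return Binary matrix identical to the input mask.
#' @export
vessel_only <- function(vessel) {
  mask_pixels(vessel)
}

#' Map data to and from the model value convention
#'
#' Networks operate on values in \[-1, 1\]: binary masks map
#' `{0, 1} -> {-1, +1}`, 8-bit images `[0, 255] -> [-1, 1]` (and the fused
#' encoding, already on the 8-bit scale, maps like an image).
#' `denormalize_image()` inverts the image mapping back to quantized 8-bit.
#'
#' @param x Mask array in `{0, 1}` (`normalize_mask`), 8-bit image array
#'   (`normalize_image`), or model-scale array (`denormalize_image`).
#' @return Array of the same shape on the target scale.
#' @export
normalize_mask <- function(x) {
  y <- unclass(x) * 2 - 1
  attr(y, "channel_semantics") <- NULL
  y
}

#' @rdname normalize_mask
#' @export
normalize_image <- function(x) x / 127.5 - 1

#' @rdname normalize_mask
#' @export
denormalize_image <- function(x) {
  y <- (x + 1) * 127.5
  y[y < 0] <- 0
  y[y > 255] <- 255
  round(y)
}

#' Encode landmark masks for a given conditioning mode
#'
#' Produces the normalized model input for one sample under the selected
#' encoding: `"mcml"` (3 channels), `"fused_one_channel"` or `"vessel_only"`
#' (1 channel each).
#'
#' @param vessel,disc,cup Binary masks (cup/disc may be `NULL` for the
#'   single-channel encodings).
#' @param encoding Conditioning mode.
#' @return Model-scale array `H x W x C`, `C` matching the encoding.
#' @export
encode_conditioning <- function(vessel, disc = NULL, cup = NULL,
                                encoding = c("mcml", "fused_one_channel",
                                             "vessel_only")) {
  encoding <- match.arg(encoding)
  switch(encoding,
    mcml = normalize_mask(compose_mcml(vessel, disc, cup)),
    fused_one_channel = {
      f <- normalize_image(fuse_one_channel(vessel, disc))
      dim(f) <- c(dim(f), 1L); f
    },
    vessel_only = {
      v <- normalize_mask(vessel_only(vessel))
      dim(v) <- c(dim(v), 1L); v
    })
}

#' Channel count of a conditioning encoding
#'
#' @param encoding `"mcml"`, `"fused_one_channel"` or `"vessel_only"`.
#' @return 3 for the multi-channel encoding, 1 for the single-channel
#'   baselines.
#' @export
encoding_channels <- function(encoding) {
  if (encoding == "mcml") 3L else 1L
}

# --- resampling ------------------------------------------------------------

resample_matrix_1d <- function(n_src, n_dst, method) {
  scale <- n_src / n_dst
  centers <- (seq_len(n_dst) - 0.5) * scale - 0.5   # 0-based source coords
  W <- matrix(0, n_dst, n_src)
  if (method == "nearest") {
    idx <- pmin(pmax(floor(centers + 0.5), 0), n_src - 1)
    W[cbind(seq_len(n_dst), idx + 1)] <- 1
  } else {
    cubic <- function(t) {         # Keys kernel, a = -0.5
      t <- abs(t)
      ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
             ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
    }
    for (i in seq_len(n_dst)) {
      base <- floor(centers[i])
      taps <- (base - 1):(base + 2)
      w <- cubic(centers[i] - taps)
      taps <- pmin(pmax(taps, 0), n_src - 1)        # clamp at edges
      for (j in seq_along(taps))
        W[i, taps[j] + 1] <- W[i, taps[j] + 1] + w[j]
    }
  }
  W
}

#' Resize an image or mask
#'
#' Direct resampling to the target size (no padding, no aspect preservation).
#' Masks should use `"nearest"` (output stays two-valued); photographs use
#' `"bicubic"` (Keys kernel, a = -0.5, edge-clamped).
#'
#' @param x Matrix or `H x W x C` array.
#' @param target Target size `(H, W)` (a single integer is used for both).
#' @param method `"nearest"` or `"bicubic"`.
#' @return Resized matrix or array.
#' @export
resize_image <- function(x, target, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  if (length(target) == 1L) target <- c(target, target)
  if (any(target < 1)) stop("target size must be positive", call. = FALSE)
  was_matrix <- is.matrix(x)
  x <- as_hwc(x)
  d <- dim(x)
  if (all(d[1:2] == target)) {
    out <- x
  } else {
    Wr <- resample_matrix_1d(d[1], target[1], method)
    Wc <- resample_matrix_1d(d[2], target[2], method)
    out <- array(0, dim = c(target, d[3]))
    for (k in seq_len(d[3]))
      out[, , k] <- Wr %*% x[, , k] %*% t(Wc)
  }
  if (was_matrix) out[, , 1] else out
}

#' Resize a (photograph, mask) pair consistently
#'
#' The photograph is resampled bicubically, the mask with nearest-neighbour
#' so it stays binary.
#'
#' @param image 8-bit image array.
#' @param mask Binary mask matrix.
#' @param target Target `(H, W)`.
#' @return List with resized `image` and `mask`.
#' @export
resize_pair <- function(image, mask, target) {
  list(image = resize_image(image, target, "bicubic"),
       mask = resize_image(mask, target, "nearest"))
}
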