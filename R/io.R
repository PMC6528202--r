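# PNG reading/writing on the 8-bit integer scale used throughout the
# package.  Round trips are bit-exact for 8-bit data.

#' Read an 8-bit image from PNG
#'
#' Returns intensities on the integer \[0, 255\] scale.  Inputs with higher
#' bit depth are rescaled to 8 bits with a warning.
#'
#' @param path PNG file path.
#' @return Matrix (grayscale) or `H x W x C` array.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  v <- x * 255
  if (max(abs(v - round(v))) > 1e-6) {
    warning("non-8-bit PNG rescaled to 8-bit: ", path, call. = FALSE)
  }
  round(v)
}

#' Write an 8-bit image to PNG
#'
#' @param img Matrix or `H x W x 3` array with values in \[0, 255\].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (min(img) < 0 || max(img) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  png::writePNG(round(img) / 255, path)
  invisible(path)
}

#' Read a binary landmark mask from PNG
#'
#' Accepts single-channel `{0, 255}` masks (any grayscale input is
#' thresholded at the 8-bit midpoint).
#'
#' @param path PNG file path.
#' @return Binary matrix with values 0/1.
#' @export
read_mask_png <- function(path) {
  x <- read_image_png(path)
  if (length(dim(x)) == 3L) {
    if (stats::sd(x) > 0 && !all(x[, , 1] == x[, , 2] & x[, , 1] == x[, , 3]))
      warning("multi-channel mask collapsed to first channel: ", path,
              call. = FALSE)
    x <- x[, , 1]
  }
  binarize(x, 127)
}

#' Write a binary mask to PNG as `{0, 255}`
#'
#' @param mask Binary matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  write_image_png(mask_pixels(mask) * 255, path)
}

#' Load a paired phantom-layout dataset
#'
#' Reads the standard layout (`masks/vessel|disc|cup/<id>.png`,
#' `fundus/<id>.png`) and returns model-ready pairs: the conditioning input
#' under the requested encoding and the normalized target image.
#'
#' @param root Dataset root directory.
#' @param encoding Conditioning mode passed to [encode_conditioning()].
#' @param size Optional target size; images are resized bicubically and
#'   masks with nearest-neighbour when it differs from the stored size.
#' @return List of samples, each `list(id, cond, real, masks)` with `cond`
#'   and `real` on the model \[-1, 1\] scale.
#' @export
load_paired_dataset <- function(root,
                                encoding = c("mcml", "fused_one_channel",
                                             "vessel_only"),
                                size = NULL) {
  encoding <- match.arg(encoding)
  vdir <- file.path(root, "masks", "vessel")
  if (!dir.exists(vdir))
    stop("not a phantom-layout dataset (missing masks/vessel): ", root,
         call. = FALSE)
  ids <- sort(sub("\\.png$", "", list.files(vdir, pattern = "\\.png$")))
  if (length(ids) == 0) stop("no mask images found under ", vdir, call. = FALSE)
  lapply(ids, function(id) {
    vessel <- read_mask_png(file.path(root, "masks/vessel", paste0(id, ".png")))
    disc <- read_mask_png(file.path(root, "masks/disc", paste0(id, ".png")))
    cup <- read_mask_png(file.path(root, "masks/cup", paste0(id, ".png")))
    fundus <- read_image_png(file.path(root, "fundus", paste0(id, ".png")))
    if (!is.null(size) && !all(dim(vessel) == size)) {
      vessel <- resize_image(vessel, size, "nearest")
      disc <- resize_image(disc, size, "nearest")
      cup <- resize_image(cup, size, "nearest")
      fundus <- resize_image(fundus, size, "bicubic")
      fundus[fundus < 0] <- 0; fundus[fundus > 255] <- 255
    }
    list(id = id,
         cond = encode_conditioning(vessel, disc, cup, encoding),
         real = normalize_image(fundus),
         masks = list(vessel = vessel, disc = disc, cup = cup))
  })
}
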