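# Image-quality metrics: peak signal-to-noise ratio and the structural
# similarity index, plus the paired-directory evaluation protocol and a
# region-restricted SSIM for disc/cup ROIs.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` with the mean squared error pooled over
#' all pixels and channels.  Identical images return `Inf` (a documented
#' sentinel, not a capped value).
#'
#' @param reference,test Images of identical shape, 8-bit scale by default.
#' @param data_range Maximum possible intensity (255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = 255) {
  if (!identical(dim(as_hwc(reference)), dim(as_hwc(test))))
    stop("psnr: image shapes differ", call. = FALSE)
  if (data_range <= 0) stop("data_range must be positive", call. = FALSE)
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_weights <- function(window, sigma) {
  half <- (window - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-mode separable windowed means: row/column band matrices applied as
# A_r %*% X %*% t(A_c); output is (H - w + 1) x (W - w + 1).
window_filter <- function(x, g) {
  w <- length(g)
  H <- nrow(x); W <- ncol(x)
  Ar <- matrix(0, H - w + 1, H)
  for (i in seq_len(H - w + 1)) Ar[i, i:(i + w - 1)] <- g
  Ac <- matrix(0, W - w + 1, W)
  for (i in seq_len(W - w + 1)) Ac[i, i:(i + w - 1)] <- g
  Ar %*% x %*% t(Ac)
}

ssim_map_channel <- function(ref, test, window, sigma, k1, k2, data_range) {
  g <- gaussian_weights(window, sigma)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu_x <- window_filter(ref, g)
  mu_y <- window_filter(test, g)
  sxx <- window_filter(ref^2, g) - mu_x^2
  syy <- window_filter(test^2, g) - mu_y^2
  sxy <- window_filter(ref * test, g) - mu_x * mu_y
  ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
}

#' Structural similarity index
#'
#' Mean over sliding Gaussian windows of the standard
#' luminance-contrast-structure product with stabilizers
#' `C1 = (k1 * data_range)^2`, `C2 = (k2 * data_range)^2`.  Only windows
#' fully inside the image contribute.  Multichannel images are scored per
#' channel and averaged (set `grayscale = TRUE` to score the luminance mean
#' instead).  The result lies in \[-1, 1\]; 1 means identical structure.
#'
#' @param reference,test Images of identical shape.
#' @param window Odd window side length, at most `min(H, W)`.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param k1,k2 Stabilizer constants.
#' @param data_range Maximum possible intensity.
#' @param grayscale Average channels before scoring.
#' @return Scalar SSIM.
#' @export
ssim <- function(reference, test, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, data_range = 255,
                 grayscale = FALSE) {
  ref <- as_hwc(reference); tst <- as_hwc(test)
  if (!identical(dim(ref), dim(tst)))
    stop("ssim: image shapes differ", call. = FALSE)
  if (window %% 2 == 0) stop("ssim window must be odd", call. = FALSE)
  if (window > min(dim(ref)[1:2]))
    stop("ssim window larger than image", call. = FALSE)
  if (grayscale && dim(ref)[3] > 1L) {
    ref <- array(apply(ref, 1:2, mean), dim = c(dim(ref)[1:2], 1L))
    tst <- array(apply(tst, 1:2, mean), dim = c(dim(tst)[1:2], 1L))
  }
  vals <- vapply(seq_len(dim(ref)[3]), function(k)
    mean(ssim_map_channel(ref[, , k], tst[, , k], window, sigma, k1, k2,
                          data_range)), numeric(1))
  mean(vals)
}

#' Region-restricted SSIM
#'
#' SSIM over the bounding box of a binary region of interest, with each
#' window weighted by the ROI value at its center pixel.  For a filled
#' rectangular ROI this equals the plain SSIM of the cropped rectangles.
#'
#' @param reference,test Images of identical shape.
#' @param roi Binary mask of the same height and width; its bounding box
#'   must be at least `window` pixels in each direction.
#' @inheritParams ssim
#' @return Scalar SSIM over the region.
#' @export
regional_ssim <- function(reference, test, roi, window = 11L, sigma = 1.5,
                          k1 = 0.01, k2 = 0.03, data_range = 255) {
  ref <- as_hwc(reference); tst <- as_hwc(test)
  roi <- mask_pixels(roi)
  if (!all(dim(roi) == dim(ref)[1:2]))
    stop("roi dimensions differ from image", call. = FALSE)
  idx <- which(roi > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("roi is empty", call. = FALSE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  if (r1 - r0 + 1 < window || c1 - c0 + 1 < window)
    stop("roi bounding box smaller than the ssim window", call. = FALSE)
  half <- (window - 1) / 2
  wts <- roi[(r0 + half):(r1 - half), (c0 + half):(c1 - half), drop = FALSE]
  if (sum(wts) == 0)
    stop("roi contains no window-center pixels", call. = FALSE)
  vals <- vapply(seq_len(dim(ref)[3]), function(k) {
    m <- ssim_map_channel(ref[r0:r1, c0:c1, k], tst[r0:r1, c0:c1, k],
                          window, sigma, k1, k2, data_range)
    sum(m * wts) / sum(wts)
  }, numeric(1))
  mean(vals)
}

#' Evaluate paired directories of generated and reference images
#'
#' Matches images by filename, scores each pair with SSIM and PSNR, and
#' returns a `metric_report`.  Generated images whose size differs from the
#' reference are bicubically resampled to the reference size when
#' `resize_to_reference = TRUE`.  Pairs with infinite PSNR (bit-identical
#' images) are excluded from the PSNR mean with a warning.
#'
#' @param generated_dir,reference_dir Directories of identically named PNGs.
#' @param resize_to_reference Resample generated images to reference size.
#' @param csv Optional path for the per-image CSV report.
#' @inheritParams ssim
#' @return A `metric_report`: list with `per_image` tibble, `mean_ssim`,
#'   `mean_psnr`, `n_pairs` and the metric `settings`.
#' @export
evaluate_pairs <- function(generated_dir, reference_dir,
                           resize_to_reference = TRUE, csv = NULL,
                           window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                           data_range = 255, grayscale = FALSE) {
  gfiles <- sort(list.files(generated_dir, pattern = "\\.png$"))
  rfiles <- sort(list.files(reference_dir, pattern = "\\.png$"))
  common <- intersect(gfiles, rfiles)
  orphans <- c(setdiff(gfiles, rfiles), setdiff(rfiles, gfiles))
  if (length(common) == 0)
    stop("no identically named image pairs between the two directories",
         call. = FALSE)
  if (length(orphans) > 0)
    stop("unmatched images: ", paste(orphans, collapse = ", "),
         call. = FALSE)

  rows <- purrr::map(common, function(f) {
    gen <- read_image_png(file.path(generated_dir, f))
    ref <- read_image_png(file.path(reference_dir, f))
    if (!identical(dim(as_hwc(gen))[1:2], dim(as_hwc(ref))[1:2])) {
      if (!resize_to_reference)
        stop("size mismatch for ", f, " (set resize_to_reference)",
             call. = FALSE)
      gen <- resize_image(gen, dim(as_hwc(ref))[1:2], "bicubic")
      gen[gen < 0] <- 0; gen[gen > 255] <- 255
    }
    tibble::tibble(id = sub("\\.png$", "", f),
                   ssim = ssim(ref, gen, window, sigma, k1, k2, data_range,
                               grayscale),
                   psnr = psnr(ref, gen, data_range))
  })
  per_image <- dplyr::bind_rows(rows)
  finite_psnr <- per_image$psnr[is.finite(per_image$psnr)]
  if (length(finite_psnr) < nrow(per_image))
    warning("identical image pairs excluded from the PSNR mean",
            call. = FALSE)
  report <- structure(list(
    per_image = per_image,
    mean_ssim = mean(per_image$ssim),
    mean_psnr = if (length(finite_psnr)) mean(finite_psnr) else Inf,
    n_pairs = nrow(per_image),
    settings = list(window = window, sigma = sigma, k1 = k1, k2 = k2,
                    data_range = data_range, grayscale = grayscale)),
    class = "metric_report")
  if (!is.null(csv))
    utils::write.csv(per_image, csv, row.names = FALSE)
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d image pair(s)\n", x$n_pairs))
  cat(sprintf("  mean SSIM %.4f | mean PSNR %.4f dB\n",
              x$mean_ssim, x$mean_psnr))
  invisible(x)
}
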