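# Independent reference implementations used to cross-check the package's
# metrics and losses.  Deliberately written as direct loops over the
# definitions, sharing no code with the implementation under test.

oracle_psnr <- function(ref, test, data_range = 255) {
  err <- as.numeric(ref) - as.numeric(test)
  mse <- sum(err^2) / length(err)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

oracle_gaussian_window <- function(size = 11, sigma = 1.5) {
  half <- (size - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- outer(g1, g1)
  w / sum(w)
}

# Per-window SSIM by explicit iteration over every valid window position.
oracle_ssim_gray <- function(ref, test, window = 11, sigma = 1.5,
                             k1 = 0.01, k2 = 0.03, data_range = 255) {
  w <- oracle_gaussian_window(window, sigma)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  H <- nrow(ref); W <- ncol(ref)
  vals <- c()
  for (i in seq_len(H - window + 1)) {
    for (j in seq_len(W - window + 1)) {
      x <- ref[i:(i + window - 1), j:(j + window - 1)]
      y <- test[i:(i + window - 1), j:(j + window - 1)]
      mux <- sum(w * x); muy <- sum(w * y)
      sxx <- sum(w * x^2) - mux^2
      syy <- sum(w * y^2) - muy^2
      sxy <- sum(w * x * y) - mux * muy
      vals <- c(vals, ((2 * mux * muy + c1) * (2 * sxy + c2)) /
                        ((mux^2 + muy^2 + c1) * (sxx + syy + c2)))
    }
  }
  mean(vals)
}

oracle_ssim <- function(ref, test, ...) {
  if (length(dim(ref)) == 3) {
    mean(sapply(seq_len(dim(ref)[3]), function(k)
      oracle_ssim_gray(ref[, , k], test[, , k], ...)))
  } else {
    oracle_ssim_gray(ref, test, ...)
  }
}

# 8-connected component count of a binary matrix (BFS flood fill).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  comp <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      idx <- queue[1]; queue <- queue[-1]
      r <- (idx - 1) %% nrow(mask) + 1
      c <- (idx - 1) %/% nrow(mask) + 1
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb$dr[k]; cc <- c + nb$dc[k]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] > 0 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- comp
          queue <- c(queue, (cc - 1) * nrow(mask) + rr)
        }
      }
    }
  }
  comp
}

random_image <- function(h, w, ch = NULL, max = 255) {
  if (is.null(ch)) matrix(runif(h * w, 0, max), h, w)
  else array(runif(h * w * ch, 0, max), dim = c(h, w, ch))
}

# md5 fingerprint of a directory tree (relative paths + file contents).
dir_fingerprint <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  hashes <- vapply(file.path(root, files), function(f)
    unname(tools::md5sum(f)), character(1))
  paste(files, hashes, collapse = ";")
}

tiny_dataset <- function(n = 2, size = 32, seed = 1, dir = tempfile(), ...) {
  generate_dataset(n, dir, phantom_params(image_size = size), seed = seed, ...)
  dir
}

small_train_config <- function(encoding = "mcml", family = "resunet",
                               epochs = 2, size = 32, seed = 0,
                               base_width = 4, ...) {
  train_config(mode = "pix2pix", input_encoding = encoding,
               generator = generator_spec(
                 family, in_channels = encoding_channels(encoding),
                 base_width = base_width, n_res_blocks = 1),
               epochs = epochs, image_size = size, seed = seed,
               disc_base_width = 4, ...)
}
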