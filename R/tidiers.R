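#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the loss history of a training run
#'
#' @param x An `mcml_train_result`.
#' @param ... Unused.
#' @return The per-iteration loss history as a tibble (one row per
#'   iteration: `iteration`, `epoch`, `adv_g`, `adv_d`, `l1`, `cycle`,
#'   `total_g`, `total_d`).
#' @method tidy mcml_train_result
#' @export
tidy.mcml_train_result <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x An `mcml_train_result`.
#' @param ... Unused.
#' @return One-row tibble with the final-epoch mean losses, epoch/iteration
#'   counts, parameter counts and wall time.
#' @method glance mcml_train_result
#' @export
glance.mcml_train_result <- function(x, ...) {
  g <- x$generator %||% x$generator_ab
  dplyr::bind_cols(
    tibble::tibble(mode = x$config$mode,
                   encoding = x$config$input_encoding,
                   generator = x$config$generator$family,
                   epochs = x$config$epochs,
                   iterations = nrow(x$history),
                   n_parameters = count_parameters(g),
                   wall_time_s = x$wall_time),
    x$final_losses)
}

#' @export
print.mcml_train_result <- function(x, ...) {
  cat(sprintf("<%s training run: %s generator, %s encoding>\n",
              x$config$mode, x$config$generator$family,
              x$config$input_encoding))
  cat(sprintf("  %d epochs, %d iterations\n",
              x$config$epochs, nrow(x$history)))
  fl <- x$final_losses
  if (is.finite(fl$l1))
    cat(sprintf("  final-epoch mean L1 %.4f, adv_g %.4f, adv_d %.4f\n",
                fl$l1, fl$adv_g, fl$adv_d))
  if (is.finite(fl$cycle))
    cat(sprintf("  final-epoch mean cycle %.4f\n", fl$cycle))
  invisible(x)
}

#' Loss curves of a training run
#'
#' Per-epoch mean of each logged loss component, on a free y scale per
#' component.
#'
#' @param object An `mcml_train_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcml_train_result
#' @export
autoplot.mcml_train_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("adv_g", "adv_d", "l1", "cycle"),
                              names_to = "component", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  epoch_means <- dplyr::summarise(
    dplyr::group_by(long, .data$epoch, .data$component),
    value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(epoch_means,
                  ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "mean loss (nats / L1 units)",
                  title = "Training loss components") +
    ggplot2::theme_minimal()
}

#' Tidy a metric report
#'
#' @param x A `metric_report` from [evaluate_pairs()].
#' @param ... Unused.
#' @return The per-image tibble (`id`, `ssim`, `psnr`).
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_image

#' One-row summary of a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return One-row tibble with `mean_ssim`, `mean_psnr`, `n_pairs`.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(mean_ssim = x$mean_ssim, mean_psnr = x$mean_psnr,
                 n_pairs = x$n_pairs)
}

#' Per-image metric plot
#'
#' SSIM and PSNR per image pair, with the report means as reference lines.
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image, c("ssim", "psnr"),
                              names_to = "metric", values_to = "value")
  means <- tibble::tibble(metric = c("ssim", "psnr"),
                          value = c(object$mean_ssim, object$mean_psnr))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-image SSIM and PSNR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Display a phantom sample
#'
#' Shows the rendered pseudo-fundus image next to the three ground-truth
#' landmark masks.
#'
#' @param object A `phantom_sample` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom_sample
#' @export
autoplot.phantom_sample <- function(object, ...) {
  to_df <- function(m, panel) {
    d <- dim(m)[1:2]
    tibble::tibble(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   value = as.numeric(if (length(dim(m)) == 3)
                     (m[, , 1] * 0.3 + m[, , 2] * 0.59 + m[, , 3] * 0.11) / 255
                     else m),
                   panel = panel)
  }
  df <- dplyr::bind_rows(to_df(object$fundus, "fundus (luma)"),
                         to_df(object$vessel, "vessel"),
                         to_df(object$disc, "disc"),
                         to_df(object$cup, "cup"))
  df$panel <- factor(df$panel,
                     levels = c("fundus (luma)", "vessel", "disc", "cup"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
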