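# ---------------------------------------------------------------------------
# broom-style tidiers and ggplot2 autoplot methods for the result objects.
# ---------------------------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x a `daunet_fit`.
#' @param ... unused.
#' @return the per-epoch log as a tibble (`epoch`, `loss`, `val_dice`,
#'   `lr`, `steps`).
#' @exportS3Method generics::tidy
tidy.daunet_fit <- function(x, ...) x$log

#' One-row summary of a training run
#'
#' @param x a `daunet_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.daunet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), steps = x$steps,
                 best_dice = x$best_dice, best_epoch = x$best_epoch,
                 final_loss = x$log$loss[nrow(x$log)],
                 final_lr = x$log$lr[nrow(x$log)],
                 parameters = count_parameters(x$final_network))
}

#' Tidy a metrics report
#'
#' @param x a `daunet_metrics`.
#' @param ... unused.
#' @return the per-case tibble.
#' @exportS3Method generics::tidy
tidy.daunet_metrics <- function(x, ...) x$cases

#' Aggregate rows of a metrics report
#'
#' @param x a `daunet_metrics`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.daunet_metrics <- function(x, ...) x$summary

#' Plot the training trajectory
#'
#' Loss and monitored Dice per epoch, with the learning-rate decays
#' visible as vertical guides.
#'
#' @param object a `daunet_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.daunet_fit <- function(object, ...) {
  log <- object$log
  df <- rbind(
    data.frame(epoch = log$epoch, value = log$loss, quantity = "training loss"),
    data.frame(epoch = log$epoch, value = log$val_dice,
               quantity = "monitored Dice"))
  decays <- log$epoch[c(FALSE, diff(log$lr) < 0)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
  if (length(decays) > 0)
    p <- p + ggplot2::geom_vline(xintercept = decays, linetype = "dotted")
  p
}

#' Plot per-case segmentation scores
#'
#' @param object a `daunet_metrics`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.daunet_metrics <- function(object, ...) {
  cs <- object$cases
  long <- rbind(
    data.frame(case = cs$case, score = cs$dice, metric = "dice"),
    data.frame(case = cs$case, score = cs$sensitivity, metric = "sensitivity"),
    data.frame(case = cs$case, score = cs$specificity, metric = "specificity"),
    data.frame(case = cs$case, score = cs$precision, metric = "precision"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case, y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "score")
}

#' Plot a central slice of a volume, optionally with a mask overlay
#'
#' @param object an `mra_volume`.
#' @param mask optional `label_mask` whose foreground contour is overlaid.
#' @param slice depth index (default: middle slice).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @importFrom rlang .data
autoplot.mra_volume <- function(object, mask = NULL, slice = NULL, ...) {
  d <- dim(object$data)
  if (is.null(slice)) slice <- d[1] %/% 2L
  sl <- object$data[slice, , ]
  df <- expand.grid(h = seq_len(d[2]), w = seq_len(d[3]))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$h,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("depth slice ", slice))
  if (!is.null(mask)) {
    ms <- .vol_data(mask)[slice, , ]
    if (any(ms == 1)) {
      mdf <- df
      mdf$m <- as.vector(ms)
      p <- p + ggplot2::geom_tile(data = mdf[mdf$m == 1, ],
                                  fill = "red", alpha = 0.4)
    }
  }
  p
}
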