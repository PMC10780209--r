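#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted risk model
#'
#' @param x A `grud_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_auroc`.
#' @export
tidy.grud_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted risk model
#'
#' @param x A `grud_fit`.
#' @param ... Unused.
#' @return Tibble with model variant, dimensions, parameter count,
#'   epochs run, best epoch and its model-selection AUROC, loss settings
#'   and seed.
#' @export
glance.grud_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, D = x$D, H = x$H,
    n_parameters = length(x$theta),
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_auroc = x$best_val_auroc,
    lambda = x$lambda, w_pos = x$w_pos, seed = x$config$seed
  )
}

#' Tidy a horizon evaluation report
#'
#' @param x An `icu_eval` tibble.
#' @param ... Unused.
#' @return Long tibble (`horizon`, `metric`, `value`, `n_pos`, `n_neg`).
#' @export
tidy.icu_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), c("auroc", "auprc"),
                      names_to = "metric", values_to = "value") |>
    dplyr::select("horizon", "metric", "value", "n_pos", "n_neg")
}

#' Plot training curves of a fitted risk model
#'
#' @param object A `grud_fit`.
#' @param ... Unused.
#' @return A ggplot: training loss and model-selection AUROC per epoch.
#' @export
autoplot.grud_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste0("training history (", object$variant, ")"))
}

#' Plot AUROC/AUPRC against the prediction horizon
#'
#' @param object An `icu_eval` report (or several row-bound together, with
#'   an extra `model` column for comparison).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icu_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object), c("auroc", "auprc"),
                           names_to = "metric", values_to = "value")
  aes <- if ("model" %in% names(d)) {
    ggplot2::aes(.data$horizon, .data$value, colour = .data$model)
  } else {
    ggplot2::aes(.data$horizon, .data$value)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = unique(d$horizon)) +
    ggplot2::labs(x = "in-advance horizon (h)", y = NULL,
                  title = "discrimination by prediction horizon")
}

#' Plot a variable-importance ranking
#'
#' @param importance Tibble from [rank_variables()].
#' @return A ggplot bar chart, most important variable on top.
#' @export
plot_importance <- function(importance) {
  d <- dplyr::mutate(importance,
                     variable = stats::reorder(.data$variable,
                                               .data$importance))
  ggplot2::ggplot(d, ggplot2::aes(.data$importance, .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Shapley importance (pooled AUROC)", y = NULL,
                  title = "top influential variables")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
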