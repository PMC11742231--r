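# broom-style accessors and ggplot2 methods for fitted models and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted drug-response model
#'
#' Returns the per-epoch training history as a tibble (epoch, train loss,
#' validation loss, validation PCC/RMSE, running best validation loss).
#'
#' @param x A `gf_fit`.
#' @param ... Unused.
#' @export
tidy.gf_fit <- function(x, ...) x$history

#' One-row summary of a fitted drug-response model
#'
#' @param x A `gf_fit`.
#' @param ... Unused.
#' @return Tibble with variant, layer count, epochs trained, best epoch,
#'   best validation loss and RMSE, validation PCC at the best epoch, and
#'   the parameter count.
#' @export
glance.gf_fit <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    variant = x$config$variant,
    n_layers = x$config$n_layers,
    epochs_trained = x$epochs_trained,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_rmse = sqrt(x$best_val_loss),
    val_pcc = if (nrow(best)) best$val_pcc else NA_real_,
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}

#' Plot training curves of a fitted model
#'
#' Train and validation loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param object A `gf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(train_loss = "#1b9e77", val_loss = "#d95f02"),
      labels = c(train_loss = "train", val_loss = "validation")
    ) +
    ggplot2::labs(x = "epoch", y = "MSE loss", colour = NULL,
                  title = "Training history",
                  subtitle = paste0("variant: ", object$config$variant,
                                    "; best epoch ", object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot predicted against observed responses
#'
#' Scatter of predicted versus true normalized IC50 for the pairs behind an
#' evaluation report, with the identity line and the report's PCC/RMSE in
#' the subtitle.
#'
#' @param object A `gf_report` from [gf_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_report <- function(object, ...) {
  preds <- attr(object, "predictions")
  ggplot2::ggplot(preds, ggplot2::aes(x = .data$y, y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "observed normalized IC50", y = "predicted",
      title = "Predicted vs observed drug response",
      subtitle = sprintf("PCC %.3f, RMSE %.4f, n = %d",
                         object$pcc, object$rmse, object$n)
    ) +
    ggplot2::theme_minimal()
}
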