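# broom-style tidiers for result objects.

#' Tidy a metrics report (per-class rows)
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
tidy.metrics_report <- function(x, ...) {
  attr(x, "per_class")
}

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with the five overall metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a training run (per-epoch rows)
#'
#' @param x A `kct_fit` from [train_classifier()].
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.kct_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a training run
#'
#' @param x A `kct_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs, best epoch, best validation accuracy,
#'   final training loss, parameter count.
#' @export
glance.kct_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_acc = x$best_val_acc,
                 final_loss = x$history$loss[nrow(x$history)],
                 n_params = count_params(x$model))
}

#' Tidy a robustness table
#'
#' @param x A `robustness_table`.
#' @param ... Unused.
#' @return Long-format tibble with columns `sigma`, `metric`, `value`.
#' @export
tidy.robustness_table <- function(x, ...) {
  metrics <- setdiff(names(x), "sigma")
  out <- lapply(metrics, function(m) {
    tibble::tibble(sigma = x$sigma, metric = m, value = x[[m]])
  })
  do.call(rbind, out)
}
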