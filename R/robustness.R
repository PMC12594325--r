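# Noise-robustness sweep: evaluate a fixed model on Gaussian-corrupted
# copies of the test set across a list of noise levels, reporting each
# metric plus the decline statistic decline(sigma) = AUC(sigma) - AUC(0).

#' Noise-robustness sweep
#'
#' For each `sigma` the test images are corrupted with seeded additive
#' Gaussian noise ([add_noise()]) and the fixed model is re-evaluated. The
#' decline column is the AUC difference relative to the clean row; it is
#' exactly 0 at `sigma = 0`.
#'
#' @param model A trained `kct_model` (or anything `predict_fn` accepts).
#' @param images H x W x n test image array in `[0, 1]`.
#' @param labels Test labels.
#' @param sigma_list Noise standard deviations; must contain 0.
#' @param seed Seed; each sigma derives its own noise stream.
#' @param predict_fn Prediction function, defaulting to
#'   [predict_classifier()].
#' @return A `robustness_table`: tibble with columns `sigma`, `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`, `decline`.
#' @export
robustness_sweep <- function(model, images, labels,
                             sigma_list = c(0, 0.01, 0.05, 0.1), seed = 1,
                             predict_fn = predict_classifier) {
  if (!any(sigma_list == 0)) stop_input("sigma_list must contain 0")
  sigma_list <- sort(sigma_list)
  rows <- lapply(seq_along(sigma_list), function(i) {
    sg <- sigma_list[i]
    noisy <- if (sg == 0) images else
      add_noise(images, sg, derive_seed(seed, "noise", i))
    rep <- evaluate_model(model, noisy, labels, predict_fn = predict_fn)
    tibble::tibble(sigma = sg, accuracy = rep$accuracy,
                   precision = rep$precision, recall = rep$recall,
                   f1 = rep$f1, auc = rep$auc)
  })
  tab <- do.call(rbind, rows)
  tab$decline <- decline_from_auc(tab$auc, tab$sigma)
  structure(tab, class = c("robustness_table", class(tab)))
}

#' Decline statistic from an AUC column
#'
#' `decline(sigma) = AUC(sigma) - AUC(0)`; by construction the clean row's
#' decline is exactly 0 and degraded rows are negative.
#'
#' @param auc Numeric AUC values.
#' @param sigma Matching noise levels; one must be 0.
#' @return Numeric decline values.
#' @export
decline_from_auc <- function(auc, sigma) {
  i0 <- which(sigma == 0)
  if (length(i0) != 1) stop_input("exactly one sigma must be 0")
  auc - auc[i0]
}
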