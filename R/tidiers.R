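#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model's loss history
#'
#' @param x A trained `mgo_deepmgo`.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `set` (train/validation), `loss`.
#' @export
tidy.mgo_deepmgo <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "set",
                        values_to = "loss") |>
    dplyr::mutate(set = dplyr::recode(.data$set, train_loss = "train",
                                      val_loss = "validation")) |>
    dplyr::filter(!is.na(.data$loss))
}

#' One-row summary of a trained model
#'
#' @inheritParams tidy.mgo_deepmgo
#' @return Tibble: `parameters`, `epochs`, `final_train_loss`,
#'   `final_val_loss`.
#' @export
glance.mgo_deepmgo <- function(x, ...) {
  tibble::tibble(
    parameters = count_trainable_parameters(x),
    epochs = nrow(x$history),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    final_val_loss = x$history$val_loss[nrow(x$history)]
  )
}

#' Tidy ROC validation results
#'
#' @param x An `mgo_roc` from [roc_report()].
#' @param ... Unused.
#' @return ROC curve coordinates: `threshold`, `tpr`, `fpr`.
#' @export
tidy.mgo_roc <- function(x, ...) roc_curve_points(x$labels, x$scores)

#' @rdname tidy.mgo_roc
#' @return For `glance()`: one row with `auroc`, `ci_low`, `ci_high`,
#'   `optimal_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @export
glance.mgo_roc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, ci_low = unname(x$ci["low"]),
                 ci_high = unname(x$ci["high"]),
                 optimal_cutoff = x$optimal_cutoff, youden_j = x$youden_j,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a benchmark grid
#'
#' @param x An `mgo_benchmark`.
#' @param ... Unused.
#' @return The cell tibble (family, fraction, metrics).
#' @export
tidy.mgo_benchmark <- function(x, ...) x$cells

#' @rdname tidy.mgo_benchmark
#' @export
glance.mgo_benchmark <- function(x, ...) {
  ok <- dplyr::filter(x$cells, is.na(.data$error))
  dplyr::slice_max(ok, .data$r2, n = 1, with_ties = FALSE)[
    c("family", "fraction", "r2", "log2_rmse", "pcc")]
}

#' Tidy a Shapley report into per-feature global importance
#'
#' @param x An `mgo_shap_report`.
#' @param ... Unused.
#' @return Tibble `feature_name`, `mean_abs_shap`, `rank`.
#' @export
tidy.mgo_shap_report <- function(x, ...) x$global_importance
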