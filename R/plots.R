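#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_col geom_tile labs theme_minimal scale_color_viridis_c coord_flip
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot the training history of a fitted model
#'
#' @param object A trained `mgo_deepmgo`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss curves.
#' @export
autoplot.mgo_deepmgo <- function(object, ...) {
  ggplot(tidy(object), aes(.data$epoch, .data$loss, color = .data$set)) +
    geom_line() +
    labs(x = "epoch", y = "RMSE loss", color = NULL,
         title = "Training history") +
    theme_minimal()
}

#' Plot a ROC curve with its AUROC
#'
#' @param object An `mgo_roc` from [roc_report()].
#' @param ... Unused.
#' @return A ggplot ROC curve.
#' @export
autoplot.mgo_roc <- function(object, ...) {
  ggplot(tidy(object), aes(.data$fpr, .data$tpr)) +
    geom_abline(linetype = "dashed", color = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUROC %.3f (95%% CI %.3f-%.3f)",
                         object$auroc, object$ci["low"], object$ci["high"])) +
    theme_minimal()
}

#' Plot the benchmark grid as a dot heatmap
#'
#' R-squared (point color) and log2 RMSE (point size, smaller = better) per
#' (family, feature-fraction) cell.
#'
#' @param object An `mgo_benchmark`.
#' @param metric `"r2"` or `"log2_rmse"` for the fill.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgo_benchmark <- function(object, metric = c("r2", "log2_rmse"), ...) {
  metric <- match.arg(metric)
  ok <- dplyr::filter(object$cells, is.na(.data$error))
  ggplot(ok, aes(factor(.data$fraction), .data$family,
                 fill = .data[[metric]])) +
    geom_tile(color = "white") +
    labs(x = "feature fraction (%)", y = NULL, fill = metric,
         title = "Model x feature-fraction benchmark") +
    theme_minimal()
}

#' Plot screening hits
#'
#' Predicted activity score per compound and concentration, with the
#' activity-call cutoff.
#'
#' @param object An `mgo_screen`.
#' @param top_k Show at most this many compounds (by best rank).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgo_screen <- function(object, top_k = 20, ...) {
  per <- attr(object, "per_compound")
  keep <- head(per$compound_id, top_k)
  df <- dplyr::filter(tibble::as_tibble(object), .data$compound_id %in% keep)
  df$compound_id <- factor(df$compound_id, levels = rev(keep))
  ggplot(df, aes(.data$score, .data$compound_id,
                 color = factor(.data$concentration_uM))) +
    geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff_used"),
                        linetype = "dashed") +
    labs(x = "predicted activity score", y = NULL,
         color = "concentration (uM)", title = "Virtual screen") +
    theme_minimal()
}

#' Plot global Shapley feature importance
#'
#' @param object An `mgo_shap_report`.
#' @param top_k Number of top features to show.
#' @param ... Unused.
#' @return A ggplot bar chart of mean |SHAP| per feature.
#' @export
autoplot.mgo_shap_report <- function(object, top_k = 20, ...) {
  df <- head(object$global_importance, top_k)
  df$feature_name <- factor(df$feature_name, levels = rev(df$feature_name))
  ggplot(df, aes(.data$mean_abs_shap, .data$feature_name)) +
    geom_col() +
    labs(x = "mean |Shapley value|", y = NULL,
         title = sprintf("Global feature importance at %g uM",
                         object$concentration_uM)) +
    theme_minimal()
}
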