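# Model-agnostic kernel Shapley-value explanations.
#
# Shapley values are estimated by the kernel-weighted linear regression over
# feature coalitions: a coalition z (subset of features taking the explained
# instance's values, the rest taking background values) is scored by the mean
# model output over the background rows, and phi solves the weighted least
# squares with Shapley kernel weights w(z) = (p - 1) / (choose(p, |z|) |z|
# (p - |z|)), constrained so base_value + sum(phi) equals the model output at
# the instance. Under full coalition enumeration this recovers the exact
# Shapley values; under sampling it approximates them.

shap_kernel_weight <- function(p, s) {
  (p - 1) / (choose(p, s) * s * (p - s))
}

# Mean model output over the background with coalition features replaced by
# the instance's values. Z: matrix of coalitions (rows) x features (0/1).
coalition_values <- function(model_fn, background, instance, Z) {
  n_bg <- nrow(background)
  vapply(seq_len(nrow(Z)), function(i) {
    on <- Z[i, ] == 1
    x <- background
    if (any(on)) x[, on] <- matrix(instance[on], n_bg, sum(on), byrow = TRUE)
    out <- model_fn(x)
    if (!all(is.finite(out))) stopf("model returned non-finite output on a coalition")
    mean(out)
  }, double(1))
}

solve_kernel_shap <- function(Z, v, w, fx, base) {
  p <- ncol(Z)
  # eliminate phi_p through the local-accuracy constraint sum(phi) = fx - base
  delta <- fx - base
  zp <- Z[, p]
  A <- Z[, -p, drop = FALSE] - zp
  b <- v - base - zp * delta
  WA <- A * w
  beta <- tryCatch(solve(crossprod(WA, A), crossprod(WA, b)),
                   error = function(e) qr.solve(crossprod(WA, A) +
                                                  diag(1e-10, p - 1),
                                                crossprod(WA, b)))
  phi <- c(drop(beta), delta - sum(beta))
  phi
}

#' Kernel Shapley values for one instance
#'
#' Explains `model_fn`'s output at `instance` against a background dataset:
#' features absent from a coalition are replaced by background values, and
#' the Shapley values are estimated by kernel-weighted linear regression over
#' coalitions. With `p <= 12` features (or `exact = TRUE`) all `2^p - 2`
#' non-trivial coalitions are enumerated and the values are exact; otherwise
#' `coalition_samples` coalitions are drawn (size-weighted, seeded).
#'
#' @param model_fn Function: feature matrix (rows = instances) -> numeric
#'   scores. Must be pure.
#' @param background Matrix/data frame of background rows (training rows;
#'   the reference protocol samples 100 of them).
#' @param instance Single feature row (vector or 1-row matrix).
#' @param coalition_samples Number of sampled coalitions when not exact, or
#'   `"auto"` (`2 * p + 2048`).
#' @param seed Seed for coalition sampling.
#' @param exact Force full enumeration regardless of p.
#' @return List of class `mgo_shap`: `phi` (named per-feature vector),
#'   `base_value` (mean model output over the background), `fx` (model output
#'   at the instance), `exact`.
#' @export
kernel_shap_values <- function(model_fn, background, instance,
                               coalition_samples = "auto", seed = 1L,
                               exact = NULL) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stopf("background is empty")
  instance <- as.numeric(instance)
  p <- ncol(background)
  if (length(instance) != p) stopf("instance length does not match background width")
  base <- mean(model_fn(background))
  fx <- mean(model_fn(matrix(instance, 1, p,
                             dimnames = list(NULL, colnames(background)))))
  if (!is.finite(base) || !is.finite(fx)) stopf("model returned non-finite output")
  nms <- colnames(background) %||% paste0("x", seq_len(p))
  if (p == 1) {
    out <- list(phi = stats::setNames(fx - base, nms), base_value = base,
                fx = fx, exact = TRUE)
    return(structure(out, class = "mgo_shap"))
  }
  exact <- exact %||% (p <= 12)
  if (exact) {
    sizes <- 1:(p - 1)
    Z <- as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
    s <- rowSums(Z)
    keep <- s > 0 & s < p
    Z <- Z[keep, , drop = FALSE]
    w <- shap_kernel_weight(p, rowSums(Z))
  } else {
    m <- if (identical(coalition_samples, "auto")) 2L * p + 2048L
         else as.integer(coalition_samples)
    Z <- with_seed(seed, {
      sizes <- 1:(p - 1)
      pr <- shap_kernel_weight(p, sizes) * choose(p, sizes)
      s_draw <- sample(sizes, m, replace = TRUE, prob = pr / sum(pr))
      t(vapply(s_draw, function(s) {
        z <- integer(p); z[sample.int(p, s)] <- 1L; z
      }, integer(p)))
    })
    w <- rep(1, nrow(Z))   # sampling already follows the kernel distribution
  }
  v <- coalition_values(model_fn, background, instance, Z)
  phi <- solve_kernel_shap(Z, v, w, fx, base)
  structure(list(phi = stats::setNames(phi, nms), base_value = base, fx = fx,
                 exact = exact),
            class = "mgo_shap")
}

#' @export
print.mgo_shap <- function(x, ...) {
  cat(sprintf("<mgo_shap> %d features; base %.4f; f(x) %.4f (%s)\n",
              length(x$phi), x$base_value, x$fx,
              if (x$exact) "exact enumeration" else "sampled coalitions"))
  invisible(x)
}

#' Explain a trained model over a set of instances
#'
#' Runs [kernel_shap_values()] for each row of `instances` against a
#' background sampled from the training rows (default size 100), holding the
#' concentration input fixed at `concentration_uM`, and aggregates global
#' importance as the mean absolute Shapley value per feature.
#'
#' @param model A trained `mgo_deepmgo`.
#' @param train_descriptors Descriptor table the model was trained on
#'   (background source).
#' @param instances Descriptor table of the rows to explain (e.g. test
#'   compounds).
#' @param concentration_uM Concentration (µM) at which to explain.
#' @param background_size Background rows sampled from the training table.
#' @param seed Seed for background sampling and coalition sampling.
#' @param coalition_samples See [kernel_shap_values()].
#' @return List of class `mgo_shap_report`: `phi` (instances x features
#'   matrix), `base_value`, `global_importance` tibble (`feature_name`,
#'   `mean_abs_shap`, `rank`).
#' @export
explain_model <- function(model, train_descriptors, instances,
                          concentration_uM = 400, background_size = 100,
                          seed = 1L, coalition_samples = "auto") {
  xtr <- descriptor_matrix(train_descriptors)
  if (background_size > nrow(xtr)) {
    stopf("background_size (%d) exceeds the %d training rows",
          background_size, nrow(xtr))
  }
  bg_rows <- with_seed(child_seed(seed, "background"),
                       sample.int(nrow(xtr), background_size))
  background <- xtr[bg_rows, , drop = FALSE]
  model_fn <- shap_model_fn(model, concentration_uM)
  xi <- descriptor_matrix(instances)
  reports <- lapply(seq_len(nrow(xi)), function(i) {
    kernel_shap_values(model_fn, background, xi[i, ],
                       coalition_samples = coalition_samples,
                       seed = child_seed(seed, paste0("coalitions", i)))
  })
  phi <- do.call(rbind, lapply(reports, function(r) r$phi))
  rownames(phi) <- instances$compound_id
  structure(list(phi = phi, base_value = reports[[1]]$base_value,
                 concentration_uM = concentration_uM,
                 global_importance = global_importance(phi)),
            class = "mgo_shap_report")
}

# Raw-descriptor prediction closure at a fixed concentration; normalization
# is applied inside so SHAP perturbs the natural descriptor scale.
shap_model_fn <- function(model, concentration_uM) {
  state <- model$normalization
  function(x) {
    x <- as.matrix(x)
    colnames(x) <- state$feature_names
    xs <- scale_features(state, x)
    cs <- scale_concentration(state, rep(concentration_uM, nrow(x)))
    network_forward(model$net, xs, cs, training = FALSE)$pred
  }
}

#' Global feature importance from Shapley values
#'
#' Mean absolute Shapley value per feature over all explained instances,
#' ranked descending; ties broken by column order.
#'
#' @param phi Matrix of Shapley values, instances x features.
#' @return Tibble: `feature_name`, `mean_abs_shap`, `rank`.
#' @export
global_importance <- function(phi) {
  phi <- rbind(phi)
  if (nrow(phi) < 1) stopf("need at least one explained instance")
  imp <- colMeans(abs(phi))
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(feature_name = colnames(phi)[ord] %||% as.character(ord),
                 mean_abs_shap = unname(imp[ord]),
                 rank = seq_along(ord))
}

#' @export
print.mgo_shap_report <- function(x, ...) {
  cat(sprintf("<mgo_shap_report> %d instances x %d features at %g uM; top features:\n",
              nrow(x$phi), ncol(x$phi), x$concentration_uM))
  print(head(x$global_importance, 5))
  invisible(x)
}
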