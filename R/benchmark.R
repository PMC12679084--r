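#' Univariate F-test feature importance
#'
#' Scores every descriptor by the univariate linear-regression F statistic of
#' that single feature against the activity score:
#' `F = (n - 2) * r^2 / (1 - r^2)` with `r` the Pearson correlation — a
#' strictly increasing function of `r^2` at fixed `n`, so the ranking equals
#' the `r^2` ranking. A feature identical to the response gets `F = Inf`;
#' zero-variance features score 0 and rank last. Ties are broken by original
#' column order. Feature importance is meant to be computed on training rows
#' only.
#'
#' @param x Numeric feature matrix (or data frame), n >= 3 rows.
#' @param y Numeric response, length n.
#' @return A tibble: `feature_name`, `f_statistic`, `rank` (1 = best),
#'   ordered by rank.
#' @export
univariate_feature_scores <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stopf("need at least 3 rows for univariate F tests")
  if (length(y) != n) stopf("x and y are not aligned")
  sds <- apply(x, 2, sd)
  degenerate <- sds == 0
  r <- rep(0, ncol(x))
  if (any(!degenerate)) r[!degenerate] <- drop(cor(x[, !degenerate, drop = FALSE], y))
  r2 <- r ^ 2
  f <- ifelse(degenerate, 0, ifelse(r2 >= 1, Inf, (n - 2) * r2 / (1 - r2)))
  key <- ifelse(degenerate, -Inf, f)   # zero-variance features sort last
  ord <- order(key, seq_along(f), decreasing = c(TRUE, FALSE), method = "radix")
  tibble::tibble(
    feature_name = colnames(x)[ord] %||% as.character(ord),
    f_statistic = unname(f[ord]),
    rank = seq_along(ord)
  )
}

#' Keep the top fraction of ranked features
#'
#' Retains the `floor(q * p / 100)` best-ranked features (at least 1).
#' `q = 100` is the identity: all features, restored to their original
#' column order.
#'
#' @param scores Tibble from [univariate_feature_scores()].
#' @param q Percent of features to keep, in (0, 100].
#' @param original_order Character vector of the original column order, used
#'   to restore it at `q = 100`; defaults to the order implied by the ranks.
#' @return Character vector of feature names, best rank first (original
#'   order at `q = 100`).
#' @export
select_top_fraction <- function(scores, q, original_order = NULL) {
  if (q <= 0 || q > 100) stopf("q must be in (0, 100], got %g", q)
  p <- nrow(scores)
  ranked <- dplyr::arrange(scores, .data$rank)$feature_name
  if (q == 100) return(original_order %||% ranked)
  ranked[seq_len(max(1L, floor(q * p / 100)))]
}

#' Baseline model specification
#'
#' @param family One of `"lasso"`, `"ridge"`, `"random_forest"`, `"svr"`,
#'   `"deepmgo"`, `"deepic50_like"`, `"resnet18_like"`.
#' @param grid Named list of hyperparameter vectors searched exhaustively on
#'   the validation set; `NULL` for the family default. Penalized families
#'   take `alpha` (penalty strength), the forest `num_trees` and `max_depth`
#'   (`NA` = unlimited), the support-vector regressor `cost` and `epsilon`
#'   (radial kernel). Deep families have no search grid; they train under
#'   `deep_config`.
#' @param seed Integer seed.
#' @param deep_config [train_config()] used by the deep families.
#' @return A list of class `mgo_baseline_spec`.
#' @export
baseline_spec <- function(family = c("lasso", "ridge", "random_forest", "svr",
                                     "deepmgo", "deepic50_like", "resnet18_like"),
                          grid = NULL, seed = 1L, deep_config = train_config()) {
  family <- match.arg(family)
  default_grid <- switch(family,
    lasso = ,
    ridge = list(alpha = 10 ^ seq(-4, 2, length.out = 7)),
    random_forest = list(num_trees = c(100, 500), max_depth = c(NA, 16)),
    svr = list(cost = c(0.1, 1, 10), epsilon = c(0.01, 0.1)),
    list())
  grid <- grid %||% default_grid
  if (family %in% c("lasso", "ridge", "random_forest", "svr") && !length(grid)) {
    stopf("family '%s' is tunable but the hyperparameter grid is empty", family)
  }
  structure(list(family = family, grid = grid, seed = as.integer(seed),
                 deep_config = deep_config),
            class = "mgo_baseline_spec")
}

# Design matrix for the tabular baselines: normalized descriptors plus the
# normalized concentration as one extra column, the same information the
# network receives.
baseline_design <- function(dataset) {
  cbind(dataset$x, conc = dataset$conc)
}

fit_one_baseline <- function(family, params, x, y, seed) {
  switch(family,
    lasso = glmnet::glmnet(x, y, alpha = 1, lambda = params$alpha, standardize = FALSE),
    ridge = glmnet::glmnet(x, y, alpha = 0, lambda = params$alpha, standardize = FALSE),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = params$num_trees,
      max.depth = if (is.na(params$max_depth)) NULL else params$max_depth,
      seed = seed, num.threads = 1),
    svr = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     cost = params$cost, epsilon = params$epsilon, scale = FALSE),
    stopf("unknown baseline family '%s'", family))
}

predict_one_baseline <- function(family, fit, x) {
  switch(family,
    lasso = ,
    ridge = drop(predict(fit, newx = x)),
    random_forest = predict(fit, data = as.data.frame(x), num.threads = 1)$predictions,
    svr = drop(predict(fit, x)))
}

#' Fit a baseline with validation-set hyperparameter search
#'
#' Exhaustive search over the spec's grid: every hyperparameter combination
#' is fit on the training set and scored by RMSE on the validation set; the
#' best combination (ties broken by grid order) is refit on the training set
#' and returned. Deep families train once under their training configuration.
#'
#' @param spec A [baseline_spec()].
#' @param train,val Disjoint normalized datasets from [apply_normalization()].
#' @return An object of class `mgo_baseline`: `family`, `fit`, `best_params`,
#'   `val_rmse`, `search` (tibble of every grid point and its validation
#'   RMSE).
#' @export
fit_baseline <- function(spec, train, val) {
  family <- spec$family
  if (family %in% c("deepmgo", "deepic50_like", "resnet18_like")) {
    p <- ncol(train$x)
    arch <- switch(family,
      deepmgo = deepmgo_spec(p),
      deepic50_like = deep_spec(p, conv_kernels = c(16, 32, 64, 64),
                                feature_dense = 256, head = c(128, 1)),
      resnet18_like = deep_spec(p, conv_kernels = c(16, 32, 64, 128),
                                feature_dense = 128, head = c(64, 1)))
    model <- train_model(arch, train, spec$deep_config, validation = val)
    vp <- network_forward(model$net, val$x, val$conc, training = FALSE)$pred
    return(structure(list(family = family, fit = model, best_params = list(),
                          val_rmse = sqrt(mean((vp - val$y) ^ 2)),
                          search = tibble::tibble()),
                     class = "mgo_baseline"))
  }
  xtr <- baseline_design(train)
  xval <- baseline_design(val)
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best <- NULL
  search <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    fit <- fit_one_baseline(family, params, xtr, train$y, spec$seed)
    rmse <- sqrt(mean((predict_one_baseline(family, fit, xval) - val$y) ^ 2))
    search[[i]] <- tibble::tibble(!!!params, val_rmse = rmse)
    if (is.null(best) || rmse < best$val_rmse) {   # strict: ties keep grid order
      best <- list(params = params, fit = fit, val_rmse = rmse)
    }
  }
  structure(list(family = family, fit = best$fit, best_params = best$params,
                 val_rmse = best$val_rmse, search = dplyr::bind_rows(search)),
            class = "mgo_baseline")
}

#' Predict activity scores from a fitted baseline
#'
#' @param object An `mgo_baseline`.
#' @param dataset A normalized `mgo_dataset`.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.mgo_baseline <- function(object, dataset, ...) {
  if (object$family %in% c("deepmgo", "deepic50_like", "resnet18_like")) {
    network_forward(object$fit$net, dataset$x, dataset$conc, training = FALSE)$pred
  } else {
    predict_one_baseline(object$family, object$fit, baseline_design(dataset))
  }
}

subset_dataset <- function(dataset, features) {
  out <- dataset
  out$x <- dataset$x[, features, drop = FALSE]
  out$feature_names <- features
  out
}

#' Run the models-by-feature-fractions benchmark grid
#'
#' For one fixed split: scores features on the training rows, then for every
#' requested feature fraction and model family fits the model (validation-set
#' hyperparameter search for the tabular baselines) on the selected columns
#' and evaluates on the test set. A failing cell is recorded and the grid
#' continues.
#'
#' @param descriptors Descriptor table.
#' @param assays Companion assay table.
#' @param split An [make_split()] over the assay records.
#' @param families Character vector of [baseline_spec()] families.
#' @param fractions Feature percentages, subset of {10, 30, 50, 70, 90, 100}.
#' @param seed Seed passed to every family.
#' @param deep_config [train_config()] for the deep families.
#' @return An object of class `mgo_benchmark`: `cells` (tibble: family,
#'   fraction, n_features, rmse, log2_rmse, r2, pcc, n, error), `best_cell`
#'   (maximum test R^2), `feature_scores`.
#' @export
run_benchmark_grid <- function(descriptors, assays, split,
                               families = c("lasso", "ridge", "random_forest", "svr", "deepmgo"),
                               fractions = c(10, 30, 50, 70, 90, 100),
                               seed = 1L, deep_config = train_config()) {
  state <- fit_normalization(descriptors, assays, split$train)
  folds <- lapply(list(train = split$train, val = split$val, test = split$test),
                  function(ix) apply_normalization(state, descriptors, assays[ix, ]))
  scores <- univariate_feature_scores(folds$train$x, folds$train$y)
  original_order <- colnames(folds$train$x)

  cells <- list()
  for (q in fractions) {
    feats <- select_top_fraction(scores, q, original_order = original_order)
    sub <- lapply(folds, subset_dataset, features = feats)
    for (family in families) {
      res <- tryCatch({
        fit <- fit_baseline(baseline_spec(family, seed = seed,
                                          deep_config = deep_config),
                            sub$train, sub$val)
        pred <- predict(fit, sub$test)
        m <- regression_metrics(sub$test$y, pred)
        dplyr::mutate(m, family = family, fraction = q,
                      n_features = length(feats), error = NA_character_,
                      .before = 1)
      }, error = function(e) {
        tibble::tibble(family = family, fraction = q,
                       n_features = length(feats), rmse = NA_real_,
                       log2_rmse = NA_real_, r2 = NA_real_, pcc = NA_real_,
                       n = NA_integer_, error = conditionMessage(e))
      })
      cells[[length(cells) + 1L]] <- res
    }
  }
  cells <- dplyr::bind_rows(cells)
  ok <- dplyr::filter(cells, is.na(.data$error))
  best <- if (nrow(ok)) dplyr::slice_max(ok, .data$r2, n = 1, with_ties = FALSE)
  structure(list(cells = cells,
                 best_cell = if (!is.null(best)) best[c("family", "fraction")],
                 feature_scores = scores, split = split),
            class = "mgo_benchmark")
}

#' @export
print.mgo_benchmark <- function(x, ...) {
  cat(sprintf("<mgo_benchmark> %d cells (%d families x %d fractions)\n",
              nrow(x$cells), length(unique(x$cells$family)),
              length(unique(x$cells$fraction))))
  if (!is.null(x$best_cell)) {
    cat(sprintf("  best cell: %s at %g%% features\n",
                x$best_cell$family, x$best_cell$fraction))
  }
  print(x$cells)
  invisible(x)
}
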