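test_that("univariate F scores rank features exactly as r-squared does", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(10:60, 1); p <- sample(4:15, 1)
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    sc <- univariate_feature_scores(x, y)
    r2 <- drop(cor(x, y)) ^ 2
    expect_equal(sc$feature_name, colnames(x)[order(-r2)])
    # F statistic equals the univariate linear-regression F test
    j <- sample(p, 1)
    f_lm <- unname(summary(stats::lm(y ~ x[, j]))$fstatistic["value"])
    expect_equal(sc$f_statistic[sc$feature_name == colnames(x)[j]], f_lm,
                 tolerance = 1e-10)
  }
})

test_that("degenerate features score at the extremes", {
  set.seed(4)
  y <- rnorm(20)
  x <- cbind(self = y, noise = rnorm(20), flat = rep(2, 20))
  sc <- univariate_feature_scores(x, y)
  expect_equal(sc$feature_name[1], "self")
  expect_equal(sc$f_statistic[1], Inf)
  expect_equal(sc$feature_name[3], "flat")
  expect_equal(sc$f_statistic[3], 0)
  expect_error(univariate_feature_scores(x[1:2, ], y[1:2]), "at least 3")
})

test_that("top-fraction selection floors, keeps nesting, and restores order at 100%", {
  set.seed(9)
  x <- matrix(rnorm(30 * 10), 30, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(30)
  sc <- univariate_feature_scores(x, y)
  expect_length(select_top_fraction(sc, 30), 3L)
  expect_identical(select_top_fraction(sc, 100, original_order = colnames(x)),
                   colnames(x))
  qs <- c(10, 30, 50, 70, 90, 100)
  for (i in seq_len(length(qs) - 1)) {
    expect_true(all(select_top_fraction(sc, qs[i]) %in%
                      select_top_fraction(sc, qs[i + 1])))
  }
  # the published width: 90% of 2,756 descriptors
  big <- tibble::tibble(feature_name = paste0("d", 1:2756),
                        f_statistic = runif(2756), rank = 1:2756)
  expect_length(select_top_fraction(big, 90), 2480L)
  expect_error(select_top_fraction(sc, 0), "in \\(0, 100\\]")
})

make_linear_folds <- function(n = 60, p = 6, noise = 0, seed = 2) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- seq_len(p) / p
  y <- drop(x %*% beta) + rnorm(n, sd = noise)
  mk <- function(ix) structure(list(x = x[ix, , drop = FALSE],
                                    conc = rep(0.5, length(ix)),
                                    y = y[ix], n = length(ix)),
                               class = "mgo_dataset")
  list(train = mk(1:40), val = mk(41:50), test = mk(51:60))
}

test_that("validation-set grid search picks the best point with grid-order ties", {
  folds <- make_linear_folds()
  fit <- fit_baseline(baseline_spec("ridge", grid = list(alpha = c(1e-8, 10))),
                      folds$train, folds$val)
  expect_equal(fit$best_params$alpha, 1e-8)
  expect_lt(fit$val_rmse, 1e-3)   # near-interpolation at vanishing penalty
  expect_equal(nrow(fit$search), 2L)
  expect_true(all(fit$val_rmse <= fit$search$val_rmse))

  tie <- fit_baseline(baseline_spec("ridge", grid = list(alpha = c(2, 2))),
                      folds$train, folds$val)
  expect_equal(which(tie$search$val_rmse == tie$val_rmse)[1], 1L)

  big_alpha <- fit_baseline(baseline_spec("lasso", grid = list(alpha = 1e6)),
                            folds$train, folds$val)
  pred <- predict(big_alpha, folds$val)
  expect_lt(sd(pred), 1e-12)      # shrunk to the intercept
  expect_lte(regression_metrics(folds$val$y, pred + rnorm(10, sd = 1e-9))$r2, 0)

  expect_error(baseline_spec("svr", grid = list()), "grid is empty")
})

test_that("forest and support-vector baselines train and predict", {
  folds <- make_linear_folds(noise = 0.05)
  for (family in c("random_forest", "svr")) {
    fit <- fit_baseline(baseline_spec(family), folds$train, folds$val)
    expect_s3_class(fit, "mgo_baseline")
    m <- regression_metrics(folds$test$y, predict(fit, folds$test))
    expect_gt(m$r2, 0.3)
  }
})

test_that("the larger deep comparator presets build, train, and predict", {
  set.seed(12)
  n <- 80; p <- 200
  x <- matrix(runif(n * p), n, dimnames = list(NULL, sprintf("f%03d", 1:p)))
  y <- drop(x[, 1:4] %*% c(1, -1, 0.5, 0.5)) + rnorm(n, sd = 0.1)
  mk <- function(ix) structure(list(x = x[ix, , drop = FALSE],
                                    conc = rep(0.5, length(ix)),
                                    y = y[ix], n = length(ix)),
                               class = "mgo_dataset")
  folds <- list(train = mk(1:60), val = mk(61:80))
  for (family in c("deepic50_like", "resnet18_like")) {
    fit <- fit_baseline(baseline_spec(family,
                                      deep_config = train_config(epochs = 2, seed = 1)),
                        folds$train, folds$val)
    pred <- predict(fit, folds$val)
    expect_length(pred, 20L)
    expect_true(all(is.finite(pred)))
    # the presets are strictly larger than the reference architecture
    expect_gt(count_trainable_parameters(fit$fit),
              count_trainable_parameters(build_deepmgo(deepmgo_spec(p), 1)))
  }
})

test_that("the benchmark grid fills every cell deterministically", {
  w <- small_world()
  rep1 <- run_benchmark_grid(w$descriptors, w$assays, w$split,
                             families = c("lasso", "random_forest"),
                             fractions = c(50, 100), seed = 3)
  expect_equal(nrow(rep1$cells), 4L)
  expect_true(all(is.na(rep1$cells$error)))
  rep2 <- run_benchmark_grid(w$descriptors, w$assays, w$split,
                             families = c("lasso", "random_forest"),
                             fractions = c(50, 100), seed = 3)
  expect_identical(rep1$cells, rep2$cells)
  expect_s3_class(glance(rep1), "tbl_df")
  expect_s3_class(autoplot(rep1), "ggplot")
  # feature selection sees training rows only: corrupting test records
  # leaves the selected subset untouched
  assays2 <- w$assays
  assays2$activity[w$split$test] <- rev(assays2$activity[w$split$test])
  rep3 <- run_benchmark_grid(w$descriptors, assays2, w$split,
                             families = "lasso", fractions = c(50), seed = 3)
  expect_identical(rep3$feature_scores, rep1$feature_scores)
})

test_that("a failing cell is recorded while the grid continues", {
  w <- small_world()
  # 10% of 40 features = 4 columns: too short for the deep architecture
  rep_ <- run_benchmark_grid(w$descriptors, w$assays, w$split,
                             families = c("deepmgo", "lasso"),
                             fractions = c(10), seed = 3,
                             deep_config = train_config(epochs = 1, seed = 3))
  deep_cell <- dplyr::filter(rep_$cells, .data$family == "deepmgo")
  expect_false(is.na(deep_cell$error))
  lasso_cell <- dplyr::filter(rep_$cells, .data$family == "lasso")
  expect_true(is.na(lasso_cell$error))
})

test_that("forest and network recover low-noise synthetic structure", {
  w <- small_world()   # zero noise
  rep_ <- run_benchmark_grid(
    w$descriptors, w$assays, w$split,
    families = c("random_forest", "deepmgo"), fractions = 100, seed = 7,
    deep_config = train_config(epochs = 60, seed = 7))
  expect_true(all(is.na(rep_$cells$error)))
  expect_true(all(rep_$cells$r2 >= 0.8),
              info = paste(rep_$cells$family, round(rep_$cells$r2, 3),
                           collapse = "; "))
})
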