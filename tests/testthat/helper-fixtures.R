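# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures (trained models) are built once per test run and
# memoized.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small synthetic world shared by several files: zero noise, continuous
# features only, learnable in a few seconds
small_config <- function(noise_sd = 0, seed = 101L) {
  synth_config(n_compounds = 120, p_binary = 0, p_continuous = 40,
               k_informative = 6, weight_scale = 1.5, noise_sd = noise_sd,
               concentration_grid = c(1, 10, 100, 400, 1000),
               records_total = NULL, seed = seed)
}

small_world <- function() {
  memoize("small_world", function() {
    cfg <- small_config()
    cmp <- generate_compounds(cfg)
    assays <- generate_assays(cmp$descriptors, cmp$truth, cfg)
    split <- make_split(nrow(assays), seed = 101)
    list(config = cfg, descriptors = cmp$descriptors, truth = cmp$truth,
         assays = assays, split = split)
  })
}

# a trained model over the small world (reduced epochs; enough signal at
# zero noise for ranking checks)
small_model <- function() {
  memoize("small_model", function() {
    w <- small_world()
    train_deepmgo(w$descriptors, w$assays, w$split,
                  config = train_config(epochs = 60, seed = 101))
  })
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# ---- independent oracles -------------------------------------------------

# Eq.-style convolution by an explicit triple loop over output position j,
# kernel m, tap l (and channel), with optional bias/activation
oracle_conv <- function(x, kernels, bias = 0, stride = 1, activation = identity) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(kernels)) kernels <- array(kernels, c(length(kernels), 1, 1))
  L <- dim(kernels)[1]; ch <- dim(kernels)[2]; M <- dim(kernels)[3]
  bias <- rep_len(bias, M)
  out_len <- (nrow(x) - L) %/% stride + 1
  out <- matrix(0, out_len, M)
  for (j in seq_len(out_len)) {
    for (m in seq_len(M)) {
      acc <- 0
      for (l in seq_len(L)) {
        for (cc in seq_len(ch)) {
          acc <- acc + kernels[l, cc, m] * x[(j - 1) * stride + l, cc]
        }
      }
      out[j, m] <- activation(acc + bias[m])
    }
  }
  out
}

oracle_regression_metrics <- function(y, p) {
  n <- length(y)
  rmse <- sqrt(sum((y - p) ^ 2) / n)
  ybar <- sum(y) / n
  list(rmse = rmse,
       r2 = 1 - sum((y - p) ^ 2) / sum((y - ybar) ^ 2),
       pcc = sum((y - mean(y)) * (p - mean(p))) /
         sqrt(sum((y - mean(y)) ^ 2) * sum((p - mean(p)) ^ 2)),
       log2_rmse = log2(rmse))
}

# AUROC by exhaustive positive-negative pair counting, ties credited 0.5
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# best Youden threshold by brute force over a dense threshold set
oracle_cutoff <- function(labels, scores) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  j <- vapply(cand, function(th) {
    mean(scores[labels == 1] > th) + mean(scores[labels == 0] <= th) - 1
  }, double(1))
  max(j)
}

# exact Shapley values by enumerating subsets with multinomial weights;
# value of a coalition = mean model output with absent features drawn from
# the background (same value function as the kernel estimator)
oracle_shapley <- function(model_fn, background, instance) {
  p <- ncol(background)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  val <- function(on) {
    x <- background
    if (any(on)) x[, on] <- matrix(instance[on], nrow(background), sum(on), byrow = TRUE)
    mean(model_fn(x))
  }
  v <- apply(subsets, 1, val)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (s in seq_len(nrow(subsets))) {
      on <- unlist(subsets[s, ])
      if (on[i]) next
      size <- sum(on)
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      on_i <- on; on_i[i] <- TRUE
      key_with <- sum(2 ^ (which(on_i) - 1)) + 1
      phi[i] <- phi[i] + w * (v[key_with] - v[s])
    }
  }
  phi
}
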