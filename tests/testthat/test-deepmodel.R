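test_that("convolution block matches the brute-force triple-loop oracle", {
  set.seed(31)
  cases <- expand.grid(len = c(7, 12), ch = c(1, 3), M = c(1, 4),
                       L = c(1, 3, 5), stride = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    if (cs$len < cs$L) next
    x <- matrix(rnorm(cs$len * cs$ch), cs$len, cs$ch)
    k <- array(rnorm(cs$L * cs$ch * cs$M), c(cs$L, cs$ch, cs$M))
    b <- rnorm(cs$M)
    got <- conv_block_forward(x, k, bias = b, stride = cs$stride)
    want <- oracle_conv(x, k, bias = b, stride = cs$stride)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("convolution block handles the hand-checked cases", {
  # identity kernel: M = 1, L = 1, w = 1, b = 0
  x <- c(0.3, -1, 2)
  expect_equal(drop(conv_block_forward(x, 1)), x)
  # [1,2,3] * [1,1] -> [3,5]
  expect_equal(drop(conv_block_forward(c(1, 2, 3), c(1, 1))), c(3, 5))
  # ReLU clamps a negative pre-activation to zero
  expect_equal(drop(conv_block_forward(1, 1, bias = -3, activation = "relu")), 0)
  # input shorter than the kernel is an error
  expect_error(conv_block_forward(c(1, 2), c(1, 1, 1)), "shorter than")
})

test_that("the reference architecture builds with the 3-conv/3-dense shape", {
  spec <- deepmgo_spec(2756)
  net <- build_deepmgo(spec, seed = 1)
  expect_s3_class(net, "mgo_network")
  expect_length(net$conv, 3L)
  expect_length(net$head, 2L)
  # scalar output for a batch
  out <- mgoscav:::network_forward(net, matrix(runif(5 * 2756), 5), runif(5))$pred
  expect_length(out, 5L)
  # identical seeds give identical initial weights
  expect_identical(build_deepmgo(spec, seed = 9), build_deepmgo(spec, seed = 9))
  expect_error(deepmgo_spec(100, conv_kernels = c(8, 8)), "exactly 3")
  expect_error(deepmgo_spec(100, head = c(16, 8, 1)), "head")
  bad <- mgoscav:::deep_spec(100, conv_kernels = c(8, 8))
  expect_error(build_deepmgo(bad), "3-convolution")
})

test_that("parameter counts equal the closed-form layer-shape sum", {
  # one dense layer, 4 inputs -> 1 unit: 5 parameters
  dense <- mgoscav:::new_dense_layer(4, 1, "identity")
  expect_equal(length(dense$W) + length(dense$b), 5L)
  # one conv block M = 8, L = 5, 1 input channel, batch norm: 8*5 + 8 + 2*8
  conv <- mgoscav:::new_conv_layer(100, 1, 8, 5, 2, "relu", TRUE)
  expect_equal(length(conv$W) + length(conv$b) + length(conv$gamma) +
                 length(conv$beta), 64L)

  closed_form <- function(p, kernels, L, fd, cd, head) {
    lens <- integer(3); chans <- c(1, kernels[1], kernels[2])
    len <- p
    total <- 0
    for (i in 1:3) {
      total <- total + kernels[i] * L * chans[i] + kernels[i] + 2 * kernels[i]
      len <- (len - L) %/% 2 + 1
      lens[i] <- len
    }
    flat <- len * kernels[3]
    total <- total + flat * fd + fd + 1 * cd + cd +
      (fd + cd) * head[1] + head[1] + head[1] * head[2] + head[2]
    total
  }
  set.seed(17)
  for (i in 1:8) {
    p <- sample(40:400, 1)
    kernels <- sample(2:12, 3, replace = TRUE)
    fd <- sample(5:50, 1); cd <- sample(2:10, 1); h1 <- sample(4:30, 1)
    spec <- deepmgo_spec(p, conv_kernels = kernels, feature_dense = fd,
                         conc_dense = cd, head = c(h1, 1))
    net <- build_deepmgo(spec, seed = i)
    expect_equal(count_trainable_parameters(net),
                 closed_form(p, kernels, 5, fd, cd, c(h1, 1)))
  }
})

test_that("training descends, keeps a finite history, and is bit-for-bit reproducible", {
  w <- small_world()
  st <- fit_normalization(w$descriptors, w$assays, w$split$train)
  ds <- apply_normalization(st, w$descriptors, w$assays[w$split$train[1:120], ])
  spec <- deepmgo_spec(ncol(ds$x))
  cfg <- train_config(epochs = 8, seed = 42)
  m1 <- train_model(build_deepmgo(spec, cfg$seed), ds, cfg, normalization = st)
  expect_equal(nrow(m1$history), 8L)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_lt(m1$history$train_loss[8], m1$history$train_loss[1])
  m2 <- train_model(build_deepmgo(spec, cfg$seed), ds, cfg, normalization = st)
  expect_identical(m1$net, m2$net)
})

test_that("a non-finite loss aborts with a diagnostic", {
  w <- small_world()
  st <- fit_normalization(w$descriptors, w$assays, w$split$train)
  ds <- apply_normalization(st, w$descriptors, w$assays[w$split$train[1:60], ])
  ds$y[1] <- NaN   # a poisoned target must be caught, not silently trained on
  spec <- deepmgo_spec(ncol(ds$x))
  expect_error(
    train_model(build_deepmgo(spec, 1), ds,
                train_config(epochs = 2, seed = 1), normalization = st),
    "non-finite loss.*learning rate")
})

test_that("prediction is pure and invariant to batch composition", {
  m <- small_model()
  w <- small_world()
  d <- w$descriptors
  dup <- d[c(1, 1, 2), ]
  dup$compound_id <- c("x1", "x1b", "x2")
  s <- predict_scores(m, dup, 400)
  expect_equal(unname(s[1]), unname(s[2]))
  # batch of one equals the corresponding row of a larger batch
  big <- predict_scores(m, d[1:10, ], 400)
  one <- predict_scores(m, d[3, ], 400)
  expect_equal(unname(one), unname(big[3]), tolerance = 1e-6)
  # row order does not matter
  perm <- c(5, 2, 9, 1)
  expect_equal(unname(predict_scores(m, d[perm, ], 400)),
               unname(big[perm]), tolerance = 1e-12)
  # per-row concentrations are honoured
  two <- predict_scores(m, d[c(1, 1), ] |>
                          dplyr::mutate(compound_id = c("a", "b")),
                        c(10, 1000))
  expect_false(isTRUE(all.equal(two[[1]], two[[2]])))
})

test_that("prediction rejects a feature-space mismatch with the paired state", {
  m <- small_model()
  w <- small_world()
  renamed <- w$descriptors
  names(renamed)[2] <- "not_a_feature"
  expect_error(predict_scores(m, renamed, 400), "feature names")
})

test_that("checkpoints reload to bit-identical predictions", {
  m <- small_model()
  w <- small_world()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  p1 <- predict_scores(m, w$descriptors[1:20, ], 400)
  p2 <- predict_scores(m2, w$descriptors[1:20, ], 400)
  expect_identical(p1, p2)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_true(all(c("weights.rds", "normalization.json") %in% manifest$file))
})

test_that("model summaries expose history and parameter count", {
  m <- small_model()
  td <- tidy(m)
  expect_true(all(c("epoch", "set", "loss") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$parameters, count_trainable_parameters(m))
  expect_s3_class(autoplot(m), "ggplot")
})
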