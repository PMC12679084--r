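test_that("descriptor CSVs parse, impute by column median, and log QC", {
  path <- write_temp_csv(c("Name,d1,d2,d3,d4",
                           "cpdA,0,1.5,3,0",
                           "cpdB,1,2.5,4,0",
                           "cpdC,0,3.5,5,1"))
  d <- read_descriptor_table(path)
  expect_s3_class(d, "mgo_descriptors")
  expect_equal(dim(descriptor_matrix(d)), c(3L, 4L))
  expect_equal(nrow(attr(d, "qc")), 0L)

  # one empty cell in a column whose present values have median 0.5
  path2 <- write_temp_csv(c("Name,d1,d2",
                            "a,0.1,1",
                            "b,,2",
                            "c,0.9,3"))
  d2 <- read_descriptor_table(path2)
  expect_equal(descriptor_matrix(d2)["b", "d1"], 0.5)
  qc <- attr(d2, "qc")
  expect_equal(nrow(qc), 1L)
  expect_equal(qc$imputed_value, 0.5)
  # idempotence: re-reading the completed table imputes nothing
  complete <- tibble::as_tibble(d2)
  names(complete)[1] <- "Name"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(complete, path3)
  expect_equal(nrow(attr(read_descriptor_table(path3), "qc")), 0L)
})

test_that("descriptor parsing rejects duplicates and non-numeric cells by name", {
  dup <- write_temp_csv(c("Name,d1", "a,1", "a,2"))
  expect_error(read_descriptor_table(dup), "duplicate compound")
  bad <- write_temp_csv(c("Name,d1,d2", "a,1,x", "b,2,3"))
  expect_error(read_descriptor_table(bad), "d2.*row 1|row 1.*d2")
  # plain dialect with a custom id column
  plain <- write_temp_csv(c("cid,d1", "a,1", "b,2"))
  expect_equal(read_descriptor_table(plain, dialect = "plain_csv",
                                     id_column = "cid")$compound_id, c("a", "b"))
})

test_that("assay tables parse, validate concentrations, and resolve compounds", {
  desc <- as_descriptor_table(data.frame(id = c("a", "b"), d1 = c(1, 2)))
  path <- write_temp_csv(c("compound_id,concentration_uM,activity",
                           "a,100,0.5", "a,400,0.9", "b,400,0.1"))
  assays <- read_assay_table(path, desc)
  expect_equal(nrow(assays), 3L)
  expect_equal(attr(assays, "concentration_range"), c(100, 400))

  neg <- write_temp_csv(c("compound_id,concentration_uM,activity", "a,-1,0.5"))
  expect_error(read_assay_table(neg), "concentration.*row")
  orphan <- write_temp_csv(c("compound_id,concentration_uM,activity", "zz,10,0.5"))
  expect_error(read_assay_table(orphan, desc), "absent from descriptor")
})

test_that("normalization statistics come from training records only", {
  desc <- as_descriptor_table(data.frame(
    id = c("a", "b", "c"), f1 = c(2, 4, 100), f2 = c(5, 5, 7)))
  assays <- as_assay_table(data.frame(
    compound_id = c("a", "b", "c"), concentration_uM = c(10, 20, 30),
    activity = c(0, 2, 50)))
  st <- fit_normalization(desc, assays, train_idx = 1:2)
  expect_equal(unname(st$feature_min["f1"]), 2)
  expect_equal(unname(st$feature_max["f1"]), 4)
  expect_equal(st$activity_mean, 1)
  expect_equal(st$activity_sd, sqrt(2))   # sample SD, n - 1
  # score of raw 2 under those moments
  ds <- apply_normalization(st, desc, assays)
  expect_equal(ds$y[2], (2 - 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(ds$y[2], 0.7071, tolerance = 1e-4)

  # leakage guard: perturbing a non-training record leaves the state unchanged
  assays2 <- assays
  assays2$activity[3] <- 9999
  desc2 <- desc
  desc2$f1[3] <- -1e6
  st2 <- fit_normalization(desc2, assays2, train_idx = 1:2)
  expect_identical(st, st2)

  # constant training feature maps to 0; out-of-range values are not clipped
  expect_equal(unname(ds$x[1:2, "f2"]), c(0, 0))
  expect_gt(ds$x[3, "f1"], 1)            # 100 is far above the training max
  expect_equal(unname(ds$x[1, "f1"]), 0) # value at the training min
})

test_that("degenerate activity targets are rejected", {
  desc <- as_descriptor_table(data.frame(id = c("a", "b"), d1 = c(1, 2)))
  assays <- as_assay_table(data.frame(compound_id = c("a", "b"),
                                      concentration_uM = c(1, 2),
                                      activity = c(3, 3)))
  expect_error(fit_normalization(desc, assays, 1:2), "degenerate")
  expect_error(fit_normalization(desc, assays, integer(0)), "empty")
})

test_that("activity scores invert back to raw activities", {
  w <- small_world()
  st <- fit_normalization(w$descriptors, w$assays, w$split$train)
  ds <- apply_normalization(st, w$descriptors, w$assays)
  expect_equal(invert_activity(st, ds$y), w$assays$activity, tolerance = 1e-9)
})

test_that("8:1:1 record splits obey the floor/floor/remainder rule", {
  s10 <- make_split(10, seed = 1)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  s <- make_split(2262, seed = 7)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 1810L, val = 226L, test = 226L))
  expect_identical(make_split(2262, seed = 7), s)
  expect_error(make_split(9), "at least 10")
})

test_that("splits partition the records for arbitrary n and seed", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    s <- make_split(n, seed = sample.int(1e6, 1))
    all_idx <- c(s$train, s$val, s$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
})

test_that("group-aware splits keep a compound's records together", {
  groups <- rep(sprintf("g%02d", 1:20), each = 3)
  s <- make_split(60, seed = 5, groups = groups)
  expect_equal(sort(c(s$train, s$val, s$test)), 1:60)
  for (fold in list(s$val, s$test)) {
    expect_true(all(table(groups[fold]) == 3))
  }
})

test_that("normalization state and splits round-trip through JSON", {
  w <- small_world()
  st <- fit_normalization(w$descriptors, w$assays, w$split$train)
  f1 <- withr::local_tempfile(fileext = ".json")
  write_normalization(st, f1)
  st2 <- read_normalization(f1)
  expect_equal(st2$feature_min, st$feature_min)
  expect_equal(st2$activity_sd, st$activity_sd)
  expect_identical(st2$fit_on, st$fit_on)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_split(w$split, f2)
  expect_identical(read_split(f2)$train, w$split$train)
})
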