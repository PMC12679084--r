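#' Read a molecular descriptor table
#'
#' Reads a CSV of per-compound molecular descriptors: one row per compound,
#' an identifier column first, every remaining column a numeric descriptor
#' (binary substructure flags or continuous physicochemical values). The
#' `padel_csv` dialect is the output convention of common descriptor
#' calculators (identifier column named `Name`); `plain_csv` accepts any
#' identifier column named via `id_column`.
#'
#' Missing cells are imputed with the column median of the present values and
#' each imputation is recorded in the attached QC log, together with the names
#' of constant (zero-variance) columns. Reading an already-complete table
#' performs zero imputations.
#'
#' @param path Path to the CSV file.
#' @param dialect `"padel_csv"` (identifier column `Name`) or `"plain_csv"`.
#' @param id_column Identifier column name for `plain_csv`; defaults to the
#'   first column.
#' @param provenance Free-text source tag stored on the result.
#' @return A tibble of class `mgo_descriptors`: column `compound_id` followed
#'   by one numeric column per descriptor. Attributes: `qc` (tibble of imputed
#'   cells: `compound_id`, `feature`, `imputed_value`), `constant_features`
#'   (character), `provenance`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Name = c("a", "b"), mw = c(180, 342), nring = c(1, 2)),
#'           path, row.names = FALSE)
#' read_descriptor_table(path)
read_descriptor_table <- function(path, dialect = c("padel_csv", "plain_csv"),
                                  id_column = NULL, provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("descriptor file not found: %s", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stopf("descriptor table needs an id column plus at least one descriptor")
  id_column <- id_column %||% if (dialect == "padel_csv") "Name" else names(raw)[1]
  if (!id_column %in% names(raw)) stopf("id column '%s' not present in %s", id_column, path)
  as_descriptor_table(raw, id_column = id_column, provenance = provenance)
}

#' Coerce a data frame to a descriptor table
#'
#' Validates, numerically parses, and median-imputes an in-memory data frame
#' with one compound per row. Used by [read_descriptor_table()] and by the
#' synthetic-data generator.
#'
#' @param df Data frame; `id_column` plus numeric (or numeric-parseable)
#'   descriptor columns.
#' @inheritParams read_descriptor_table
#' @return See [read_descriptor_table()].
#' @export
as_descriptor_table <- function(df, id_column = names(df)[1], provenance = "in-memory") {
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids)) {
    stopf("duplicate compound name(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feat <- df[setdiff(names(df), id_column)]
  if (anyDuplicated(names(feat))) {
    stopf("duplicate feature name(s): %s",
          paste(unique(names(feat)[duplicated(names(feat))]), collapse = ", "))
  }
  parsed <- purrr::imap(feat, function(col, nm) {
    if (is.numeric(col)) return(as.double(col))
    chr <- trimws(as.character(col))
    chr[chr == ""] <- NA_character_
    num <- suppressWarnings(as.double(chr))
    bad <- which(!is.na(chr) & is.na(num))
    if (length(bad)) {
      stopf("non-numeric value '%s' in column '%s', row %d (compound '%s')",
            chr[bad[1]], nm, bad[1], ids[bad[1]])
    }
    num
  })
  x <- matrix(unlist(parsed, use.names = FALSE), nrow = length(ids),
              dimnames = list(NULL, names(feat)))

  qc <- tibble::tibble(compound_id = character(), feature = character(),
                       imputed_value = double())
  for (j in seq_len(ncol(x))) {
    miss <- which(is.na(x[, j]))
    if (length(miss)) {
      med <- median(x[, j], na.rm = TRUE)
      if (is.na(med)) stopf("column '%s' is entirely missing", colnames(x)[j])
      x[miss, j] <- med
      qc <- dplyr::bind_rows(qc, tibble::tibble(
        compound_id = ids[miss], feature = colnames(x)[j], imputed_value = med))
    }
  }
  constant <- colnames(x)[apply(x, 2, function(v) max(v) == min(v))]

  out <- tibble::as_tibble(as.data.frame(x))
  out <- dplyr::bind_cols(tibble::tibble(compound_id = ids), out)
  class(out) <- c("mgo_descriptors", class(out))
  attr(out, "qc") <- qc
  attr(out, "constant_features") <- constant
  attr(out, "provenance") <- provenance
  out
}

#' Extract the numeric descriptor matrix
#'
#' @param descriptors A descriptor table from [read_descriptor_table()].
#' @return Numeric matrix, one row per compound, `compound_id` as rownames.
#' @export
descriptor_matrix <- function(descriptors) {
  feat <- setdiff(names(descriptors), "compound_id")
  x <- as.matrix(descriptors[feat])
  rownames(x) <- descriptors$compound_id
  x
}

#' Read an assay table of scavenging measurements
#'
#' One row per measurement: `compound_id`, `concentration_uM` (> 0), and the
#' raw fluorescence-derived scavenging activity value. Replicate
#' (compound, concentration) pairs are permitted and preserved.
#'
#' @param path Path to the CSV file.
#' @param descriptors Optional companion descriptor table; every
#'   `compound_id` must resolve in it.
#' @return A tibble of class `mgo_assays` with columns `compound_id`,
#'   `concentration_uM`, `activity`; attribute `concentration_range`.
#' @export
read_assay_table <- function(path, descriptors = NULL) {
  if (!file.exists(path)) stopf("assay file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    concentration_uM = readr::col_double(),
    activity = readr::col_double()), progress = FALSE)
  as_assay_table(df, descriptors = descriptors)
}

#' Coerce a data frame to an assay table
#'
#' @param df Data frame with columns `compound_id`, `concentration_uM`,
#'   `activity`.
#' @inheritParams read_assay_table
#' @return See [read_assay_table()].
#' @export
as_assay_table <- function(df, descriptors = NULL) {
  need <- c("compound_id", "concentration_uM", "activity")
  if (!all(need %in% names(df))) {
    stopf("assay table must have columns %s", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$concentration_uM) | df$concentration_uM <= 0)
  if (length(bad)) {
    stopf("non-positive concentration in assay row(s): %s",
          paste(head(bad, 5), collapse = ", "))
  }
  if (!is.null(descriptors)) {
    missing_ids <- setdiff(unique(df$compound_id), descriptors$compound_id)
    if (length(missing_ids)) {
      stopf("assay compound(s) absent from descriptor table: %s",
            paste(head(missing_ids, 5), collapse = ", "))
    }
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("mgo_assays", class(out))
  attr(out, "concentration_range") <- range(out$concentration_uM)
  out
}

#' Fit normalization statistics on the training records
#'
#' Computes the only statistics ever applied to new data: per-feature min and
#' max (min-max scaling of descriptors), the mean and sample standard
#' deviation (denominator n - 1) of the raw activity (Z-scaling into the
#' scavenging activity score), and the training concentration range (min-max
#' scaling of the concentration input). All statistics come from training
#' records only: feature ranges from the compounds appearing in training
#' records, activity moments from training activity values.
#'
#' The concentration is scaled on the log10 scale by default — assay doses
#' span six orders of magnitude and EC50s are log-distributed, so log dose is
#' the natural axis; `conc_scale = "linear"` opts out.
#'
#' @param descriptors Descriptor table.
#' @param assays Assay table; `compound_id`s must resolve in `descriptors`.
#' @param train_idx Integer indices of training assay records.
#' @param conc_scale `"log10"` (default) or `"linear"` concentration scale.
#' @return An object of class `mgo_normalization`.
#' @export
fit_normalization <- function(descriptors, assays, train_idx,
                              conc_scale = c("log10", "linear")) {
  conc_scale <- match.arg(conc_scale)
  if (length(train_idx) == 0) stopf("train_idx is empty")
  train <- assays[train_idx, ]
  x <- descriptor_matrix(descriptors)
  train_compounds <- unique(train$compound_id)
  unknown <- setdiff(train_compounds, rownames(x))
  if (length(unknown)) stopf("training compound(s) missing descriptors: %s",
                             paste(head(unknown, 5), collapse = ", "))
  xt <- x[train_compounds, , drop = FALSE]
  y <- train$activity
  if (length(unique(y)) < 2) stopf("degenerate target: fewer than 2 distinct training activities")
  sdy <- sd(y)
  if (sdy == 0) stopf("degenerate target: zero activity standard deviation")
  structure(list(
    feature_names = colnames(x),
    feature_min = apply(xt, 2, min),
    feature_max = apply(xt, 2, max),
    activity_mean = mean(y),
    activity_sd = sdy,
    conc_scale = conc_scale,
    conc_min = min(conc_transform(conc_scale, train$concentration_uM)),
    conc_max = max(conc_transform(conc_scale, train$concentration_uM)),
    fit_on = as.integer(train_idx)
  ), class = "mgo_normalization")
}

#' @export
print.mgo_normalization <- function(x, ...) {
  cat(sprintf("<mgo_normalization> %d features; activity mean %.4g, sd %.4g; fit on %d records\n",
              length(x$feature_names), x$activity_mean, x$activity_sd, length(x$fit_on)))
  invisible(x)
}

# Min-max scale a descriptor matrix; constant training features map to 0,
# out-of-range values are left unclipped (the transform stays linear).
scale_features <- function(state, x) {
  if (!identical(colnames(x), state$feature_names)) {
    stopf("feature names do not match the normalization state")
  }
  rng <- state$feature_max - state$feature_min
  keep <- rng > 0
  out <- sweep(x, 2, state$feature_min, "-")
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, rng[keep], "/")
  out[, !keep] <- 0
  out
}

conc_transform <- function(scale, conc) {
  if (scale == "log10") log10(conc) else conc
}

scale_concentration <- function(state, conc) {
  v <- conc_transform(state$conc_scale %||% "linear", conc)
  rng <- state$conc_max - state$conc_min
  if (rng <= 0) return(rep(0, length(conc)))
  (v - state$conc_min) / rng
}

#' Apply fitted normalization to descriptors and assays
#'
#' Maps descriptors through `x' = (x - min) / (max - min)` (constant training
#' features to 0; values outside the training range fall outside \[0, 1\]
#' without clipping), raw activities through `y' = (y - mean) / sd` — the
#' scavenging activity score — and concentrations through min-max scaling
#' over the training concentration range.
#'
#' @param state An `mgo_normalization` from [fit_normalization()].
#' @inheritParams fit_normalization
#' @return A list of class `mgo_dataset`: `x` (record-level normalized feature
#'   matrix), `conc` (normalized), `conc_uM`, `y` (activity score), `compound_id`,
#'   `feature_names`, `n`.
#' @export
apply_normalization <- function(state, descriptors, assays) {
  x <- descriptor_matrix(descriptors)
  xs <- scale_features(state, x)
  unknown <- setdiff(unique(assays$compound_id), rownames(x))
  if (length(unknown)) stopf("assay compound(s) missing descriptors: %s",
                             paste(head(unknown, 5), collapse = ", "))
  structure(list(
    x = xs[assays$compound_id, , drop = FALSE],
    conc = scale_concentration(state, assays$concentration_uM),
    conc_uM = assays$concentration_uM,
    y = (assays$activity - state$activity_mean) / state$activity_sd,
    compound_id = assays$compound_id,
    feature_names = state$feature_names,
    n = nrow(assays)
  ), class = "mgo_dataset")
}

#' Invert an activity score back to the raw activity scale
#'
#' @param state An `mgo_normalization`.
#' @param score Activity scores (Z scale).
#' @return Raw activity values.
#' @export
invert_activity <- function(state, score) {
  score * state$activity_sd + state$activity_mean
}

#' Split assay records into training / validation / test sets
#'
#' Shuffles record indices under the seed and takes `floor(n * v / sum(ratio))`
#' records for validation and likewise for test, with the remainder for
#' training (8:1:1 by default). Splitting is by assay record, so replicate
#' measurements of one compound can land in different folds; pass `groups`
#' (one compound id per record) to keep each compound's records in one fold.
#'
#' @param n_records Number of assay records (>= 10).
#' @param ratio Integer ratio, default `c(8, 1, 1)`.
#' @param seed Integer seed; the same seed reproduces identical sets.
#' @param groups Optional vector of length `n_records`; records sharing a
#'   group value stay in the same fold (sizes then approximate the ratio).
#' @return A list of class `mgo_split` with integer index vectors `train`,
#'   `val`, `test` and fields `n`, `ratio`, `seed`.
#' @export
make_split <- function(n_records, ratio = c(8, 1, 1), seed = 1L, groups = NULL) {
  if (n_records < 10) stopf("need at least 10 records to split, got %d", n_records)
  total <- sum(ratio)
  if (is.null(groups)) {
    idx <- with_seed(seed, sample.int(n_records))
    n_val <- floor(n_records * ratio[2] / total)
    n_test <- floor(n_records * ratio[3] / total)
    val <- idx[seq_len(n_val)]
    test <- idx[n_val + seq_len(n_test)]
    train <- idx[-seq_len(n_val + n_test)]
  } else {
    if (length(groups) != n_records) stopf("groups must have length n_records")
    gs <- unique(groups)
    gidx <- with_seed(seed, sample(gs))
    n_gval <- floor(length(gs) * ratio[2] / total)
    n_gtest <- floor(length(gs) * ratio[3] / total)
    gval <- gidx[seq_len(n_gval)]
    gtest <- gidx[n_gval + seq_len(n_gtest)]
    val <- which(groups %in% gval)
    test <- which(groups %in% gtest)
    train <- setdiff(seq_len(n_records), c(val, test))
  }
  structure(list(train = sort(as.integer(train)), val = sort(as.integer(val)),
                 test = sort(as.integer(test)), n = as.integer(n_records),
                 ratio = ratio, seed = as.integer(seed)),
            class = "mgo_split")
}

#' @export
print.mgo_split <- function(x, ...) {
  cat(sprintf("<mgo_split> n=%d train/val/test = %d/%d/%d (seed %d)\n",
              x$n, length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Serialize / restore normalization state and splits as JSON
#'
#' Indices round-trip exactly; floating-point statistics are written at full
#' precision.
#'
#' @param x An `mgo_normalization` or `mgo_split`.
#' @param path Output / input file path.
#' @return `write_*` returns `path` invisibly; `read_*` the restored object.
#' @export
write_normalization <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$feature_min <- stats::setNames(as.double(obj$feature_min), obj$feature_names)
  obj$feature_max <- stats::setNames(as.double(obj$feature_max), obj$feature_names)
  obj$fit_on <- as.integer(obj$fit_on)
  structure(obj, class = "mgo_normalization")
}

#' @rdname write_normalization
#' @export
write_split <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_split <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train", "val", "test", "n", "seed")) obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "mgo_split")
}
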