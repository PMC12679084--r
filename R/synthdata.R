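#' Configuration for the synthetic scavenging-assay simulator
#'
#' The simulator emulates the statistical structure the pipeline assumes:
#' a descriptor table mixing binary substructure flags and continuous
#' physicochemical values, a sparse set of informative descriptors driving a
#' latent scavenging potency through a logistic link, a monotone Hill-type
#' dose response in concentration, and additive Gaussian measurement noise on
#' the raw activity. Defaults emulate the shape of the in-house assay
#' campaign the model is designed for: 660 compounds, 2,262 records over a
#' 0.001–1,000 µM concentration range.
#'
#' @param n_compounds Number of compounds.
#' @param p_binary,p_continuous Numbers of binary (Bernoulli(0.2)) and
#'   continuous (standard normal) descriptor columns.
#' @param k_informative Number of descriptors carrying signal.
#' @param weight_scale Scale of the informative descriptor weights
#'   (magnitudes are uniform in `[0.5, 1.5] * weight_scale`).
#' @param hill_coefficient Hill slope `h` (> 0) of the dose response.
#' @param ec50_log10_range Range (log10 µM) spanned by per-compound EC50s;
#'   log10 EC50 decreases linearly in latent potency across this range.
#' @param noise_sd SD of Gaussian measurement noise on the raw activity.
#' @param concentration_grid Assay concentrations (µM), within 0.001–1,000.
#' @param records_total Optional total record count; concentrations per
#'   compound are sampled from the grid so the total matches exactly.
#' @param seed Integer seed; one global seed fans out to per-stage child
#'   seeds so each stage is independently reproducible.
#' @return A list of class `mgo_synth_config`.
#' @export
synth_config <- function(n_compounds = 660, p_binary = 100, p_continuous = 100,
                         k_informative = 10, weight_scale = 1.5,
                         hill_coefficient = 1, ec50_log10_range = c(0, 2.5),
                         noise_sd = 0.05,
                         concentration_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 400, 1000),
                         records_total = 2262, seed = 1L) {
  if (k_informative > p_binary + p_continuous) {
    stopf("k_informative (%d) exceeds the number of descriptors (%d)",
          k_informative, p_binary + p_continuous)
  }
  if (hill_coefficient <= 0) stopf("hill_coefficient must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(concentration_grid) == 0) stopf("concentration grid is empty")
  if (any(concentration_grid < 0.001 | concentration_grid > 1000)) {
    stopf("concentration grid must lie within 0.001–1000 uM")
  }
  structure(list(
    n_compounds = as.integer(n_compounds), p_binary = as.integer(p_binary),
    p_continuous = as.integer(p_continuous), k_informative = as.integer(k_informative),
    weight_scale = weight_scale, hill_coefficient = hill_coefficient,
    ec50_log10_range = ec50_log10_range, noise_sd = noise_sd,
    concentration_grid = sort(concentration_grid),
    records_total = if (is.null(records_total)) NULL else as.integer(records_total),
    seed = as.integer(seed)
  ), class = "mgo_synth_config")
}

#' Generate a synthetic compound descriptor table with ground truth
#'
#' Binary descriptors are Bernoulli(0.2), continuous descriptors standard
#' normal. `k_informative` randomly chosen descriptors get weights of random
#' sign with magnitude uniform in `[0.5, 1.5] * weight_scale` (bounded away
#' from zero, so every informative descriptor carries detectable signal);
#' the latent potency of each compound is
#' `plogis(w . f - center)`, with the centering constant chosen so the linear
#' predictor is centred at the population mean — spreading potencies across
#' (0, 1) rather than stacking them at one end. Each compound's EC50 is
#' coupled to its potency (log10 EC50 decreasing linearly in potency over
#' `ec50_log10_range`), so the full dose-response surface is a deterministic
#' function of the descriptors plus measurement noise.
#'
#' @param config An [synth_config()] object.
#' @return A list: `descriptors` (an `mgo_descriptors` tibble) and `truth`
#'   (class `mgo_ground_truth`: `informative_idx`, `weights` over all p,
#'   `potency`, `ec50` per compound).
#' @export
generate_compounds <- function(config) {
  p <- config$p_binary + config$p_continuous
  with_seed(child_seed(config$seed, "compounds"), {
    xb <- matrix(rbinom(config$n_compounds * config$p_binary, 1, 0.2),
                 nrow = config$n_compounds)
    xc <- matrix(rnorm(config$n_compounds * config$p_continuous),
                 nrow = config$n_compounds)
    x <- cbind(xb, xc)
    colnames(x) <- c(sprintf("bin_%03d", seq_len(config$p_binary)),
                     sprintf("cont_%03d", seq_len(config$p_continuous)))
    informative <- sort(sample.int(p, config$k_informative))
    w <- numeric(p)
    # random sign, magnitude uniform in [0.5, 1.5] x weight_scale: every
    # nominally informative descriptor carries detectable signal (a
    # zero-magnitude "informative" weight would be a contradiction in terms)
    w[informative] <- sample(c(-1, 1), config$k_informative, replace = TRUE) *
      config$weight_scale * runif(config$k_informative, 0.5, 1.5)
    # expected linear predictor: binary features have mean 0.2, continuous 0
    center <- sum(w[seq_len(config$p_binary)]) * 0.2
    eta <- drop(x %*% w) - center
    potency <- stats::plogis(eta)
    # potency/EC50 coupling: stronger scavengers act at lower dose, with
    # log10 EC50 falling linearly in potency across the configured range —
    # so the dose response is a deterministic function of the descriptors
    lo <- config$ec50_log10_range[1]; hi <- config$ec50_log10_range[2]
    ec50 <- 10 ^ (hi - (hi - lo) * potency)
    ids <- sprintf("CPD-%04d", seq_len(config$n_compounds))
    df <- dplyr::bind_cols(tibble::tibble(compound_id = ids),
                           tibble::as_tibble(as.data.frame(x)))
    list(
      descriptors = as_descriptor_table(df, provenance = "synthetic"),
      truth = structure(list(informative_idx = informative, weights = w,
                             potency = potency, ec50 = ec50,
                             compound_id = ids),
                        class = "mgo_ground_truth")
    )
  })
}

# Noise-free Hill-type dose response of one compound at concentration c (uM).
hill_response <- function(potency, ec50, conc, h) {
  potency * conc ^ h / (conc ^ h + ec50 ^ h)
}

#' Generate synthetic assay records from ground truth
#'
#' Raw activity is `potency * c^h / (c^h + EC50^h) + Normal(0, noise_sd)` —
#' monotone increasing in concentration at zero noise. When
#' `config$records_total` is set, each compound receives either
#' `floor(records_total / n)` or one more concentration, sampled without
#' replacement from the grid, so the table has exactly `records_total` rows.
#' Otherwise every compound is measured on the full grid. Activities are
#' emitted raw; Z-scaling into activity scores is always done downstream by
#' [fit_normalization()]/[apply_normalization()] so the production path is
#' exercised.
#'
#' @param compounds Descriptor table from [generate_compounds()].
#' @param truth Matching `mgo_ground_truth`.
#' @param config The same [synth_config()].
#' @return An `mgo_assays` tibble.
#' @export
generate_assays <- function(compounds, truth, config) {
  if (!identical(compounds$compound_id, truth$compound_id)) {
    stopf("compounds and ground truth are inconsistent")
  }
  grid <- config$concentration_grid
  n <- length(truth$compound_id)
  with_seed(child_seed(config$seed, "assays"), {
    if (is.null(config$records_total)) {
      per <- rep(length(grid), n)
    } else {
      base <- config$records_total %/% n
      extra <- config$records_total %% n
      if (base < 1 || base + 1 > length(grid)) {
        stopf("records_total (%d) implies %d–%d concentrations per compound; grid has %d",
              config$records_total, base, base + (extra > 0), length(grid))
      }
      per <- rep(base, n)
      if (extra > 0) per[sample.int(n, extra)] <- base + 1
    }
    rows <- purrr::map(seq_len(n), function(i) {
      conc <- sort(sample(grid, per[i]))
      mu <- hill_response(truth$potency[i], truth$ec50[i], conc,
                          config$hill_coefficient)
      tibble::tibble(compound_id = truth$compound_id[i],
                     concentration_uM = conc,
                     activity = mu + rnorm(length(conc), sd = config$noise_sd))
    })
    as_assay_table(dplyr::bind_rows(rows), descriptors = compounds)
  })
}

#' Generate a labeled independent-validation set from ground truth
#'
#' Labels a compound active iff its latent potency is at or above the given
#' cutoff, emulating a literature-curated set of known scavengers and
#' non-scavengers.
#'
#' @param compounds Descriptor table.
#' @param truth Matching ground truth.
#' @param threshold Potency cutoff in (0, 1), or `NULL` with
#'   `inactive_fraction` to place the cutoff at a potency quantile.
#' @param inactive_fraction When `threshold` is `NULL`: fraction labeled
#'   inactive (cutoff at this potency quantile, type-1 so class counts are
#'   exact).
#' @return A tibble `compound_id`, `active` (0/1), `potency`; attribute
#'   `one_class` flags an all-one-class output (ROC undefined downstream).
#' @export
generate_labeled_set <- function(compounds, truth, threshold = NULL,
                                 inactive_fraction = 11 / 61) {
  if (is.null(threshold)) {
    threshold <- quantile(truth$potency, inactive_fraction, type = 1) +
      .Machine$double.eps
  }
  active <- as.integer(truth$potency >= threshold)
  if (length(unique(active)) < 2) {
    warn("labeled set has a single class; ROC analysis will be undefined")
  }
  out <- tibble::tibble(compound_id = truth$compound_id, active = active,
                        potency = truth$potency)
  attr(out, "one_class") <- length(unique(active)) < 2
  attr(out, "threshold") <- threshold
  out
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Emits the same CSV dialects the readers consume: a descriptor CSV
#' (identifier column `Name`), an assay CSV (`compound_id`,
#' `concentration_uM`, `activity`), optionally a labeled-set CSV, and the
#' ground truth as JSON for test assertions.
#'
#' @param dir Output directory (created if needed).
#' @param config An [synth_config()].
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_dataset <- function(dir, config = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- generate_compounds(config)
  assays <- generate_assays(cmp$descriptors, cmp$truth, config)
  labeled <- generate_labeled_set(cmp$descriptors, cmp$truth)
  paths <- list(descriptors = file.path(dir, "descriptors.csv"),
                assays = file.path(dir, "assays.csv"),
                labels = file.path(dir, "labels.csv"),
                truth = file.path(dir, "ground_truth.json"))
  desc_out <- dplyr::rename(tibble::as_tibble(cmp$descriptors), Name = "compound_id")
  readr::write_csv(desc_out, paths$descriptors)
  readr::write_csv(tibble::as_tibble(assays), paths$assays)
  readr::write_csv(labeled[c("compound_id", "active")], paths$labels)
  jsonlite::write_json(unclass(cmp$truth), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
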