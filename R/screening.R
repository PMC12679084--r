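#' Virtually screen compounds over a concentration grid
#'
#' Scores every (compound, concentration) pair with a trained model, ranks
#' all pairs descending by predicted activity score (rank 1 = best; ties
#' broken lexicographically by compound id then concentration), and calls
#' activity at a score cutoff (strict `score > cutoff`). The default grid is
#' 100, 400, 500, 1000 µM.
#'
#' @param model A trained `mgo_deepmgo`.
#' @param compounds Descriptor table of candidate compounds.
#' @param grid Concentrations in µM.
#' @param cutoff Activity-call cutoff on the score scale; the reference
#'   screen uses -0.186.
#' @return A tibble of class `mgo_screen`: `compound_id`,
#'   `concentration_uM`, `score`, `rank`, `active`; attributes `cutoff_used`,
#'   `concentration_grid`, `per_compound` (each compound's best score and
#'   concentration).
#' @export
screen_compounds <- function(model, compounds, grid = c(100, 400, 500, 1000),
                             cutoff = -0.186) {
  if (length(grid) == 0) stopf("concentration grid is empty")
  if (any(grid <= 0)) stopf("concentrations must be positive")
  rows <- tidyr::expand_grid(compound_id = compounds$compound_id,
                             concentration_uM = as.double(grid))
  idx <- match(rows$compound_id, compounds$compound_id)
  rows$score <- unname(predict_scores(model, compounds[idx, ],
                                      rows$concentration_uM))
  rows <- dplyr::arrange(rows, dplyr::desc(.data$score), .data$compound_id,
                         .data$concentration_uM)
  rows$rank <- seq_len(nrow(rows))
  rows$active <- classify_active(rows$score, cutoff)
  per_compound <- rows |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::slice_min(.data$rank, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rank)
  structure(rows, class = c("mgo_screen", class(rows)),
            cutoff_used = cutoff, concentration_grid = as.double(grid),
            per_compound = per_compound)
}

#' Call activity at a score cutoff
#'
#' `1` iff `score > cutoff`, strictly: a score exactly at the cutoff is
#' inactive.
#'
#' @param scores Numeric activity scores (finite).
#' @param cutoff Score cutoff; default -0.186, the reference screen's value.
#' @return Integer 0/1 vector.
#' @export
classify_active <- function(scores, cutoff = -0.186) {
  if (!all(is.finite(scores))) stopf("scores must be finite")
  as.integer(scores > cutoff)
}

#' Top-ranked rows of a screening result
#'
#' @param result An `mgo_screen` from [screen_compounds()].
#' @param top_k Number of rows to keep (>= 1); if larger than the table, all
#'   rows are returned with a note.
#' @return Tibble of the `top_k` best-ranked rows.
#' @export
rank_candidates <- function(result, top_k) {
  if (nrow(result) == 0) stopf("screening result is empty")
  if (top_k < 1) stopf("top_k must be >= 1")
  if (top_k > nrow(result)) {
    inform(sprintf("top_k = %d exceeds the %d screened rows; returning all",
                   top_k, nrow(result)))
    top_k <- nrow(result)
  }
  out <- dplyr::slice_min(tibble::as_tibble(result), .data$rank, n = top_k,
                          with_ties = FALSE)
  dplyr::arrange(out, .data$rank)
}
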