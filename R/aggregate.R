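#' Aggregate tile probabilities into a patient-level MSI score
#'
#' The patient score is the fraction of the patient's tiles whose
#' MSI probability strictly exceeds the tile-level threshold (default
#' 0.5). Tiles from all of a patient's slides are pooled before
#' aggregation. A tile scoring exactly at the threshold does not count
#' toward the numerator; the comparison is strictly greater and is
#' configurable via `strict`.
#'
#' @param p_msi numeric vector of tile-level MSI probabilities.
#' @param tile_threshold tile-level decision threshold (default 0.5).
#' @param patient_id,cohort_id identifiers carried into the result.
#' @param label optional binary patient label (1 = MSI/dMMR).
#' @param strict logical; `TRUE` (default) counts tiles with
#'   `p > threshold`, `FALSE` counts `p >= threshold`.
#' @return One-row data frame: `patient_id`, `cohort_id`, `n_tiles`,
#'   `score`, `label`.
#' @export
aggregate_patient <- function(p_msi, tile_threshold = 0.5,
                              patient_id = "patient", cohort_id = NA_character_,
                              label = NA_integer_, strict = TRUE) {
  if (length(p_msi) < 1L)
    stop("patient '", patient_id, "' has no tiles after quality control; ",
         "flagged unevaluable", call. = FALSE)
  stopifnot(all(p_msi >= 0 & p_msi <= 1))
  hits <- if (strict) sum(p_msi > tile_threshold) else sum(p_msi >= tile_threshold)
  data.frame(patient_id = as.character(patient_id),
             cohort_id = as.character(cohort_id),
             n_tiles = length(p_msi),
             score = hits / length(p_msi),
             label = as.integer(label),
             stringsAsFactors = FALSE)
}
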