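#' Score thresholds for edema classification
#'
#' Defaults follow the cohort-derived operating points: the Cerebral Edema
#' Score (CES) is the series-averaged proportion of intracranial pixels with
#' HU 17--24, called severe at `>= 16.03`\% and flagged for delayed-edema
#' risk at `>= 16.29`\%; the mortality score (mCES) is the HU 19--23
#' proportion, flagged at `>= 15.27`\%. An alternative CES cutoff of 22.58
#' has also circulated for the same operating characteristics; it is
#' selectable here but not the default.
#'
#' @param ces_band,mces_band Integer length-2 inclusive HU bands.
#' @param ces_cutoff,delayed_cutoff,mces_cutoff Percent cutoffs in (0, 100).
#' @return A list of class `score_thresholds`.
#' @export
score_thresholds <- function(ces_band = c(17L, 24L), ces_cutoff = 16.03,
                             delayed_cutoff = 16.29,
                             mces_band = c(19L, 23L), mces_cutoff = 15.27) {
  stopifnot(length(ces_band) == 2L, length(mces_band) == 2L)
  cuts <- c(ces_cutoff, delayed_cutoff, mces_cutoff)
  if (any(cuts <= 0 | cuts >= 100)) {
    ctces_abort("Cutoffs must lie in (0, 100).", "ctces_error_bounds")
  }
  structure(list(ces_band = as.integer(ces_band), ces_cutoff = ces_cutoff,
                 delayed_cutoff = delayed_cutoff,
                 mces_band = as.integer(mces_band), mces_cutoff = mces_cutoff),
            class = "score_thresholds")
}

#' Cerebral Edema Score (CES) and mortality score (mCES)
#'
#' CES is the proportion of intracranial pixels with HU 17--24 in a
#' distribution; mCES uses the nested band HU 19--23, so `mCES <= CES`
#' always.
#'
#' @param dist A `density_distribution`.
#' @param band Inclusive HU band (override for sensitivity analyses).
#' @return A percentage in `[0, 100]`.
#' @export
compute_ces <- function(dist, band = c(17L, 24L)) {
  band_proportion(dist, band[1], band[2])
}

#' @rdname compute_ces
#' @export
compute_mces <- function(dist, band = c(19L, 23L)) {
  band_proportion(dist, band[1], band[2])
}

#' Classify a score against a cutoff
#'
#' Ties classify positive: the verdict is `"at_or_above"` iff
#' `score >= cutoff`.
#'
#' @param score,cutoff Percentages in `[0, 100]`.
#' @return `"below"` or `"at_or_above"`.
#' @export
classify_score <- function(score, cutoff) {
  stopifnot(all(score >= 0 & score <= 100), all(cutoff >= 0 & cutoff <= 100))
  ifelse(score >= cutoff, "at_or_above", "below")
}

#' Score one subject
#'
#' Computes CES and mCES from a series-level distribution and applies all
#' three thresholds: severity (CES cutoff), delayed-edema risk (delayed
#' cutoff on CES) and mortality risk (mCES cutoff).
#'
#' @param dist A series- or group-level `density_distribution`.
#' @param thresholds A [score_thresholds()].
#' @param subject_id Subject identifier carried into the report.
#' @return One-row tibble of class `edema_score`: subject_id, ces, mces and
#'   the three verdicts.
#' @export
score_subject <- function(dist, thresholds = score_thresholds(),
                          subject_id = "unknown") {
  stopifnot(inherits(dist, "density_distribution"))
  if (dist_level(dist) == "slice") {
    ctces_abort("Subject scoring needs a series-level distribution; average the slices first.",
                "ctces_error_level")
  }
  ces <- compute_ces(dist, thresholds$ces_band)
  mces <- compute_mces(dist, thresholds$mces_band)
  out <- tibble(
    subject_id = subject_id, ces = ces, mces = mces,
    verdict_severity = ifelse(ces >= thresholds$ces_cutoff, "severe", "mild"),
    verdict_delayed_risk = ifelse(ces >= thresholds$delayed_cutoff, "high", "low"),
    verdict_mortality_risk = ifelse(mces >= thresholds$mces_cutoff, "high", "low"))
  class(out) <- c("edema_score", class(out))
  out
}

#' Score every subject of a cohort
#'
#' @param series_dists Named list of series-level distributions (names are
#'   subject ids).
#' @param thresholds A [score_thresholds()].
#' @return Tibble with one `edema_score` row per subject.
#' @export
score_cohort <- function(series_dists, thresholds = score_thresholds()) {
  ids <- names(series_dists) %||% as.character(seq_along(series_dists))
  dplyr::bind_rows(purrr::map2(series_dists, ids,
                               function(d, id) score_subject(d, thresholds, id)))
}
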