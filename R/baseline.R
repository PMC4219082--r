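#' Baseline counts of the reference pediatric TBI cohort
#'
#' Published baseline characteristics of the 70-patient pediatric traumatic
#' brain injury cohort on which the default CES/mCES cutoffs were derived:
#' counts by edema severity group for deaths, delayed-edema conversions,
#' trauma mechanism and Marshall grade. These printed counts are inputs for
#' worked examples (group percentages, categorical tests); no image data are
#' involved.
#'
#' @return Tibble with columns `variable`, `total`, `mild`, `severe`.
#' @export
#' @examples
#' b <- cohort_baseline()
#' subset(b, variable == "deaths")
cohort_baseline <- function() {
  readr::read_csv(system.file("extdata", "cohort_baseline_counts.csv",
                              package = "ctces"),
                  show_col_types = FALSE)
}
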