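## Bundled reference tables (plain-text CSV under inst/extdata).

#' Reference ACA donor cohort: arterial dimensions by neuropathological stage
#'
#' Per-segment records of a human anterior cerebral artery donor cohort:
#' donor age, sex, neurofibrillary-tangle stage group (control, early,
#' intermediate, advanced) and the measured wall thickness and inner/outer
#' diameters (mm). Several segments may come from the same donor, so
#' dimension averages are taken over segments while age averages are taken
#' over donors (see [cohortSummary()]).
#'
#' @return A cohort data.frame (see [validateCohortTable()] for columns).
#' @examples
#' cohortSummary(acaCohort(), "inner_diameter_mm")
#' @export
acaCohort <- function() {
  path <- system.file("extdata", "aca_cohort_dimensions.csv",
                      package = "arteryMech", mustWork = TRUE)
  validateCohortTable(read.csv(path, stringsAsFactors = FALSE))
}

#' Reference collagen composition summary
#'
#' Group-level relative abundances (percent of total collagen, mean and SD)
#' of the collagen types quantified by label-free proteomics in the control
#' and advanced-disease ACA groups, with the significance flag after
#' Bonferroni-corrected t-tests.
#'
#' @return data.frame with columns `type`, `control_mean_pct`,
#'   `control_sd_pct`, `ad_mean_pct`, `ad_sd_pct`, `significant`.
#' @export
collagenSummary <- function() {
  path <- system.file("extdata", "collagen_abundance_summary.csv",
                      package = "arteryMech", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
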