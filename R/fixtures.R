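#' Packaged CBCT cohort organ-dose fixtures
#'
#' Loads the packaged per-cohort, per-acquisition-mode organ equivalent-dose
#' table (cohort means of 15 radiotherapy patients each for a lung-cancer
#' and a liver-cancer cohort, under 3D-CBCT thorax, 3D-CBCT pelvis and
#' 4D-CBCT acquisition modes). The thyroid lies outside the imaged range of
#' the liver cohort and is absent from its tables.
#'
#' @param cohort `"lung"` or `"liver"`.
#' @param mode `"thorax"`, `"pelvis"` or `"fourD"`.
#' @return An [organ_dose_table()] with a `volume_cm3` column.
#' @export
#' @examples
#' cbct_dose_fixture("lung", "fourD")
cbct_dose_fixture <- function(cohort = c("lung", "liver"),
                              mode = c("thorax", "pelvis", "fourD")) {
  cohort <- match.arg(cohort)
  mode <- match.arg(mode)
  path <- system.file("extdata", "organ_equivalent_doses.tsv",
                      package = "cbctrisk", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df <- df[df$cohort == cohort & df$mode == mode, , drop = FALSE]
  organ_dose_table(df$organ_id, df$mean_dose_mGy, df$volume_cm3)
}

#' Packaged organ-dose dispersion (cohort SDs)
#'
#' Companion to [cbct_dose_fixture()]: the between-patient standard
#' deviations of the packaged cohort mean doses, for report formatting.
#'
#' @inheritParams cbct_dose_fixture
#' @return data.frame with columns `organ_id`, `sd_mGy`.
#' @export
cbct_dose_fixture_sd <- function(cohort = c("lung", "liver"),
                                 mode = c("thorax", "pelvis", "fourD")) {
  cohort <- match.arg(cohort)
  mode <- match.arg(mode)
  path <- system.file("extdata", "organ_equivalent_doses.tsv",
                      package = "cbctrisk", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df <- df[df$cohort == cohort & df$mode == mode, c("organ_id", "sd_mGy")]
  row.names(df) <- NULL
  df
}
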