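#' Clinical and clonality summary of the 22-case whole-genome NAI cohort
#'
#' The packaged per-case summary table of the neoadjuvant
#' aromatase-inhibitor (NAI) whole-genome cohort: age, intrinsic subtype at
#' baseline and surgery, proportion of Ki67-positive cells at both time
#' points, Ki67-defined response label, ER Allred scores, the published
#' clonal instability index (missing for the three cases whose clonal
#' architecture required manual review), clone counts where reported,
#' collision-tumour status, and the `manual_pattern` override for the
#' manually assigned cases.
#'
#' @return A tibble with one row per case.
#' @examples
#' clin <- nai_cohort_clinical()
#' cohort_summary(dplyr::mutate(clin, pattern = classify_pattern(
#'   clin$collision, clin$n_clones, clin$instability_index,
#'   clin$manual_pattern)))
#' @export
nai_cohort_clinical <- function() {
  path <- system.file("extdata", "nai_cohort_clinical.csv",
                      package = "clonaldrift", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    case = readr::col_character(),
                    collision = readr::col_logical(),
                    manual_pattern = readr::col_character(),
                    subtype_bl = readr::col_character(),
                    subtype_surg = readr::col_character(),
                    ki67_response = readr::col_character(),
                    .default = readr::col_double()))
}

#' Druggable mutations from the targeted panel of the extension cohort
#'
#' The packaged table of clinically actionable mutations (ERBB2, ESR1,
#' PIK3CA) observed by targeted panel sequencing of baseline and
#' post-treatment samples, with VAFs in percent and Ki67 response labels.
#' Useful for per-gene VAF-shift screening (see [gene_vaf_shift()]).
#'
#' @return A tibble with one row per mutation.
#' @export
nai_panel_druggable <- function() {
  path <- system.file("extdata", "nai_panel_druggable.csv",
                      package = "clonaldrift", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = readr::col_character(),
                    wgs_case = readr::col_character(),
                    gene = readr::col_character(),
                    aa_change = readr::col_character(),
                    ki67_response = readr::col_character(),
                    .default = readr::col_double()))
}
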