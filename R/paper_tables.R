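#' Published validation tables used as pipeline inputs
#'
#' The western-blot densitometry table, the promoter-methylation vs
#' expression counts and the cohort cross-sectional 2x2 tables were
#' published as printed tables; they are the inputs to the validation-assay
#' and cross-sectional statistics and are reproduced here verbatim as the
#' deterministic "published mode" of the data layer (the synthetic
#' generators emulate their structure for everything the study did not
#' print).
#'
#' @name published_tables
NULL

#' Western-blot densitometry of UCH-L1 against beta-actin
#'
#' Band intensities (density units) for six tumors, one paired para-tumor
#' tissue and three normal pancreatic tissues, with the published
#' UCH-L1/beta-actin ratios and IHC calls.
#'
#' @return data.frame with `sample_id`, `group`, `uchl1`, `actin`,
#'   `ratio` (as printed, 2 decimals) and `ihc_call`.
#' @export
wb_densitometry_table <- function() {
  data.frame(
    sample_id = c("#4", "#289", "#44", "#290", "#67", "#5",
                  "#5N", "Nor#1", "Nor#2", "Nor#3"),
    group = c(rep("tumor", 6), "para_tumor", rep("normal", 3)),
    uchl1 = c(1450, 492, 4660, 713, 171, 434, 32, 0, 0, 0),
    actin = c(1224, 459, 5835, 880, 1335, 1267, 777, 631, 458, 365),
    ratio = c(1.18, 1.07, 0.79, 0.81, 0.13, 0.34, 0.04, 0, 0, 0),
    ihc_call = c(rep("positive", 6), rep("negative", 4)),
    stringsAsFactors = FALSE
  )
}

#' UCH-L1 promoter demethylation vs protein expression (2x2)
#'
#' Demethylation (unmethylated band present) was seen in 13 of 13
#' expressing samples and 9 of 20 non-expressing samples; rows are
#' expression positive/negative, columns demethylation present/absent.
#'
#' @return A `contingency_2x2`.
#' @export
msp_demethylation_table <- function() contingency_2x2(13, 0, 9, 11)

#' UCH-L1 promoter methylation vs protein expression (2x2)
#'
#' The methylated band was present in 3 of 13 expressing and 20 of 20
#' non-expressing samples.
#'
#' @return A `contingency_2x2`.
#' @export
msp_methylation_table <- function() contingency_2x2(3, 10, 20, 0)

#' The published 8.3-fold worked example
#'
#' UCH-L1/beta-actin ratios for tumor #5 and its paired tissue #5N.
#'
#' @return Named numeric vector `c(tumor = 0.342, para_tumor = 0.041)`.
#' @export
wb_fold_example <- function() c(tumor = 0.342, para_tumor = 0.041)

#' Cross-sectional 2x2 tables for concurrent marker status
#'
#' Counts of patients by concurrent UCH-L1/alpha-internexin expression
#' (columns present/absent) for the published outcome rows: death of
#' disease among patients with known survival (1/59 present vs 37/133
#' absent), recurrence (4/57 vs 59/108) and disease-free survival at last
#' follow-up (57/3 vs 106/62).
#'
#' @return Named list of `contingency_2x2`: `death`, `recurrence`,
#'   `disease_free_survival`.
#' @export
outcome_marker_tables <- function() {
  list(
    # rows: dead / alive; columns: concurrent present / absent
    death = contingency_2x2(1, 37, 59, 133),
    # rows: recurrence yes / no
    recurrence = contingency_2x2(4, 59, 57, 108),
    # rows: disease-free / disease-or-death
    disease_free_survival = contingency_2x2(57, 106, 3, 62)
  )
}

#' Published cohort stage distribution
#'
#' @return Named integer vector of patients per ENETS stage (n = 305 with
#'   known stage).
#' @export
stage_distribution <- function() {
  c(I = 95L, IIa = 98L, IIb = 34L, III = 31L, IV = 47L)
}
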