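#' Western-blot densitometry, IHC scoring and MSP call handling
#'
#' Band intensities are normalized to a loading control (beta-actin);
#' tumor vs control ratio groups are compared with the exact Mann-Whitney
#' test. Immunohistochemistry positivity follows the <20% rule: fewer than
#' 20% stained tumor cells is negative expression (the (+/-) category is
#' merged into negative), 20% or more is positive. Methylation-specific
#' PCR yields two band indicators per sample — methylated (M) and
#' unmethylated (U) — and both may be present in one sample
#' (heterogeneous/hemi-methylation); a sample with neither band is an
#' invalid MSP result.
#'
#' @name assay_validation
NULL

#' Band intensity ratio against the loading control
#'
#' Full precision is retained; display rounding (2 decimals, as ratio
#' tables are conventionally printed) is left to [report_round()].
#'
#' @param target_intensity Non-negative density units.
#' @param control_intensity Positive density units of the loading control.
#' @return `target_intensity / control_intensity` (vectorized).
#' @examples
#' band_ratio(1450, 1224)  # 1.1846..., prints as 1.18
#' @export
band_ratio <- function(target_intensity, control_intensity) {
  if (any(control_intensity == 0)) {
    stop("undefined ratio: loading-control intensity is zero",
         call. = FALSE)
  }
  if (any(target_intensity < 0) || any(control_intensity < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  target_intensity / control_intensity
}

#' Fold difference between two control-normalized ratios
#'
#' @param ratio_a,ratio_b Ratios (e.g. tumor and its paired tissue);
#'   `ratio_b` must be positive.
#' @return `ratio_a / ratio_b`; conventionally reported at 1 decimal.
#' @examples
#' fold_between(0.342, 0.041)  # 8.34..., prints as 8.3-fold
#' @export
fold_between <- function(ratio_a, ratio_b) {
  if (any(ratio_b == 0)) {
    stop("undefined fold: reference ratio is zero", call. = FALSE)
  }
  ratio_a / ratio_b
}

#' Round a value to its reporting precision
#'
#' @param x Numeric.
#' @param digits Decimals (2 for band ratios, 1 for folds).
#' @return `round(x, digits)`.
#' @export
report_round <- function(x, digits) round(x, digits)

#' Compare two groups of band ratios (exact Mann-Whitney)
#'
#' @param group1,group2 Non-empty numeric ratio vectors.
#' @param max_exact_n Passed to [mann_whitney_exact()].
#' @return A `pnet_test_result` (U statistic, exact two-sided p for small
#'   samples).
#' @export
compare_ratio_groups <- function(group1, group2, max_exact_n = 20) {
  mann_whitney_exact(group1, group2, max_exact_n = max_exact_n)
}

#' IHC positivity call from percent stained tumor cells
#'
#' @param percent_positive_cells Value(s) in [0, 100]; `NA` propagates.
#' @return `"negative"` when < 20, `"positive"` when >= 20.
#' @export
classify_ihc <- function(percent_positive_cells) {
  p <- as.numeric(percent_positive_cells)
  if (any(!is.na(p) & (p < 0 | p > 100))) {
    stop("percent stained cells must be in [0,100]", call. = FALSE)
  }
  ifelse(is.na(p), NA_character_, ifelse(p < 20, "negative", "positive"))
}

#' Project MSP band calls onto methylation/demethylation presence
#'
#' @param record List or one-row data.frame with logical `methylated_band`
#'   and `unmethylated_band`.
#' @return List with `methylation_present` and `demethylation_present`
#'   (presence of the U band is read as promoter demethylation).
#' @export
msp_category <- function(record) {
  m <- isTRUE(as.logical(record$methylated_band))
  u <- isTRUE(as.logical(record$unmethylated_band))
  if (!m && !u) {
    stop("invalid MSP result: neither methylated nor unmethylated band",
         call. = FALSE)
  }
  list(methylation_present = m, demethylation_present = u)
}

#' Association between a promoter band call and protein expression
#'
#' Builds the 2x2 table of band presence (rows: present/absent) against
#' expression (columns: positive/negative) and applies the two-sided
#' Fisher exact test.
#'
#' @param records data.frame of MSP calls with columns `methylated_band`,
#'   `unmethylated_band` and `expression` (`positive`/`negative`).
#' @param band `"demethylation"` (U band, default) or `"methylation"`
#'   (M band).
#' @return List with the `contingency_2x2` and the Fisher `pnet_test_result`.
#' @export
msp_expression_association <- function(records,
                                       band = c("demethylation",
                                                "methylation")) {
  band <- match.arg(band)
  invalid <- !records$methylated_band & !records$unmethylated_band
  if (any(invalid)) {
    stop("invalid MSP result in row(s) ",
         paste(which(invalid), collapse = ", "), call. = FALSE)
  }
  present <- if (band == "demethylation") records$unmethylated_band else
    records$methylated_band
  pos <- records$expression == "positive"
  tab <- contingency_2x2(sum(present & pos), sum(present & !pos),
                         sum(!present & pos), sum(!present & !pos))
  list(table = tab, test = fisher_exact_2x2(tab))
}
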