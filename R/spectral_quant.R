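#' NSAF/ppm label-free quantification and paired differential expression
#'
#' Spectral counts are converted to normalized spectral abundance factors,
#' NSAF_N = (S_N / L_N) / sum_i (S_i / L_i), where S is the spectral count
#' and L the protein length in residues; NSAF values lie in [0, 1] and sum
#' to 1 within a sample. For readability each profile is rescaled to parts
#' per million (sum 1,000,000). Tumor vs para-tumor differences are then
#' assessed per protein with a two-sided paired t-test on log2(ppm +
#' pseudocount) across pairs, with the Tu/Nor fold-change ratio capped so
#' proteins detected only in one condition keep a finite log2 fold change.
#'
#' @name spectral_quant
NULL

#' Filter proteins by unique-peptide support
#'
#' The conventional identification filter: keep proteins whose number of
#' distinct supporting peptides is at least `min_unique`. Row order is
#' preserved.
#'
#' @param x A `spectral_count_matrix`.
#' @param min_unique Non-negative integer cutoff (default 2, the
#'   two-peptide rule).
#' @return The filtered `spectral_count_matrix`.
#' @export
filter_by_unique_peptides <- function(x, min_unique = 2) {
  stopifnot(inherits(x, "spectral_count_matrix"), min_unique >= 0)
  keep <- x$proteins$unique_peptides >= min_unique
  spectral_count_matrix(x$proteins[keep, , drop = FALSE],
                        x$counts[keep, , drop = FALSE],
                        x$samples)
}

#' NSAF profile for one sample
#'
#' @param x A `spectral_count_matrix` (already filtered as desired; the
#'   normalization denominator runs over its proteins).
#' @param sample_id A sample present in `x`.
#' @return An `abundance_profile`: list with `sample_id`, `nsaf` and `ppm`
#'   (named numeric vectors over proteins).
#' @export
compute_nsaf <- function(x, sample_id) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  if (!sample_id %in% colnames(x$counts)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  s <- x$counts[, sample_id]
  if (all(s == 0)) {
    stop("degenerate sample ", sample_id, ": all spectral counts zero, ",
         "NSAF undefined", call. = FALSE)
  }
  saf <- s / x$proteins$length_aa
  nsaf <- saf / sum(saf)
  names(nsaf) <- x$proteins$protein_id
  structure(list(sample_id = sample_id, nsaf = nsaf, ppm = nsaf * 1e6),
            class = "abundance_profile")
}

#' Rescale an NSAF profile to parts per million
#'
#' @param profile An `abundance_profile`.
#' @return The profile with `ppm = nsaf * 1e6` (sum 1,000,000).
#' @export
nsaf_to_ppm <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  profile$ppm <- profile$nsaf * 1e6
  profile
}

#' NSAF/ppm profiles for every sample
#'
#' @param x A `spectral_count_matrix`.
#' @return Named list of `abundance_profile`, one per sample.
#' @export
abundance_profiles <- function(x) {
  stats::setNames(lapply(x$samples$sample, function(s) compute_nsaf(x, s)),
                  x$samples$sample)
}

#' Paired tumor vs para-tumor differential expression
#'
#' Per protein: the Tu/Nor ratio is the mean tumor ppm over the mean
#' para-tumor ppm; when the para-tumor mean is zero the ratio is reported
#' capped at `ratio_cap` with `regulation = "tumor_only"` (symmetrically
#' `1/ratio_cap` and `"para_only"`), and any finite ratio beyond the cap is
#' clamped with the `ratio_capped` flag set so log2 fold changes stay
#' finite. The p-value is a two-sided paired t-test on
#' `log2(ppm + pseudo_ppm)` across pairs; a protein with identical values
#' in every pair gets p = 1 (no evidence under the permutation-symmetric
#' null).
#'
#' @param profiles Named list of `abundance_profile` covering every sample.
#' @param samples Sample sheet data.frame (`sample`, `condition`,
#'   `pair_id`) defining the pairing.
#' @param pseudo_ppm Positive pseudocount added before log2 (default 1).
#' @param ratio_cap Positive ratio cap (default 500).
#' @return data.frame of per-protein differential records: `protein_id`,
#'   `mean_tumor_ppm`, `mean_para_ppm`, `ratio`, `ratio_capped`, `log2fc`,
#'   `p_value`, `neg_log10_p`, `regulation` (only the detection classes
#'   `tumor_only`/`para_only` are set here; see [classify_regulation()]).
#' @export
paired_differential <- function(profiles, samples, pseudo_ppm = 1,
                                ratio_cap = 500) {
  stopifnot(pseudo_ppm > 0, ratio_cap > 0)
  pairing <- split(samples, samples$pair_id)
  if (length(pairing) < 2) {
    stop("insufficient replication: need at least 2 complete pairs",
         call. = FALSE)
  }
  tum <- par <- character(length(pairing))
  for (i in seq_along(pairing)) {
    p <- pairing[[i]]
    t_s <- p$sample[p$condition == "tumor"]
    p_s <- p$sample[p$condition == "para_tumor"]
    if (length(t_s) != 1 || length(p_s) != 1) {
      stop("pairing error: pair ", p$pair_id[1],
           " lacks a tumor/para_tumor sample", call. = FALSE)
    }
    tum[i] <- t_s; par[i] <- p_s
  }
  missing <- setdiff(c(tum, par), names(profiles))
  if (length(missing)) {
    stop("pairing error: no profile for sample(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tum_ppm <- vapply(profiles[tum], `[[`,
                    numeric(length(profiles[[tum[1]]]$ppm)), "ppm")
  par_ppm <- vapply(profiles[par], `[[`,
                    numeric(length(profiles[[par[1]]]$ppm)), "ppm")
  protein_id <- names(profiles[[tum[1]]]$ppm)
  mean_t <- rowMeans(tum_ppm)
  mean_p <- rowMeans(par_ppm)

  ratio <- mean_t / mean_p
  regulation <- rep("unchanged", length(ratio))
  regulation[mean_p == 0 & mean_t > 0] <- "tumor_only"
  regulation[mean_t == 0 & mean_p > 0] <- "para_only"
  ratio[mean_p == 0 & mean_t == 0] <- 1
  capped <- rep(FALSE, length(ratio))
  hi <- !is.finite(ratio) | ratio > ratio_cap
  lo <- ratio < 1 / ratio_cap
  ratio[hi] <- ratio_cap
  ratio[lo] <- 1 / ratio_cap
  capped[hi | lo] <- TRUE

  # paired t on log2(ppm + pseudocount), per protein
  d <- log2(tum_ppm + pseudo_ppm) - log2(par_ppm + pseudo_ppm)
  k <- ncol(d)
  dbar <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - dbar)^2) / (k - 1))
  p_value <- ifelse(
    sd_d == 0,
    ifelse(dbar == 0, 1, 0),
    2 * stats::pt(-abs(dbar / (sd_d / sqrt(k))), df = k - 1)
  )

  data.frame(
    protein_id = protein_id,
    mean_tumor_ppm = mean_t,
    mean_para_ppm = mean_p,
    ratio = ratio,
    ratio_capped = capped,
    log2fc = log2(ratio),
    p_value = p_value,
    neg_log10_p = -log10(p_value),
    regulation = regulation,
    stringsAsFactors = FALSE
  )
}

#' Classify differential records as up / down / unchanged
#'
#' A protein is called up when its (capped) ratio is at least `min_fold`
#' and p <= `max_p`; down when the ratio is at most `1/min_fold` and p <=
#' `max_p`; otherwise unchanged. Proteins detected only in tumor
#' (`tumor_only`) or only in para-tumor (`para_only`) keep their detection
#' class and are counted with the up and down calls respectively when they
#' pass the p threshold.
#'
#' @param records data.frame from [paired_differential()].
#' @param min_fold Fold-change threshold >= 1 (default 2).
#' @param max_p p-value threshold in (0, 1] (default 0.05).
#' @return List with `records` (regulation column finalized) and `summary`
#'   (`n_up`, `n_down`, `n_unchanged`, counting `tumor_only` as up and
#'   `para_only` as down; the three counts partition the input).
#' @export
classify_regulation <- function(records, min_fold = 2, max_p = 0.05) {
  stopifnot(min_fold >= 1, max_p > 0, max_p <= 1)
  reg <- records$regulation
  finite <- !reg %in% c("tumor_only", "para_only")
  sig <- records$p_value <= max_p
  reg[finite] <- "unchanged"
  reg[finite & sig & records$ratio >= min_fold] <- "up"
  reg[finite & sig & records$ratio <= 1 / min_fold] <- "down"
  records$regulation <- reg
  up <- reg == "up" | (reg == "tumor_only" & sig)
  down <- reg == "down" | (reg == "para_only" & sig)
  list(records = records,
       summary = list(n_up = sum(up), n_down = sum(down),
                      n_unchanged = sum(!up & !down)))
}

#' Volcano-plot coordinates from differential records
#'
#' @param records data.frame from [paired_differential()].
#' @return data.frame with `protein_id`, `log2fc`, `neg_log10_p` and
#'   `regulation`, ready for any plotting tool.
#' @export
volcano_coordinates <- function(records) {
  records[, c("protein_id", "log2fc", "neg_log10_p", "regulation")]
}
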