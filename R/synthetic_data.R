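#' Synthetic data with the statistical structure the pipeline assumes
#'
#' The spectral generator emulates the paired design: four insulinomas and
#' their paired pancreatic tissues, long-tailed protein lengths and
#' baseline abundances, sample-specific sequencing depth, Poisson counts,
#' and a planted subset of truly up-/down-regulated proteins shifted by a
#' known log2 effect in the tumor samples. The cohort generator emulates a
#' 306-patient two-cohort clinical table with category frequencies set to
#' the study's summary proportions, marker prevalence for concurrent
#' UCH-L1/alpha-internexin expression, exponential event times whose
#' hazard is multiplied by a true hazard ratio for marker-present
#' patients, independent censoring, and a small fraction of deaths of
#' unknown cause. All generation is driven by a single integer seed; the
#' same seed gives identical output.
#'
#' @name synthetic_data
NULL

#' Build a simulation specification
#'
#' Defaults are the study conditions: 4 tumor/para-tumor pairs, a
#' 1000-protein desk-scale matrix at 100,000 expected spectra per sample,
#' 10% of proteins planted 4-fold up and 5% 4-fold down in tumors; a
#' 306-patient cohort with Table-1-style category frequencies, 27.9%
#' concurrent-marker prevalence and true hazard ratio 0.2 for
#' marker-present patients on both endpoints.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins,n_pairs Matrix dimensions.
#' @param fraction_up,fraction_down Planted fractions (sum <= 1).
#' @param effect_log2fc Planted log2 effect (4-fold = 2).
#' @param depth_per_sample Expected total spectral counts per sample.
#' @param length_meanlog,length_sdlog Log-normal protein-length parameters
#'   (residues).
#' @param overdispersion NB size parameter; `Inf` (default) gives Poisson
#'   counts — with 4 pairs the design cannot identify overdispersion.
#' @param n_subjects Cohort size.
#' @param marker_prevalence P(concurrent marker present).
#' @param marker_missing_rate P(either marker percentage missing).
#' @param hr_os,hr_dfs True hazard ratios for marker-present.
#' @param base_hazard_dfs,base_hazard_os Marker-absent monthly exponential
#'   hazards for the DFS (recurrence/death) and OS (death) endpoints.
#' @param censor_range Uniform range of last-contact times (months).
#' @param duc_rate Fraction of followed patients dying of unknown cause.
#' @param lost_rate Fraction lost to follow-up.
#' @param n_wb_tumor,n_wb_control Densitometry group sizes.
#' @param wb_shift_log2 Log2 shift of tumor over control band ratios.
#' @param n_msp MSP sample count.
#' @param msp_or Odds ratio linking promoter demethylation to expression.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1,
                            n_proteins = 1000,
                            n_pairs = 4,
                            fraction_up = 0.10,
                            fraction_down = 0.05,
                            effect_log2fc = 2,
                            depth_per_sample = 1e5,
                            length_meanlog = log(450),
                            length_sdlog = 0.5,
                            overdispersion = Inf,
                            n_subjects = 306,
                            marker_prevalence = 0.279,
                            marker_missing_rate = 0.075,
                            hr_os = 0.2,
                            hr_dfs = 0.2,
                            base_hazard_dfs = 0.004,
                            base_hazard_os = 0.0025,
                            censor_range = c(6, 218),
                            duc_rate = 0.04,
                            lost_rate = 0.19,
                            n_wb_tumor = 6,
                            n_wb_control = 4,
                            wb_shift_log2 = 3.5,
                            n_msp = 33,
                            msp_or = 30) {
  spec <- as.list(environment())
  if (spec$fraction_up < 0 || spec$fraction_down < 0 ||
      spec$fraction_up + spec$fraction_down > 1) {
    stop("fractions must be in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (spec$n_pairs < 2) stop("need at least 2 pairs", call. = FALSE)
  if (spec$depth_per_sample <= 0) stop("depth must be positive",
                                       call. = FALSE)
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate a paired tumor/para-tumor spectral-count experiment
#'
#' @param spec A `simulation_spec`.
#' @return A `spectral_count_matrix` with attributes `truth_up` and
#'   `truth_down` (protein ids of the planted effects).
#' @export
simulate_spectral_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    np <- spec$n_proteins; k <- spec$n_pairs
    protein_id <- sprintf("P%05d", seq_len(np))
    len <- pmax(50L, as.integer(round(stats::rlnorm(
      np, spec$length_meanlog, spec$length_sdlog))))
    base <- stats::rlnorm(np, meanlog = 0, sdlog = 1.5)  # long-tailed
    n_up <- round(spec$fraction_up * np)
    n_down <- round(spec$fraction_down * np)
    idx <- sample.int(np, n_up + n_down)
    up <- idx[seq_len(n_up)]
    down <- setdiff(idx, up)
    shift <- rep(1, np)
    shift[up] <- 2^spec$effect_log2fc
    shift[down] <- 2^(-spec$effect_log2fc)

    samples <- data.frame(
      sample = c(sprintf("T%d", seq_len(k)), sprintf("N%d", seq_len(k))),
      condition = rep(c("tumor", "para_tumor"), each = k),
      pair_id = rep(sprintf("pair%d", seq_len(k)), 2),
      stringsAsFactors = FALSE
    )
    depth <- spec$depth_per_sample *
      stats::rlnorm(2 * k, meanlog = 0, sdlog = 0.15)
    counts <- matrix(0L, np, 2 * k,
                     dimnames = list(protein_id, samples$sample))
    for (j in seq_len(2 * k)) {
      a <- if (samples$condition[j] == "tumor") base * shift else base
      mu <- depth[j] * (a * len) / sum(a * len)  # spectra scale with length
      lam <- if (is.finite(spec$overdispersion)) {
        mu * stats::rgamma(np, shape = spec$overdispersion,
                           rate = spec$overdispersion)
      } else mu
      counts[, j] <- stats::rpois(np, lam)
    }
    # unique peptides track abundance (and length) on the log scale
    mean_count <- rowMeans(counts)
    unique_peptides <- pmin(
      stats::rpois(np, 1 + 1.6 * log1p(mean_count)), len %/% 7)
    proteins <- data.frame(protein_id = protein_id, length_aa = len,
                           unique_peptides = as.integer(unique_peptides),
                           stringsAsFactors = FALSE)
    out <- spectral_count_matrix(proteins, counts, samples)
    attr(out, "truth_up") <- protein_id[up]
    attr(out, "truth_down") <- protein_id[down]
    out
  })
}

#' Simulate a clinical cohort
#'
#' Category frequencies default to the study's summary proportions; event
#' times are exponential with the marker-present hazard multiplied by the
#' spec's true hazard ratio; recurrence precedes death of disease;
#' censoring is an independent uniform last-contact time. Statuses are
#' assigned consistently: DOD implies an OS and DFS event, AWD a DFS event
#' only, DFS neither; a `duc_rate` fraction of followed patients become
#' DUC and a `lost_rate` fraction are lost with no usable follow-up.
#'
#' @param spec A `simulation_spec`.
#' @return data.frame of subject records (see [read_cohort_table()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_subjects
    draw <- function(levels, probs) {
      sample(levels, n, replace = TRUE, prob = probs)
    }
    cohort <- draw(c("I", "II"), c(164, 142))
    sex <- draw(c("male", "female"), c(0.425, 0.575))
    age <- round(pmin(85, pmax(15, stats::rnorm(n, 49, 15))))
    subtype <- draw(c("insulinoma", "non_insulinoma"), c(0.493, 0.507))
    functional <- ifelse(
      subtype == "insulinoma", "functional",
      draw(c("functional", "nonfunctional"), c(0.16, 0.84)))
    grade <- draw(c("G1", "G2", "G3", "unknown"),
                  c(0.556, 0.421, 0.024, 0) * 252 / 306 +
                    c(0, 0, 0, 54 / 306))
    stage <- draw(c("I", "IIa", "IIb", "III", "IV", "unknown"),
                  c(95, 98, 34, 31, 47, 1) / 306)
    metastasis <- stage == "IV" | stats::runif(n) < 0.09
    location <- draw(c("head", "body_tail", "non_pancreas", "unknown"),
                     c(127, 165, 12, 2) / 306)
    ki67_class <- draw(c("<=2%", ">2%", "unknown"),
                       c(171, 64, 71) / 306)
    size_cm <- round(pmin(17, pmax(0.7, stats::rlnorm(n, log(2.5), 0.55))),
                     1)

    present <- stats::runif(n) < spec$marker_prevalence
    uchl1 <- ifelse(present, stats::runif(n, 20, 100),
                    ifelse(stats::runif(n) < 0.5,
                           stats::runif(n, 0, 19.9),
                           stats::runif(n, 0, 100)))
    # when not concurrent-present, force at least one marker negative
    inx <- ifelse(present, stats::runif(n, 20, 100),
                  ifelse(uchl1 >= 20, stats::runif(n, 0, 19.9),
                         stats::runif(n, 0, 100)))
    miss_u <- stats::runif(n) < spec$marker_missing_rate / 2
    miss_i <- !miss_u & stats::runif(n) < spec$marker_missing_rate / 2
    uchl1[miss_u] <- NA
    inx[miss_i] <- NA

    t_dfs <- stats::rexp(n, spec$base_hazard_dfs *
                           ifelse(present, spec$hr_dfs, 1))
    t_os <- stats::rexp(n, spec$base_hazard_os *
                          ifelse(present, spec$hr_os, 1))
    censor <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])

    status <- ifelse(t_os <= censor, "DOD",
                     ifelse(t_dfs <= censor, "AWD", "DFS"))
    followup <- round(ifelse(status == "DOD", t_os, censor), 1)

    u <- stats::runif(n)
    lost <- u < spec$lost_rate
    duc <- !lost & u < spec$lost_rate + spec$duc_rate
    status[lost] <- "lost"
    followup[lost] <- NA
    status[duc] <- "DUC"

    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      cohort = cohort, age = age, sex = sex, subtype = subtype,
      functional = functional, grade = grade, stage = stage,
      size_cm = size_cm, ki67_class = ki67_class, metastasis = metastasis,
      location = location,
      uchl1_percent = round(uchl1, 1), inx_percent = round(inx, 1),
      followup_months = followup, status = status,
      stringsAsFactors = FALSE
    )
    validate_subjects(out)
    out
  })
}

#' Recovery of planted differential effects
#'
#' Compares up/down calls against the truth planted by
#' [simulate_spectral_experiment()]. Proteins detected only in one
#' condition count with the corresponding direction when they pass the
#' p threshold used for classification.
#'
#' @param sim_matrix Matrix from [simulate_spectral_experiment()] (carries
#'   `truth_up`/`truth_down`); truth is restricted to proteins present in
#'   `records` (i.e. surviving the unique-peptide filter). May be `NULL`
#'   when `truth_up`/`truth_down` are given explicitly (e.g. after a
#'   round-trip through disk, which drops the attributes).
#' @param records Classified records from [classify_regulation()].
#' @param max_p The p threshold used in classification (default 0.05).
#' @param truth_up,truth_down Planted protein ids; default to the
#'   attributes of `sim_matrix`.
#' @return List with `sensitivity_up`, `sensitivity_down` and `fdp` (the
#'   false-discovery proportion over all up+down calls).
#' @export
recovery_metrics <- function(sim_matrix, records, max_p = 0.05,
                             truth_up = attr(sim_matrix, "truth_up"),
                             truth_down = attr(sim_matrix, "truth_down")) {
  truth_up <- intersect(truth_up, records$protein_id)
  truth_down <- intersect(truth_down, records$protein_id)
  sig <- records$p_value <= max_p
  up_calls <- records$protein_id[records$regulation == "up" |
                                   (records$regulation == "tumor_only" & sig)]
  down_calls <- records$protein_id[records$regulation == "down" |
                                     (records$regulation == "para_only" & sig)]
  calls <- c(up_calls, down_calls)
  list(
    sensitivity_up = if (length(truth_up)) mean(truth_up %in% up_calls)
      else NA_real_,
    sensitivity_down = if (length(truth_down))
      mean(truth_down %in% down_calls) else NA_real_,
    fdp = if (length(calls)) mean(!calls %in% c(truth_up, truth_down))
      else 0
  )
}

#' Simulate bare survival data from an exponential proportional-hazards
#' model
#'
#' A minimal generator for calibration studies: a binary marker at the
#' given prevalence, exponential event times with the marker hazard
#' multiplied by `hr`, and independent uniform censoring.
#'
#' @param n Number of subjects.
#' @param hr True hazard ratio for marker-present.
#' @param prevalence Marker prevalence.
#' @param base_hazard Marker-absent monthly hazard.
#' @param censor_max Upper bound of the uniform censoring time.
#' @param seed Integer seed.
#' @return data.frame with `time`, `event`, `marker` (0/1).
#' @export
simulate_survival_data <- function(n, hr = 1, prevalence = 0.3,
                                   base_hazard = 0.01, censor_max = 120,
                                   seed = 1) {
  withr::with_seed(seed, {
    marker <- as.integer(stats::runif(n) < prevalence)
    t_event <- stats::rexp(n, base_hazard * hr^marker)
    censor <- stats::runif(n, 0, censor_max)
    data.frame(time = pmin(t_event, censor),
               event = as.integer(t_event <= censor),
               marker = marker)
  })
}

#' Simulate western-blot densitometry records
#'
#' Loading-control intensities are log-normal; tumor target/control ratios
#' sit `wb_shift_log2` log2 units above the para-tumor/normal ratios.
#'
#' @param spec A `simulation_spec`.
#' @return data.frame with `sample_id`, `group`, `target` and `control`
#'   band intensities.
#' @export
simulate_densitometry <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed + 2L, {
    nt <- spec$n_wb_tumor; nc <- spec$n_wb_control
    group <- c(rep("tumor", nt),
               rep(c("para_tumor", "normal"), length.out = nc))
    control <- stats::rlnorm(nt + nc, log(800), 0.4)
    base_ratio <- stats::rlnorm(nt + nc, log(0.05), 0.6)
    ratio <- base_ratio * ifelse(group == "tumor", 2^spec$wb_shift_log2, 1)
    data.frame(
      sample_id = sprintf("WB%02d", seq_len(nt + nc)),
      group = group,
      target = round(ratio * control, 1),
      control = round(control, 1),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate methylation-specific PCR calls with linked expression
#'
#' Expression-positive samples carry the unmethylated (demethylated) band
#' with odds `msp_or` times those of expression-negative samples; the
#' methylated band follows the complementary pattern; samples never end up
#' with neither band.
#'
#' @param spec A `simulation_spec`.
#' @return data.frame with `sample_id`, `methylated_band`,
#'   `unmethylated_band`, `expression`.
#' @export
simulate_methylation_calls <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed + 3L, {
    n <- spec$n_msp
    expr <- sample(c("positive", "negative"), n, replace = TRUE,
                   prob = c(13, 20))
    p0 <- 0.45  # demethylation probability when expression is negative
    odds1 <- spec$msp_or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    u_band <- stats::runif(n) < ifelse(expr == "positive", p1, p0)
    m_band <- stats::runif(n) < ifelse(expr == "positive", 0.25, 0.97)
    m_band[!u_band] <- TRUE  # a valid MSP result shows at least one band
    data.frame(
      sample_id = sprintf("MSP%02d", seq_len(n)),
      methylated_band = m_band,
      unmethylated_band = u_band,
      expression = expr,
      stringsAsFactors = FALSE
    )
  })
}
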