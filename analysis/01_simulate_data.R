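#!/usr/bin/env Rscript
# Step 1 — generate the study-shaped inputs.
#
# The raw mass-spectrometry data behind the paired insulinoma experiment
# are not publicly deposited, so the pipeline runs on synthetic inputs
# with the same structure: a 4-pair tumor/para-tumor spectral-count
# matrix with planted differential proteins, and a 306-patient clinical
# cohort with a protective concurrent-marker effect. Everything written
# here is consumed by the later steps.

library(pnetmarkers)

dir.create("results", showWarnings = FALSE)
spec <- simulation_spec(seed = 20170519)

counts <- simulate_spectral_experiment(spec)
write_count_table(counts, "results/spectral_counts.tsv",
                  "results/sample_sheet.tsv")
cat(sprintf("spectral matrix: %d proteins x %d samples (%d planted up, %d down)\n",
            nrow(counts$proteins), nrow(counts$samples),
            length(attr(counts, "truth_up")),
            length(attr(counts, "truth_down"))))
write_results_table(
  data.frame(protein_id = c(attr(counts, "truth_up"),
                            attr(counts, "truth_down")),
             direction = rep(c("up", "down"),
                             c(length(attr(counts, "truth_up")),
                               length(attr(counts, "truth_down"))))),
  "results/planted_truth.tsv")

cohort <- simulate_cohort(spec)
write_cohort_table(cohort, "results/cohort.csv")
cat(sprintf("cohort: %d patients (%d followed up, %d DUC)\n",
            nrow(cohort), sum(cohort$status != "lost"),
            sum(cohort$status == "DUC")))

wb <- simulate_densitometry(spec)
write_results_table(wb, "results/densitometry_synthetic.tsv")
msp <- simulate_methylation_calls(spec)
write_results_table(msp, "results/msp_calls_synthetic.tsv")
cat("wrote synthetic densitometry and MSP call tables\n")
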