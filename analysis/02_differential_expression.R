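#!/usr/bin/env Rscript
# Step 2 — NSAF/ppm quantification and paired differential expression.
#
# Reads the spectral-count matrix from step 1, applies the two-peptide
# identification filter, converts counts to NSAF (and ppm) relative
# abundances, and calls per-protein tumor vs para-tumor changes with a
# paired t-test on log2 ppm, capping Tu/Nor ratios at 500 for proteins
# seen in only one condition. Writes the differential table and
# volcano-plot coordinates.

library(pnetmarkers)

counts <- read_count_table("results/spectral_counts.tsv",
                           "results/sample_sheet.tsv")
filtered <- filter_by_unique_peptides(counts, min_unique = 2)
cat(sprintf("%d of %d proteins pass the unique-peptide filter\n",
            nrow(filtered$proteins), nrow(counts$proteins)))

profiles <- abundance_profiles(filtered)
stopifnot(abs(sum(profiles[[1]]$ppm) - 1e6) < 1e-3)

de <- paired_differential(profiles, filtered$samples,
                          pseudo_ppm = 1, ratio_cap = 500)
cl <- classify_regulation(de, min_fold = 2, max_p = 0.05)
cat(sprintf("regulation summary: %d up, %d down, %d unchanged\n",
            cl$summary$n_up, cl$summary$n_down, cl$summary$n_unchanged))

truth <- read_results_table("results/planted_truth.tsv")
met <- recovery_metrics(NULL, cl$records,
                        truth_up = truth$protein_id[truth$direction == "up"],
                        truth_down = truth$protein_id[truth$direction == "down"])
cat(sprintf("planted-effect recovery: sensitivity(up) %.2f, FDP %.2f\n",
            met$sensitivity_up, met$fdp))

write_results_table(cl$records, "results/differential_table.tsv")
write_results_table(volcano_coordinates(cl$records),
                    "results/volcano_coordinates.tsv")
cat("wrote differential table and volcano coordinates\n")
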