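#!/usr/bin/env Rscript
# Step 3 — validation-assay statistics.
#
# The published densitometry and methylation tables are inputs here: the
# UCH-L1/beta-actin ratio comparison (exact Mann-Whitney), the per-sample
# fold worked example, and the Fisher association between promoter
# demethylation and protein expression. The same statistics are also run
# on the synthetic assay tables from step 1 as a sanity check of the
# generator.

library(pnetmarkers)

wb <- wb_densitometry_table()
tum <- wb$ratio[wb$group == "tumor"]
ctrl <- wb$ratio[wb$group != "tumor"]
mw <- compare_ratio_groups(tum, ctrl)
s_t <- summarize_median_range(tum)
s_c <- summarize_median_range(ctrl)
cat(sprintf("UCH-L1/beta-actin: tumors median %.2g (%.2g-%.2g) vs controls %.2g (%.2g-%.2g), Mann-Whitney p = %.4f\n",
            s_t$median, s_t$min, s_t$max, s_c$median, s_c$min, s_c$max,
            mw$p_value))

ex <- wb_fold_example()
cat(sprintf("tumor #5 vs para-tumor #5N: %.1f-fold\n",
            fold_between(ex[["tumor"]], ex[["para_tumor"]])))

dem <- fisher_exact_2x2(msp_demethylation_table())
cat(sprintf("demethylation x expression: Fisher p = %.4f\n", dem$p_value))

res <- data.frame(
  analysis = c("wb_ratio_mann_whitney", "demethylation_fisher"),
  statistic = c(mw$statistic, dem$statistic),
  p_value = c(mw$p_value, dem$p_value))
write_results_table(res, "results/validation_statistics.tsv")

# synthetic replicates of the same assays
wb_syn <- read_results_table("results/densitometry_synthetic.tsv")
ratio <- band_ratio(wb_syn$target, wb_syn$control)
mw_syn <- compare_ratio_groups(ratio[wb_syn$group == "tumor"],
                               ratio[wb_syn$group != "tumor"])
msp_syn <- read_results_table("results/msp_calls_synthetic.tsv")
assoc <- msp_expression_association(msp_syn, "demethylation")
cat(sprintf("synthetic assays: WB p = %.4f, MSP Fisher p = %.4f\n",
            mw_syn$p_value, assoc$test$p_value))
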