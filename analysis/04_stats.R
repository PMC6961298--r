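#!/usr/bin/env Rscript
# Stage 4: cohort statistics.
#
# Group comparison of the six imaging parameters (pooled-variance t
# tests), covariate tables (chi-square / Fisher), ROC analysis of ADC, D,
# alpha and DDC with Youden cutoffs, paired DeLong comparisons of DDC
# against the other markers, and two-reader agreement (Lin's CCC) on
# simulated repeat measurements. Writes the report tables to results/.

suppressPackageStartupMessages(library(dwiresponse))

seed <- 1234L
tab <- utils::read.csv("results/cohort_parameters.csv")
labels <- utils::read.csv("results/response_labels.csv")
tab$group <- labels$group[match(tab$patient_id, labels$patient_id)]
covars <- utils::read.csv("results/sim/covariates.csv")

params <- c("adc", "d", "d_star", "f", "alpha", "ddc")
gs <- group_comparison_table(tab, params)
utils::write.csv(gs, "results/group_comparison.csv", row.names = FALSE)
cat("== group comparison (mean responders vs non-responders, t-test p) ==\n")
print(cbind(gs[1], round(gs[-1], 4)))

cat("\n== covariate tests ==\n")
for (cv in c("tumor_size_class", "figo_stage", "pathologic_type",
             "histologic_grade")) {
  ct <- categorical_test(table(covars$group, covars[[cv]]))
  cat(sprintf("%-18s %-7s p = %.3f\n", cv, ct$method, ct$p))
}

roc <- roc_parameter_table(tab, c(adc = "lower", d = "lower",
                                  alpha = "higher", ddc = "lower"))
utils::write.csv(roc, "results/roc_table.csv", row.names = FALSE)
cat("\n== ROC (cutoff, AUC, 95% CI, sensitivity, specificity) ==\n")
print(cbind(roc[1], round(roc[2:7], 3), roc[8]))

cmp <- do.call(rbind, lapply(c("adc", "d", "alpha"), function(p) {
  dirs <- c(adc = "lower", d = "lower", alpha = "higher")
  r <- compare_auc(tab$ddc, tab[[p]], tab$group, direction_a = "lower",
                   direction_b = unname(dirs[p]))
  data.frame(comparison = paste0("ddc_vs_", p), auc_ddc = r$auc_a,
             auc_other = r$auc_b, p = r$p)
}))
utils::write.csv(cmp, "results/auc_comparisons.csv", row.names = FALSE)
cat("\n== paired DeLong comparisons of AUCs ==\n")
print(cbind(cmp[1], round(cmp[-1], 4)))

agree <- do.call(rbind, lapply(params, function(p) {
  rd <- simulate_readers(tab[[p]], 0.05 * mean(tab[[p]]),
                         seed = seed + 200L + match(p, params))
  cc <- lin_ccc(rd$reader1, rd$reader2)
  data.frame(parameter = p, ccc = cc$ccc, band = cc$band)
}))
utils::write.csv(agree, "results/agreement.csv", row.names = FALSE)
cat("\n== inter-reader agreement (CCC at 5% reader CV) ==\n")
print(cbind(agree[1], ccc = round(agree$ccc, 3), band = agree$band))
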