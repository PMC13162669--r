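#!/usr/bin/env Rscript
# Step 4 — discrimination and internal validation.
#
# ROC analysis of the interaction variable for discriminating PFS beyond one
# year (patients censored before the horizon are excluded, their number
# reported), Youden-index operating cutoff, and 1000-iteration bootstrap
# optimism correction of the logistic-model AUC and the Cox-model Harrell
# C-index.

suppressPackageStartupMessages(library(spatprox))

seed <- 20260104
patients <- read_patient_table("results/patients.csv")
scores <- readr::read_csv("results/scores_patients.csv",
                          show_col_types = FALSE)
stopifnot(identical(patients$patient_id, scores$patient_id))

lab <- label_pfs_over_horizon(patients$pfs_days, patients$pfs_event)
cat("PFS > 1 yr:", sum(lab, na.rm = TRUE), "| <= 1 yr:",
    sum(!lab, na.rm = TRUE), "| excluded (censored early):",
    attr(lab, "n_excluded"), "\n")
keep <- !is.na(lab)

roc <- roc_auc(scores$iv[keep], lab[keep])
cut <- youden_cutoff(roc)
cat(sprintf("apparent AUC = %.3f | Youden J = %.2f at iv >= %.1f (sens %.2f, spec %.2f)\n",
            roc$auc, cut$youden_j, cut$threshold, cut$sensitivity,
            cut$specificity))

v_auc <- bootstrap_optimism_auc(scores$iv[keep], lab[keep], n_boot = 1000,
                                seed = seed)
d <- data.frame(time = patients$pfs_days, event = patients$pfs_event,
                iv = scores$iv)
v_c <- bootstrap_optimism_cindex(d, "iv", n_boot = 1000, seed = seed + 1L)
cat(sprintf("optimism-corrected AUC = %.3f (apparent %.3f)\n",
            v_auc$corrected, v_auc$apparent))
cat(sprintf("optimism-corrected C-index = %.3f (apparent %.3f)\n",
            v_c$corrected, v_c$apparent))

readr::write_csv(tibble::tibble(
  metric = c("auc_pfs1yr", "cindex_pfs"),
  apparent = c(v_auc$apparent, v_c$apparent),
  optimism = c(v_auc$optimism, v_c$optimism),
  corrected = c(v_auc$corrected, v_c$corrected),
  n_boot = 1000,
  youden_threshold = c(cut$threshold, NA),
  youden_j = c(cut$youden_j, NA)), "results/validation.csv")
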