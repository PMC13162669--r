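#!/usr/bin/env Rscript
# Step 3 — survival analysis.
#
# Dichotomizes patients at the cohort-median interaction variable, estimates
# Kaplan-Meier curves for PFS and OS by group with log-rank tests and the
# group hazard ratio, then runs the univariate -> multivariate Cox screening
# over the interaction group and the standard clinical candidates
# (dichotomized as in the clinical literature: DCP >= 100, vascular invasion
# present, age > median, AFP >= median, tumor size >= 4 cm).

suppressPackageStartupMessages(library(spatprox))

patients <- read_patient_table("results/patients.csv")
scores <- readr::read_csv("results/scores_patients.csv",
                          show_col_types = FALSE)
stopifnot(identical(patients$patient_id, scores$patient_id))

groups <- dichotomize_at_median(scores$iv)
cat("interaction groups at median", round(attr(groups, "cutoff"), 2), ":",
    sum(groups == "low"), "low /", sum(groups == "high"), "high\n")

km_rows <- list()
for (endpoint in c("pfs", "os")) {
  d <- data.frame(time = patients[[paste0(endpoint, "_days")]],
                  event = patients[[paste0(endpoint, "_event")]])
  for (g in levels(groups)) {
    km <- km_estimate(d[groups == g, ])
    km$endpoint <- endpoint; km$group <- g
    km_rows[[paste(endpoint, g)]] <- km
  }
  lr <- logrank_test(groups, d)
  d$group_high <- as.integer(groups == "high")
  hr <- tryCatch(cox_fit(d, "group_high")$terms$hazard_ratio,
                 error = function(e) NA_real_)
  cat(sprintf("%s: log-rank p = %.4g, HR (high vs low) = %.3f\n",
              toupper(endpoint), lr$p_value, hr))
}
readr::write_csv(do.call(rbind, km_rows), "results/km_curves.csv")

d <- data.frame(time = patients$pfs_days, event = patients$pfs_event,
                iv_high = as.integer(groups == "high"),
                dcp_high = as.integer(patients$dcp >= 100),
                vascular_invasion = patients$vascular_invasion,
                age_high = as.integer(patients$age > median(patients$age)),
                afp_high = as.integer(patients$afp >= median(patients$afp)),
                size_ge4cm = as.integer(patients$max_tumor_size_cm >= 4))
screen <- screen_univariate_multivariate(
  d, c("iv_high", "dcp_high", "vascular_invasion", "age_high", "afp_high",
       "size_ge4cm"))
readr::write_csv(screen$univariate, "results/screening_univariate.csv")
cat("univariate p < 0.05:",
    if (length(screen$selected)) paste(screen$selected, collapse = ", ")
    else "none", "\n")
if (!is.null(screen$multivariate)) {
  readr::write_csv(screen$multivariate$terms,
                   "results/screening_multivariate.csv")
  print(screen$multivariate)
}
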