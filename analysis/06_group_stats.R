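#!/usr/bin/env Rscript
# Stage 6 — supporting statistics.
#
# Descriptive z-CI summaries of log-CgA by disease status (patients and
# controls), the CPE LS-means ANOVA with treatment as covariate, the
# logistic likelihood-ratio test of treatment on progression, and
# single-marker ROC AUCs.

library(netarm)

patients <- read_cohort_csv("results/data/patients.csv")
controls <- read_cohort_csv("results/data/controls.csv")

summaries <- list(
  control = summarize_group(log(controls$cga_uln), group = "control"),
  PD = summarize_group(log(patients$cga_uln[patients$outcome == "PD"]),
                       group = "PD"),
  SD = summarize_group(log(patients$cga_uln[patients$outcome == "SD"]),
                       group = "SD"))
cat("log-CgA, mean (SD) [95% CI]:\n")
for (s in summaries) print(s)

anova_cpe <- ls_means_anova(patients$CPE, patients$outcome, patients$treatment)
cat("\nCPE by disease status, adjusted for treatment:\n")
print(anova_cpe)

lt <- logistic_group_test(patients$outcome, patients$treatment)
cat("\nTreatment effect on progression: ")
print(lt)

aucs <- vapply(c(CgA = "cga_uln", CPE = "CPE", `WISP-1` = "WISP-1",
                 CD160 = "CD160"),
               function(v) roc_auc(patients[[v]], patients$outcome),
               numeric(1))
cat("\nROC AUC (higher score = PD):\n")
print(round(aucs, 3))

jsonlite::write_json(list(
  log_cga = lapply(summaries, function(s)
    list(group = s$group, n = s$n, mean = s$mean, sd = s$sd,
         ci_low = s$ci_low, ci_high = s$ci_high)),
  cpe_ls_means = anova_cpe$ls_means,
  cpe_group_test = list(f = anova_cpe$f_statistic, df = anova_cpe$df,
                        p = anova_cpe$p_value),
  treatment_logistic = list(p = lt$p_value, statistic = lt$statistic,
                            df = lt$df),
  auc = as.list(aucs)
), "results/group_stats.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
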