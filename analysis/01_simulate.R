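#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohorts.
#
# Generates the siNET-like patient cohort (115 patients, 65 PD / 50 SD)
# and the 143-subject control cohort under the study's published group
# distributions (log-CgA and CPE per disease status), and writes them as
# CSV for the downstream stages.

library(netarm)

seed <- 20250814L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
patients <- generate_patients(cfg)
controls <- generate_controls(cfg)

write_cohort_csv(patients, file.path(out, "patients.csv"))
write_cohort_csv(controls, file.path(out, "controls.csv"))
jsonlite::write_json(
  list(n_patients = cfg$n_patients, pd_fraction = cfg$pd_fraction,
       n_biomarkers = cfg$n_biomarkers, n_controls = cfg$n_controls,
       seed = cfg$seed),
  file.path(out, "config.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d patients: %d PD, %d SD; %d controls\n",
            nrow(patients), sum(patients$outcome == "PD"),
            sum(patients$outcome == "SD"), nrow(controls)))
cat(sprintf("median CgA (ULN multiples): PD %.1f, SD %.1f\n",
            median(patients$cga_uln[patients$outcome == "PD"]),
            median(patients$cga_uln[patients$outcome == "SD"])))
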