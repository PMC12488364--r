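#!/usr/bin/env Rscript
# Stage 2 — discretize and encode transactions.
#
# Derives the control-cohort 95% CI cut-offs for every panel marker,
# then encodes each patient as a transaction of categorical items
# (directional biomarker items, CgA > 4 ULN, Ki-67 5% split, clinical
# categories, outcome label).

library(netarm)

patients <- read_cohort_csv("results/data/patients.csv")
controls <- read_cohort_csv("results/data/controls.csv")

cutoffs <- derive_control_ci_cutoffs(controls, ci_level = 0.95)
db <- encode_cohort(patients, cutoffs, item_thresholds())

write_cutoffs_json(cutoffs, "results/cutoffs.json")
write_basket(db, "results/transactions.basket")

cpe <- cutoffs[cutoffs$variable == "CPE", ]
cat(sprintf("cut-offs for %d markers; e.g. CPE reference band [%s, %s]\n",
            nrow(cutoffs), cpe$label_low, cpe$label_high))
cat(sprintf("%d transactions, %d distinct items, median %d items/patient\n",
            db$N, length(db$catalog),
            as.integer(median(rowSums(db$mat)))))
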