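#!/usr/bin/env Rscript
# Stage 5 — subgroup characterization and rule diagnostics.
#
# Second-pass mining with the composite consequent {female, CgA > 4 ULN}
# (support >= 8, confidence >= 0.80): the surviving antecedents describe
# what else characterizes that subgroup, with lift measured against its
# baseline rate. Also evaluates the CgA > 4 ULN rule as a classifier of
# progression within each gender stratum.

library(netarm)

db <- read_basket("results/transactions.basket")
target <- c("female", "CgA > 4 ULN")

char <- characterize_subgroup(db, target, "characterization", max_lhs = 3)
write_rules_csv(char, "results/characterization.csv")
cat(sprintf("characterization of {%s}: %d rules; baseline %d/%d -> max lift %.2f\n",
            paste(target, collapse = ", "), nrow(char),
            db_count(db, target), db$N,
            if (nrow(char)) max(char$lift) else NA))

diag <- list()
for (s in c("female", "male")) {
  d <- evaluate_rule_as_classifier("CgA > 4 ULN", "PD", db, stratum = s)
  print(d)
  diag[[s]] <- list(tp = d$tp, fp = d$fp, fn = d$fn, tn = d$tn,
                    pct = as.list(d$pct), n = d$n)
}
jsonlite::write_json(diag, "results/diagnostics.json", auto_unbox = TRUE,
                     digits = NA)
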