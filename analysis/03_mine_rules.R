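#!/usr/bin/env Rscript
# Stage 3 — Apriori rule mining.
#
# Mines association rules with up to three antecedent items and the
# disease-progression label (PD or SD) as the consequent. The support
# floor here is the smaller of the two selection profiles' thresholds;
# profile filtering happens in stage 4.

library(netarm)

db <- read_basket("results/transactions.basket")
rules <- mine_rules(db, min_support_count = 14,
                    rhs_constraint = list("PD", "SD"), max_lhs = 3)
write_rules_csv(rules, "results/rules.csv")

cat(sprintf("mined %d rules (%d -> PD, %d -> SD) over %d transactions\n",
            nrow(rules), sum(rules$rhs == "PD"), sum(rules$rhs == "SD"),
            db$N))
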