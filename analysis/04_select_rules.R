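#!/usr/bin/env Rscript
# Stage 4 — rule selection.
#
# Applies the study's threshold profiles (PD: support > 20, confidence
# >= 0.70, lift >= 1.2; SD: support > 14, same confidence/lift), removes
# permutation-redundant rules, ranks by lift then support, and
# summarizes which items recur across the selected antecedents.

library(netarm)

db <- read_basket("results/transactions.basket")
rules <- read_rules_csv("results/rules.csv", N = db$N)

for (pass in list(list(rhs = "PD", profile = "sinet_pd"),
                  list(rhs = "SD", profile = "sinet_sd"))) {
  sel <- rank_rules(remove_redundant(filter_rules(
    rules[rules$rhs == pass$rhs, ], pass$profile)))
  attr(sel, "N") <- db$N
  write_rules_csv(sel, sprintf("results/selected_%s.csv", tolower(pass$rhs)))
  freq <- item_frequency(sel)
  write.csv(freq, sprintf("results/item_freq_%s.csv", tolower(pass$rhs)),
            row.names = FALSE)
  cat(sprintf("%s profile: %d rules selected; top antecedent items: %s\n",
              pass$profile, nrow(sel),
              paste(head(freq$item, 3), collapse = ", ")))
  print(sel, n = 5)
}
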