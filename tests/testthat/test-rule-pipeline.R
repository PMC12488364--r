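make_rule_set <- function(lhs, rhs, support, confidence, lift, N = 115) {
  out <- data.frame(lhs = lhs, rhs = rhs, support_count = support,
                    support_fraction = support / N, confidence = confidence,
                    lift = lift, stringsAsFactors = FALSE)
  attr(out, "N") <- N
  class(out) <- c("rule_set", "data.frame")
  out
}

test_that("filtering uses strict support and inclusive lift/confidence", {
  rules <- make_rule_set(c("A", "B", "C"), "PD",
                         support = c(20, 21, 30),
                         confidence = c(0.9, 0.70, 0.69),
                         lift = c(1.5, 1.2, 2.0))
  kept <- filter_rules(rules, "sinet_pd")
  # support 20 fails ">20"; lift 1.2 and confidence 0.70 pass ">="
  expect_equal(kept$lhs, "B")

  prof <- filter_profile("characterization")
  rules2 <- make_rule_set(c("A", "B"), "PD", support = c(8, 7),
                          confidence = c(0.8, 0.9), lift = c(5, 5))
  expect_equal(filter_rules(rules2, prof)$lhs, "A")  # ">= 8" inclusive
})

test_that("every filter survivor satisfies all predicates", {
  set.seed(31)
  n <- 200
  rules <- make_rule_set(sprintf("R%03d", 1:n), "PD",
                         support = sample(1:40, n, TRUE),
                         confidence = runif(n), lift = runif(n, 0.5, 3))
  f <- rule_filter(15, 0.6, 1.1)
  kept <- filter_rules(rules, f)
  expect_true(all(kept$lhs %in% rules$lhs))
  expect_true(all(kept$support_count > 15))
  expect_true(all(kept$confidence >= 0.6))
  expect_true(all(kept$lift >= 1.1))
  manual <- rules$support_count > 15 & rules$confidence >= 0.6 &
    rules$lift >= 1.1
  expect_equal(nrow(kept), sum(manual))
})

test_that("redundant permutations collapse to one canonical rule", {
  rules <- make_rule_set(c("female & bmZ", "bmZ & female"), "PD",
                         c(23, 23), c(1, 1), c(2.08, 2.08))
  out <- remove_redundant(rules)
  expect_equal(nrow(out), 1)
  expect_equal(out$lhs, "bmZ & female")
  expect_identical(remove_redundant(out), out)  # idempotent

  # all n <= 6 permutations of a 3-item antecedent leave one survivor
  grid <- expand.grid(1:3, 1:3, 1:3)
  perms <- apply(grid, 1, function(p) {
    if (length(unique(p)) < 3) NA_character_ else
      paste(c("A", "B", "C")[p], collapse = " & ")
  })
  perms <- perms[!is.na(perms)]
  for (k in 1:6) {
    rs <- make_rule_set(perms[1:k], "PD", rep(10, k), rep(1, k), rep(2, k))
    expect_equal(nrow(remove_redundant(rs)), 1)
  }
})

test_that("ranking is by lift, then support, then canonical label", {
  rules <- make_rule_set(
    c("CgA > 4 ULN & Ki-67 > 5% & WISP-1 > 3.73",
      "NET grade 2 & CgA > 4 ULN & TFPI-2 > 7.07", "zzz"),
    "PD", support = c(26, 25, 40), confidence = c(1, 1, 0.9),
    lift = c(2.08, 2.08, 1.5))
  ranked <- rank_rules(rules)
  expect_equal(ranked$support_count[1:2], c(26, 25))  # equal lift: support first
  expect_equal(ranked$lhs[3], "zzz")

  expect_equal(rank_rules(rules[2, ])$lhs, rules$lhs[2])

  set.seed(77)
  rnd <- make_rule_set(sprintf("R%02d", 1:50), "PD", sample(1:30, 50, TRUE),
                       runif(50), runif(50, 1, 3))
  rk <- rank_rules(rnd)
  expect_setequal(rk$lhs, rnd$lhs)
  expect_true(all(diff(rk$lift) <= 1e-15))
  same_lift <- which(diff(rk$lift) == 0)
  expect_true(all(diff(rk$support_count)[same_lift] <= 0))
})

test_that("item frequency counts antecedent membership", {
  rules <- make_rule_set(c("A & B", "A"), "PD", c(10, 12), c(1, 1), c(2, 2))
  tab <- item_frequency(rules)
  expect_equal(tab$item, c("A", "B"))
  expect_equal(tab$n_rules, c(2L, 1L))
  expect_equal(tab$fraction, c(1, 0.5))
  expect_equal(nrow(item_frequency(rules[0, ])), 0)
})

test_that("the dominant planted item ranks first in the frequency table", {
  # Null base cohort (no group effects anywhere) with a single planted
  # perfect rule: only antecedents containing the planted item can reach
  # the confidence threshold, so it must top the frequency table.
  bp <- default_biomarker_params(4)
  bp[, c("control_mean", "sd_mean", "pd_mean")] <- 3
  bp[, c("control_sd", "sd_sd", "pd_sd")] <- 1
  freq0 <- netarm:::default_clinical_frequencies()
  for (v in names(freq0)) freq0[[v]]$PD <- freq0[[v]]$SD
  cfg <- cohort_config(n_patients = 115, n_biomarkers = 4, n_controls = 50,
                       biomarker_params = bp,
                       cga_log_params = list(control = c(1.29, 0.48),
                                             SD = c(0.3, 0.5),
                                             PD = c(0.3, 0.5)),
                       hiaa_log_params = list(SD = c(5, 0.9), PD = c(5, 0.9)),
                       clinical_frequencies = freq0, seed = 42,
                       planted_rules = list(
                         planted_rule("CgA > 4 ULN", "PD", 1, 0.4)))
  pat <- generate_patients(cfg)
  db <- encode_cohort(pat, derive_control_ci_cutoffs(generate_controls(cfg)))
  sel <- rank_rules(remove_redundant(filter_rules(
    mine_rules(db, 20, rhs_constraint = list("PD"), max_lhs = 2), "sinet_pd")))
  tab <- item_frequency(sel)
  expect_equal(tab$item[1], "CgA > 4 ULN")
  expect_true(all(vapply(sel$lhs, function(s)
    "CgA > 4 ULN" %in% split_items_test(s), logical(1))))
})

test_that("composite-consequent characterization computes lift vs the target baseline", {
  # 10 of 40 transactions carry the target; marker A co-occurs always.
  items <- c(rep(list(c("female", "CgA > 4 ULN", "A")), 10),
             rep(list("B"), 30))
  db <- transaction_db(items)
  out <- characterize_subgroup(db, c("female", "CgA > 4 ULN"),
                               rule_filter(1, 0, 0), max_lhs = 1)
  r <- out[out$lhs == "A", ]
  expect_equal(r$confidence, 1)
  expect_equal(r$lift, 40 / 10)

  expect_error(characterize_subgroup(db, "unseen item"), "absent")
})

test_that("characterization equals the generic composite-consequent mining", {
  set.seed(808)
  for (rep in 1:15) {
    items_list <- random_items_list(30, 6, p_item = 0.5)
    # make the two-item target reasonably frequent
    items_list <- lapply(items_list, function(t) {
      if (runif(1) < 0.35) unique(c(t, "A", "B")) else t
    })
    db <- transaction_db(items_list)
    target <- c("A", "B")
    flt <- rule_filter(2, 0.3, 0, support_strict = FALSE)
    got <- characterize_subgroup(db, target, flt, max_lhs = 2)

    generic <- generate_rules(
      mine_frequent_itemsets(db, 2, max_size = 4), db,
      rhs_constraint = list(target), max_lhs = 2)
    generic <- generic[!vapply(generic$lhs, function(s)
      any(c("PD", "SD") %in% split_items_test(s)), logical(1)), , drop = FALSE]
    attr(generic, "N") <- db$N
    class(generic) <- c("rule_set", "data.frame")
    generic <- rank_rules(remove_redundant(filter_rules(generic, flt)))

    expect_identical(got$lhs, generic$lhs)
    expect_equal(got$support_count, generic$support_count)
    expect_equal(got$confidence, generic$confidence, tolerance = 1e-12)
    expect_equal(got$lift, generic$lift, tolerance = 1e-12)
  }
})

test_that("rule-as-classifier matches a brute-force 2x2 recount", {
  set.seed(55)
  for (rep in 1:20) {
    items_list <- random_items_list(40, 5)
    db <- transaction_db(items_list)
    d <- evaluate_rule_as_classifier(c("A", "B"), "PD", db)
    pos <- vapply(items_list, function(t) all(c("A", "B") %in% t), logical(1))
    pd <- vapply(items_list, function(t) "PD" %in% t, logical(1))
    expect_equal(c(d$tp, d$fp, d$fn, d$tn),
                 c(sum(pos & pd), sum(pos & !pd), sum(!pos & pd), sum(!pos & !pd)))
    # identities: PPV * (tp+fp) = tp; rule-positive rate decomposition
    if (!is.na(d$ppv)) expect_equal(d$ppv * (d$tp + d$fp), d$tp)
    prev <- (d$tp + d$fn) / d$n
    if (!is.na(d$sensitivity) && !is.na(d$specificity)) {
      expect_equal(d$sensitivity * prev + (1 - d$specificity) * (1 - prev),
                   (d$tp + d$fp) / d$n, tolerance = 1e-12)
    }
  }
})

test_that("degenerate classifier denominators are flagged undefined", {
  db <- transaction_db(list(c("A", "PD"), c("A", "SD")))
  d <- evaluate_rule_as_classifier("A", "PD", db)
  expect_true(is.na(d$npv))
  expect_equal(d$undefined, "npv")
  expect_error(evaluate_rule_as_classifier("A", "PD", db, stratum = "B"),
               "not in catalog")
})

test_that("a planted perfect rule survives the study filter end to end", {
  cfg <- cohort_config(seed = 8, planted_rules = list(
    planted_rule(c("female", "CgA > 4 ULN"), "PD", 1, 0.2)))
  pat <- generate_patients(cfg)
  db <- encode_cohort(pat, derive_control_ci_cutoffs(generate_controls(cfg)))
  rules <- mine_rules(db, 21, rhs_constraint = list("PD"), max_lhs = 2)
  sel <- rank_rules(remove_redundant(filter_rules(rules, "sinet_pd")))
  r <- sel[sel$lhs == "CgA > 4 ULN & female", ]
  expect_equal(nrow(r), 1)
  expect_equal(r$confidence, 1)
  expect_equal(r$support_count, 23L)

  d <- evaluate_rule_as_classifier(c("female", "CgA > 4 ULN"), "PD", db)
  expect_equal(d$pct[["ppv"]], 100)
})
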