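#' @title Rule selection, subgroup characterization and diagnostics
#' @description
#' The interpretation layer over the miner: threshold filtering with the
#' study's operator conventions (strict ">" on the integer support,
#' inclusive ">=" on lift and confidence), redundancy removal (rules that
#' are permutations of the same attribute sets), deterministic ranking by
#' lift then support, antecedent item-frequency summaries, second-pass
#' mining against a composite consequent (e.g. females with CgA > 4 ULN)
#' and 2x2 rule-as-classifier diagnostics (PPV/NPV/sensitivity/
#' specificity), optionally within a stratum such as one gender.
#' @name rule_pipeline
NULL

#' Rule filter thresholds
#'
#' @param min_support_count support threshold (absolute count).
#' @param min_confidence confidence threshold in \[0,1\] (inclusive).
#' @param min_lift lift threshold (inclusive).
#' @param support_strict if `TRUE` (default) support must exceed the
#'   threshold strictly, matching "support > 20"; `FALSE` gives ">=",
#'   matching the characterization pass "support >= 8".
#' @return object of class `rule_filter`.
#' @export
rule_filter <- function(min_support_count = 0, min_confidence = 0,
                        min_lift = 0, support_strict = TRUE) {
  stopifnot(min_support_count >= 0, min_confidence >= 0, min_confidence <= 1,
            min_lift >= 0)
  structure(list(min_support_count = min_support_count,
                 min_confidence = min_confidence, min_lift = min_lift,
                 support_strict = support_strict),
            class = "rule_filter")
}

#' Named filter profiles
#'
#' The selection thresholds the study applied per cohort and pass:
#' \describe{
#'   \item{`sinet_pd`}{support > 20, confidence >= 0.70, lift >= 1.2}
#'   \item{`sinet_sd`}{support > 14, confidence >= 0.70, lift >= 1.2}
#'   \item{`pnet_pd`}{support > 14, confidence >= 0.70, lift >= 1.25}
#'   \item{`characterization`}{support >= 8, confidence >= 0.80; selected
#'     rules in this regime carry very high lift (> 4.7 at the study's
#'     23/115 consequent baseline), stored as attribute `report_lift`}
#' }
#'
#' @param name profile name.
#' @return a [rule_filter()].
#' @export
filter_profile <- function(name = c("sinet_pd", "sinet_sd", "pnet_pd",
                                    "characterization")) {
  name <- match.arg(name)
  switch(name,
    sinet_pd = rule_filter(20, 0.70, 1.2, support_strict = TRUE),
    sinet_sd = rule_filter(14, 0.70, 1.2, support_strict = TRUE),
    pnet_pd = rule_filter(14, 0.70, 1.25, support_strict = TRUE),
    characterization = {
      f <- rule_filter(8, 0.80, 0, support_strict = FALSE)
      attr(f, "report_lift") <- 4.7
      f
    })
}

#' Filter rules on support/confidence/lift
#'
#' @param rules a `rule_set`.
#' @param filter a [rule_filter()] or profile name.
#' @return the surviving rules (same class, attributes kept).
#' @export
filter_rules <- function(rules, filter) {
  if (is.character(filter)) filter <- filter_profile(filter)
  stopifnot(inherits(rules, "rule_set"), inherits(filter, "rule_filter"))
  sup_ok <- if (filter$support_strict) {
    rules$support_count > filter$min_support_count
  } else {
    rules$support_count >= filter$min_support_count
  }
  keep <- sup_ok & rules$confidence >= filter$min_confidence &
    rules$lift >= filter$min_lift
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- attr(rules, "N")
  class(out) <- class(rules)
  out
}

canonicalize_rule_strings <- function(s) {
  vapply(s, function(one) join_items(split_items(one)), character(1),
         USE.NAMES = FALSE)
}

#' Remove redundant rules
#'
#' Rules with the same antecedent and consequent attribute sets in a
#' different order carry no extra information; one canonical
#' representative (lexicographically ordered items) is kept per
#' (LHS-set, RHS-set) pair.
#'
#' @param rules a `rule_set`.
#' @return deduplicated `rule_set`; idempotent.
#' @export
remove_redundant <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  lhs <- canonicalize_rule_strings(rules$lhs)
  rhs <- canonicalize_rule_strings(rules$rhs)
  key <- paste(lhs, rhs, sep = "\x1f")
  keep <- !duplicated(key)
  out <- rules[keep, , drop = FALSE]
  out$lhs <- lhs[keep]
  out$rhs <- rhs[keep]
  rownames(out) <- NULL
  attr(out, "N") <- attr(rules, "N")
  class(out) <- class(rules)
  out
}

#' Rank rules by lift and support
#'
#' Sort by lift descending, then support count descending, then canonical
#' antecedent label ascending — a total, deterministic order.
#'
#' @param rules a deduplicated `rule_set`.
#' @return the same rules, reordered.
#' @export
rank_rules <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  out <- rules[order(-rules$lift, -rules$support_count, rules$lhs, rules$rhs),
               , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- attr(rules, "N")
  class(out) <- class(rules)
  out
}

#' Antecedent item frequency across a rule set
#'
#' @param rules a deduplicated `rule_set`.
#' @return data.frame `item`, `n_rules` (selected rules whose antecedent
#'   contains the item), `fraction` (of all selected rules), sorted by
#'   `n_rules` descending then item label.
#' @export
item_frequency <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  if (nrow(rules) == 0) {
    return(data.frame(item = character(0), n_rules = integer(0),
                      fraction = numeric(0)))
  }
  items <- unlist(lapply(rules$lhs, split_items))
  tab <- table(items)
  out <- data.frame(item = names(tab), n_rules = as.integer(tab),
                    fraction = as.integer(tab) / nrow(rules),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_rules, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Characterize a subgroup via composite-consequent mining
#'
#' Second-pass mining where the consequent is a fixed (possibly
#' multi-item) target — e.g. the combination of female gender and
#' CgA > 4 ULN — so that surviving antecedents describe what else
#' co-occurs in that subgroup. Lift is computed against the target's
#' baseline rate `count(target)/N`; a rare target makes high-confidence
#' rules carry very high lift (confidence 0.94 at a 23/115 baseline gives
#' lift 4.69).
#'
#' @details
#' A rule `X -> target` has `support(X u target)` equal to the support of
#' `X` among the target-positive transactions, so antecedents are mined
#' in the target-projected database (only target carriers, target and
#' outcome items removed) and their full-cohort counts supply the
#' confidence and lift denominators. This is exactly the rule set the
#' generic miner would emit for that consequent, restricted to
#' non-outcome antecedents, but never enumerates itemsets that cannot
#' reach the consequent. Outcome labels are excluded from antecedents:
#' the pass characterizes the subgroup by baseline variables, not by the
#' outcome it predicts.
#'
#' @param db a `transaction_db`.
#' @param target_rhs character vector of target items.
#' @param filter a [rule_filter()] or profile name (default
#'   `"characterization"`).
#' @param max_lhs maximum antecedent size (default 3).
#' @return filtered, deduplicated, ranked `rule_set`.
#' @export
characterize_subgroup <- function(db, target_rhs,
                                  filter = filter_profile("characterization"),
                                  max_lhs = 3) {
  if (is.character(filter)) filter <- filter_profile(filter)
  stopifnot(inherits(db, "transaction_db"), length(target_rhs) >= 1)
  target_rhs <- sort_items(target_rhs)
  absent <- setdiff(target_rhs, db$catalog)
  if (length(absent)) stop("target item(s) absent from transactions: ",
                           paste(absent, collapse = ", "))
  N <- db$N
  carrier <- rowSums(db$mat[, target_rhs, drop = FALSE]) == length(target_rhs)
  c_target <- sum(carrier)
  if (c_target == 0) stop("target itemset has zero support")
  min_sup <- max(1L, filter$min_support_count + as.integer(filter$support_strict))

  lhs_items <- setdiff(db$catalog, c(target_rhs, "PD", "SD"))
  proj <- new_transaction_db(db$mat[carrier, lhs_items, drop = FALSE],
                             db$patient_id[carrier])
  empty <- {
    e <- data.frame(lhs = character(0), rhs = character(0),
                    support_count = integer(0), support_fraction = numeric(0),
                    confidence = numeric(0), lift = numeric(0))
    attr(e, "N") <- N
    class(e) <- c("rule_set", "data.frame")
    e
  }
  if (proj$N == 0 || length(proj$catalog) == 0) return(empty)
  freq <- mine_frequent_itemsets(proj, min_sup, max_lhs)
  if (nrow(freq) == 0) return(empty)

  # full-cohort antecedent counts for the confidence denominator
  full_idx <- match(proj$catalog, db$catalog)
  mat01 <- db$mat * 1L
  levels <- attr(freq, "levels")
  cx <- unlist(lapply(levels, function(l) {
    vapply(seq_len(ncol(l$idx)), function(j) {
      v <- mat01[, full_idx[l$idx[, j]], drop = FALSE]
      sum(rowSums(v) == nrow(l$idx))
    }, numeric(1))
  }))
  cnt <- unlist(lapply(levels, `[[`, "cnt"))
  lhs <- unlist(lapply(levels, function(l) {
    labels <- lapply(seq_len(nrow(l$idx)),
                     function(r) proj$catalog[l$idx[r, ]])
    do.call(paste, c(labels, list(sep = ITEM_SEP)))
  }))
  rules <- data.frame(
    lhs = lhs, rhs = paste(target_rhs, collapse = ITEM_SEP),
    support_count = as.integer(cnt), support_fraction = cnt / N,
    confidence = cnt / cx, lift = (cnt / cx) * N / c_target,
    stringsAsFactors = FALSE
  )
  rules <- rules[order(rules$rhs, rules$lhs), , drop = FALSE]
  rownames(rules) <- NULL
  attr(rules, "N") <- N
  class(rules) <- c("rule_set", "data.frame")
  rank_rules(remove_redundant(filter_rules(rules, filter)))
}

#' Evaluate a rule antecedent as a binary classifier
#'
#' Within the whole cohort or one stratum (all transactions carrying a
#' given item), patients carrying every antecedent item are
#' rule-positive; the 2x2 table against the outcome label yields
#' PPV, NPV, sensitivity and specificity. Percentages are rounded half
#' away from zero.
#'
#' @param antecedent character vector of non-outcome items.
#' @param outcome `"PD"` or `"SD"` — the condition the rule predicts.
#' @param db a `transaction_db`.
#' @param stratum optional single item restricting the evaluated
#'   population (e.g. `"female"`).
#' @return object of class `diagnostic_metrics`: counts `tp`, `fp`, `fn`,
#'   `tn`; proportions `ppv`, `npv`, `sensitivity`, `specificity` (`NA`
#'   when the denominator is zero, with the metric named in `undefined`);
#'   integer percentages in `pct`; `n` and `stratum`.
#' @export
evaluate_rule_as_classifier <- function(antecedent, outcome, db,
                                        stratum = NULL) {
  stopifnot(inherits(db, "transaction_db"), length(antecedent) >= 1,
            outcome %in% c("PD", "SD"))
  unknown <- setdiff(c(antecedent, stratum), db$catalog)
  if (length(unknown)) stop("item(s) not in catalog: ",
                            paste(unknown, collapse = ", "))
  rows <- seq_len(db$N)
  if (!is.null(stratum)) {
    rows <- which(db$mat[, stratum])
    if (!length(rows)) stop("empty stratum: ", stratum)
  }
  positive <- rowSums(db$mat[rows, antecedent, drop = FALSE]) == length(antecedent)
  diseased <- db$outcome_item[rows] == outcome
  tp <- sum(positive & diseased)
  fp <- sum(positive & !diseased)
  fn <- sum(!positive & diseased)
  tn <- sum(!positive & !diseased)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  props <- c(ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
             sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp))
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = props[["ppv"]], npv = props[["npv"]],
    sensitivity = props[["sensitivity"]], specificity = props[["specificity"]],
    pct = round_half_up(100 * props),
    undefined = names(props)[is.na(props)],
    n = length(rows), stratum = stratum,
    antecedent = antecedent, outcome = outcome
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  where <- if (is.null(x$stratum)) "whole cohort" else paste("stratum:", x$stratum)
  cat(sprintf("Rule {%s} -> %s (%s, n = %d)\n",
              paste(x$antecedent, collapse = " ∩ "), x$outcome, where, x$n))
  cat(sprintf("  2x2: tp %d, fp %d, fn %d, tn %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(nm) if (is.na(x[[nm]])) "undefined" else sprintf("%d%%", x$pct[[nm]])
  cat(sprintf("  PPV %s, NPV %s, sensitivity %s, specificity %s\n",
              fmt("ppv"), fmt("npv"), fmt("sensitivity"), fmt("specificity")))
  invisible(x)
}
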