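#' @title End-to-end study driver
#' @description
#' Chains the full workflow — simulate, derive control cut-offs,
#' categorize, mine, select, characterize, evaluate, group statistics —
#' writing every stage output plus a checksum manifest and a run log, so
#' that a run is reproducible file-for-file from its config and seed.
#' @name run_study_stage
NULL

#' Study configuration
#'
#' @param cohort a [cohort_config()].
#' @param ci_level control-CI coverage for biomarker cut-offs.
#' @param thresholds [item_thresholds()] clinical thresholds.
#' @param pd_profile,sd_profile filter profile names for the PD and SD
#'   selection passes (see [filter_profile()]).
#' @param characterization_rhs composite consequent for the second
#'   mining pass (default: female with CgA above 4 ULN).
#' @param evaluate_antecedent,evaluate_outcome rule evaluated as a
#'   classifier within each gender stratum.
#' @param mining_min_support absolute support floor used when generating
#'   the full rule table before profile filtering; defaults to the
#'   smaller of the two profiles' thresholds.
#' @param max_lhs maximum antecedent size (default 3).
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         ci_level = 0.95,
                         thresholds = item_thresholds(),
                         pd_profile = "sinet_pd",
                         sd_profile = "sinet_sd",
                         characterization_rhs = c("female", "CgA > 4 ULN"),
                         evaluate_antecedent = "CgA > 4 ULN",
                         evaluate_outcome = "PD",
                         mining_min_support = NULL,
                         max_lhs = 3) {
  pd_f <- filter_profile(pd_profile)
  sd_f <- filter_profile(sd_profile)
  mining_min_support <- mining_min_support %||%
    max(1L, min(pd_f$min_support_count, sd_f$min_support_count))
  structure(list(cohort = cohort, ci_level = ci_level,
                 thresholds = thresholds,
                 pd_profile = pd_profile, sd_profile = sd_profile,
                 characterization_rhs = characterization_rhs,
                 evaluate_antecedent = evaluate_antecedent,
                 evaluate_outcome = evaluate_outcome,
                 mining_min_support = mining_min_support,
                 max_lhs = max_lhs),
            class = "study_config")
}

#' Run the full study workflow
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest data.frame (`stage`, `file`, `md5`);
#'   also written as `manifest.csv` alongside a plain-text `run.log`.
#'   Re-running with the same config reproduces identical checksums.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  path <- function(f) file.path(out_dir, f)

  note("seed: %d", config$cohort$seed)
  patients <- stage("simulate", generate_patients(config$cohort))
  controls <- stage("simulate", generate_controls(config$cohort))
  write_cohort_csv(patients, path("patients.csv")); emit("simulate", path("patients.csv"))
  write_cohort_csv(controls, path("controls.csv")); emit("simulate", path("controls.csv"))
  cfg_json <- path("config.json")
  jsonlite::write_json(list(
    n_patients = config$cohort$n_patients,
    pd_fraction = config$cohort$pd_fraction,
    n_biomarkers = config$cohort$n_biomarkers,
    n_controls = config$cohort$n_controls,
    seed = config$cohort$seed, ci_level = config$ci_level,
    pd_profile = config$pd_profile, sd_profile = config$sd_profile,
    characterization_rhs = config$characterization_rhs,
    max_lhs = config$max_lhs,
    mining_min_support = config$mining_min_support
  ), cfg_json, auto_unbox = TRUE, digits = NA)
  emit("simulate", cfg_json)
  note("simulated %d patients (%d PD), %d controls",
       nrow(patients), sum(patients$outcome == "PD"), nrow(controls))

  cutoffs <- stage("cutoffs",
                   derive_control_ci_cutoffs(controls, config$ci_level))
  write_cutoffs_json(cutoffs, path("cutoffs.json")); emit("cutoffs", path("cutoffs.json"))
  note("control-CI cut-offs at %.0f%% coverage for %d markers",
       100 * config$ci_level, nrow(cutoffs))

  db <- stage("categorize", encode_cohort(patients, cutoffs, config$thresholds))
  write_basket(db, path("transactions.basket")); emit("categorize", path("transactions.basket"))
  note("encoded %d transactions, %d items in catalog", db$N, length(db$catalog))

  rules <- stage("mine", mine_rules(db, config$mining_min_support,
                                    rhs_constraint = list("PD", "SD"),
                                    max_lhs = config$max_lhs))
  write_rules_csv(rules, path("rules.csv")); emit("mine", path("rules.csv"))
  note("mined %d rules at min support %d", nrow(rules), config$mining_min_support)

  select_pass <- function(profile, rhs, file_rules, file_freq) {
    sel <- rank_rules(remove_redundant(
      filter_rules(rules[rules$rhs == rhs, , drop = FALSE], profile)))
    attr(sel, "N") <- attr(rules, "N")
    write_rules_csv(sel, path(file_rules)); emit("select", path(file_rules))
    utils::write.csv(item_frequency(sel), path(file_freq), row.names = FALSE)
    emit("select", path(file_freq))
    note("profile %s (%s): %d rules selected", profile, rhs, nrow(sel))
    sel
  }
  selected_pd <- stage("select", select_pass(config$pd_profile, "PD",
                                             "selected_pd.csv", "item_freq_pd.csv"))
  selected_sd <- stage("select", select_pass(config$sd_profile, "SD",
                                             "selected_sd.csv", "item_freq_sd.csv"))

  char_rules <- stage("characterize", {
    target <- sort_items(config$characterization_rhs)
    if (all(target %in% db$catalog) && db_count(db, target) > 0) {
      characterize_subgroup(db, target, "characterization", config$max_lhs)
    } else {
      note("characterization target not observed; pass skipped")
      NULL
    }
  })
  if (!is.null(char_rules)) {
    write_rules_csv(char_rules, path("characterization.csv"))
    emit("characterize", path("characterization.csv"))
    note("characterization: %d rules for RHS {%s}", nrow(char_rules),
         paste(config$characterization_rhs, collapse = ", "))
  }

  diag <- stage("evaluate", {
    res <- list()
    for (s in intersect(c("female", "male"), db$catalog)) {
      d <- evaluate_rule_as_classifier(config$evaluate_antecedent,
                                       config$evaluate_outcome, db, stratum = s)
      res[[s]] <- list(tp = d$tp, fp = d$fp, fn = d$fn, tn = d$tn,
                       ppv = d$ppv, npv = d$npv,
                       sensitivity = d$sensitivity, specificity = d$specificity,
                       pct = as.list(d$pct), n = d$n)
    }
    res
  })
  jsonlite::write_json(diag, path("diagnostics.json"), auto_unbox = TRUE,
                       digits = NA)
  emit("evaluate", path("diagnostics.json"))

  stats_out <- stage("stats", {
    sum_one <- function(x, lab) {
      s <- summarize_group(x, config$ci_level, lab)
      list(group = lab, n = s$n, mean = s$mean, sd = s$sd,
           ci_low = s$ci_low, ci_high = s$ci_high)
    }
    anova_cpe <- ls_means_anova(patients$CPE, patients$outcome,
                                patients$treatment)
    lt <- logistic_group_test(patients$outcome, patients$treatment)
    aucs <- lapply(c("cga_uln", "CPE", "WISP-1", "CD160"), function(v) {
      if (!v %in% names(patients)) return(NULL)
      roc_auc(patients[[v]], patients$outcome)
    })
    names(aucs) <- c("CgA", "CPE", "WISP-1", "CD160")
    list(
      log_cga = list(
        control = sum_one(log(controls$cga_uln), "control"),
        SD = sum_one(log(patients$cga_uln[patients$outcome == "SD"]), "SD"),
        PD = sum_one(log(patients$cga_uln[patients$outcome == "PD"]), "PD")
      ),
      cpe_ls_means = anova_cpe$ls_means,
      cpe_group_test = list(f = anova_cpe$f_statistic,
                            df = anova_cpe$df, p = anova_cpe$p_value),
      treatment_logistic = list(p = lt$p_value, statistic = lt$statistic,
                                df = lt$df),
      auc = aucs[!vapply(aucs, is.null, logical(1))]
    )
  })
  jsonlite::write_json(stats_out, path("group_stats.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  emit("stats", path("group_stats.json"))

  writeLines(log_lines, path("run.log"))
  utils::write.csv(manifest, path("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
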