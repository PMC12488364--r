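#' @title Synthetic NET cohort generator
#' @description
#' Generates patient and control cohorts with the statistical structure the
#' rule-mining analysis assumes: a small-intestinal (or pancreatic) NET
#' cohort with a binary 3-year outcome (stable disease SD vs progressive
#' disease PD, deaths folded into PD), chromogranin A expressed as a
#' multiple of the upper limit of normal (ULN, simulated on the log scale
#' and exponentiated), 5-HIAA as percent of ULN, a 92-protein plasma panel
#' on a relative log (NPX-like) scale, Table-1-style clinical categories,
#' and an age/gender-matched control cohort used only to derive biomarker
#' reference intervals. Ground-truth association rules can be planted so
#' that rule-recovery is testable end to end.
#' @name synthetic_cohort
NULL

# Protein symbols that appear in the study's printed rules; the remainder
# of the 92-plex panel gets neutral generic names.
NAMED_MARKERS <- c(
  "CPE", "WISP-1", "VIM", "CD160", "PVRL4", "TRAIL", "DLL1", "ITGAV",
  "ABL1", "TFPI-2", "ADAM-8", "TGF-alpha", "MK", "PPY", "IFN-gamma-R1",
  "MIA", "5'-NT", "ICOSLG", "VEGFR-2", "TFF3"
)

CS_SYMPTOMS <- c("diarrhea", "flushing", "bronchospasm")

#' Names of the simulated plasma protein panel
#'
#' @param n_biomarkers panel size (default 92).
#' @return character vector of marker names; the first entries are the
#'   protein symbols used in the study's rules, the rest are generic.
#' @export
biomarker_panel <- function(n_biomarkers = 92) {
  stopifnot(n_biomarkers >= 1)
  named <- NAMED_MARKERS[seq_len(min(n_biomarkers, length(NAMED_MARKERS)))]
  extra <- if (n_biomarkers > length(named)) {
    sprintf("BM%03d", seq(length(named) + 1, n_biomarkers))
  } else character(0)
  c(named, extra)
}

#' Default per-marker distribution parameters
#'
#' One row per panel marker with normal mean/SD per population (control,
#' SD group, PD group) on the NPX-like scale. CPE uses the published
#' group means/SDs; the other rule-bearing markers get moderate group
#' shifts in the direction the study reports (e.g. WISP-1 and VIM up in
#' PD, CD160 and PVRL4 up in SD, TRAIL and ITGAV down in PD); markers
#' without a reported direction are centred near their printed rule
#' threshold with no group effect; generic markers are null N(3, 1).
#'
#' @param n_biomarkers panel size.
#' @return data.frame with columns `marker`, `control_mean`, `control_sd`,
#'   `sd_mean`, `sd_sd`, `pd_mean`, `pd_sd`.
#' @export
default_biomarker_params <- function(n_biomarkers = 92) {
  markers <- biomarker_panel(n_biomarkers)
  p <- data.frame(
    marker = markers,
    control_mean = 3, control_sd = 1,
    sd_mean = 3, sd_sd = 1,
    pd_mean = 3, pd_sd = 1,
    stringsAsFactors = FALSE
  )
  set_row <- function(p, m, ctrl, sdg, pdg) {
    i <- match(m, p$marker)
    if (is.na(i)) return(p)
    p[i, c("control_mean", "control_sd")] <- ctrl
    p[i, c("sd_mean", "sd_sd")] <- sdg
    p[i, c("pd_mean", "pd_sd")] <- pdg
    p
  }
  p <- set_row(p, "CPE", c(3.09, 0.34), c(2.96, 0.33), c(3.32, 0.74))
  p <- set_row(p, "WISP-1", c(3.30, 0.50), c(3.40, 0.60), c(3.95, 0.70))
  p <- set_row(p, "VIM", c(1.50, 0.30), c(1.55, 0.40), c(1.95, 0.50))
  p <- set_row(p, "CD160", c(4.20, 0.50), c(4.80, 0.60), c(4.30, 0.60))
  p <- set_row(p, "PVRL4", c(5.10, 0.40), c(5.60, 0.50), c(5.20, 0.50))
  p <- set_row(p, "TRAIL", c(7.50, 0.40), c(7.50, 0.50), c(7.00, 0.60))
  p <- set_row(p, "DLL1", c(8.50, 0.40), c(8.60, 0.40), c(9.00, 0.50))
  p <- set_row(p, "ITGAV", c(2.90, 0.30), c(2.90, 0.35), c(2.50, 0.40))
  # Markers that appear in printed rules without a stated group effect:
  # centred at the printed threshold so roughly half the cohort exceeds it.
  near <- c("ABL1" = 2.04, "TFPI-2" = 7.07, "ADAM-8" = 3.90,
            "TGF-alpha" = 1.21, "MK" = 5.90, "PPY" = 5.42,
            "IFN-gamma-R1" = 3.28, "MIA" = 9.52, "5'-NT" = 9.56,
            "ICOSLG" = 3.21, "VEGFR-2" = 6.32, "TFF3" = 4.00)
  for (m in names(near)) {
    p <- set_row(p, m, c(near[[m]], 0.5), c(near[[m]], 0.5), c(near[[m]], 0.5))
  }
  p
}

default_clinical_frequencies <- function() {
  # Table-1 siNET category counts; probabilities per outcome group.
  list(
    gender = list(levels = c("F", "M"),
                  SD = c(15, 35) / 50, PD = c(32, 33) / 65),
    net_grade = list(levels = c("G1", "G2", "missing"),
                     SD = c(28, 20, 2) / 50, PD = c(18, 43, 4) / 65),
    n_status = list(levels = c("N0", "N1", "Nx"),
                    SD = c(10, 40, 0) / 50, PD = c(13, 51, 1) / 65),
    m_status = list(levels = c("M0", "M1"),
                    SD = c(16, 34) / 50, PD = c(5, 60) / 65),
    treatment = list(levels = c("SSA", "SSA and surgery", "other treatment"),
                     SD = c(21, 18, 11) / 50, PD = c(37, 12, 16) / 65),
    liver_metastasis = list(SD = 0.40, PD = 0.70),
    diarrhea = list(SD = 0.35, PD = 0.55),
    flushing = list(SD = 0.30, PD = 0.45),
    bronchospasm = list(SD = 0.06, PD = 0.12)
  )
}

#' Plant a ground-truth association rule in a simulated cohort
#'
#' @param antecedent_items character vector of item labels (the same
#'   vocabulary the categorizer emits, e.g. `"female"`, `"CgA > 4 ULN"`,
#'   `"Ki-67 > 5%"`, `"CPE > 3.14"`).
#' @param outcome `"PD"` or `"SD"` — the consequent.
#' @param penetrance probability in \[0,1\] that an antecedent carrier
#'   receives the planted outcome.
#' @param carrier_fraction fraction of the cohort made antecedent-positive,
#'   in (0,1).
#' @return object of class `planted_rule`.
#' @export
planted_rule <- function(antecedent_items, outcome, penetrance,
                         carrier_fraction) {
  stopifnot(length(antecedent_items) >= 1,
            outcome %in% c("PD", "SD"),
            penetrance >= 0, penetrance <= 1,
            carrier_fraction > 0, carrier_fraction < 1)
  structure(list(antecedent_items = antecedent_items, outcome = outcome,
                 penetrance = penetrance,
                 carrier_fraction = carrier_fraction),
            class = "planted_rule")
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the siNET study conditions: 115 patients with
#' 65 PD / 50 SD, 143 controls, 92-protein panel, log-CgA group
#' distributions from the published descriptive statistics (control
#' 1.29 (0.48), SD 2.35 (1.01), PD 3.57 (1.37)), and Table-1 clinical
#' category frequencies.
#'
#' @param n_patients cohort size.
#' @param pd_fraction fraction of patients with progressive disease;
#'   the realized PD count is `round(n_patients * pd_fraction)` before
#'   planted-rule outcome resampling.
#' @param n_biomarkers protein panel size.
#' @param n_controls control cohort size.
#' @param biomarker_params data.frame as from [default_biomarker_params()].
#' @param cga_log_params list with `control`, `SD`, `PD`, each `c(mean, sd)`
#'   of log-CgA (CgA is stored as a ULN multiple, ULN = 1 internal unit,
#'   so "CgA > 4 ULN" means raw value > 4).
#' @param hiaa_log_params list with `SD`, `PD`, each `c(meanlog, sdlog)` of
#'   5-HIAA as percent of its ULN.
#' @param clinical_frequencies per-variable category probabilities per
#'   outcome group; see `netarm:::default_clinical_frequencies`.
#' @param planted_rules list of [planted_rule()] objects, applied last.
#' @param biomarker_equicorrelation equicorrelation rho in \[0,1) shared
#'   across panel markers (single common factor); default 0 (independent).
#' @param cohort `"siNET"` or `"pNET"` label.
#' @param seed integer seed; identical config (incl. seed) gives
#'   bit-identical cohorts. Controls use `seed + 1`.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 115,
                          pd_fraction = 65 / 115,
                          n_biomarkers = 92,
                          n_controls = 143,
                          biomarker_params = default_biomarker_params(n_biomarkers),
                          cga_log_params = list(control = c(1.29, 0.48),
                                                SD = c(2.35, 1.01),
                                                PD = c(3.57, 1.37)),
                          hiaa_log_params = list(SD = c(5.0, 0.9),
                                                 PD = c(6.0, 1.0)),
                          clinical_frequencies = default_clinical_frequencies(),
                          planted_rules = list(),
                          biomarker_equicorrelation = 0,
                          cohort = "siNET",
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 1,
            pd_fraction >= 0, pd_fraction <= 1,
            nrow(biomarker_params) == n_biomarkers,
            biomarker_equicorrelation >= 0, biomarker_equicorrelation < 1,
            is.numeric(seed), length(seed) == 1)
  sd_cols <- c("control_sd", "sd_sd", "pd_sd")
  if (any(as.matrix(biomarker_params[sd_cols]) <= 0)) {
    stop("all biomarker SDs must be > 0")
  }
  for (nm in c("control", "SD", "PD")) {
    if (!is.null(cga_log_params[[nm]]) && cga_log_params[[nm]][2] <= 0) {
      stop("cga_log_params SDs must be > 0")
    }
  }
  for (v in names(clinical_frequencies)) {
    f <- clinical_frequencies[[v]]
    if (!is.null(f$levels)) {
      for (g in c("SD", "PD")) {
        if (abs(sum(f[[g]]) - 1) > 1e-9) {
          stop("probabilities for '", v, "' (", g, ") must sum to 1")
        }
      }
    }
  }
  for (pr in planted_rules) {
    if (!inherits(pr, "planted_rule")) stop("planted_rules must be planted_rule objects")
    for (it in pr$antecedent_items) item_semantics(it, biomarker_params$marker)
  }
  structure(list(
    n_patients = n_patients, pd_fraction = pd_fraction,
    n_biomarkers = n_biomarkers, n_controls = n_controls,
    biomarker_params = biomarker_params,
    cga_log_params = cga_log_params, hiaa_log_params = hiaa_log_params,
    clinical_frequencies = clinical_frequencies,
    planted_rules = planted_rules,
    biomarker_equicorrelation = biomarker_equicorrelation,
    cohort = cohort, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw an n x m matrix of marker values with optional single-factor
# equicorrelation; columns named after the markers.
draw_panel <- function(n, means, sds, markers, rho) {
  m <- length(markers)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0) {
    common <- stats::rnorm(n)
    z <- sqrt(rho) * common + sqrt(1 - rho) * z
  }
  x <- sweep(sweep(z, 2, sds, `*`), 2, means, `+`)
  colnames(x) <- markers
  x
}

draw_categorical <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Generate the control cohort
#'
#' Controls carry the protein panel (plus log-normal CgA) but no outcome;
#' they exist to supply the reference intervals for biomarker
#' discretization.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `control_id`, `gender`, `age`,
#'   `cga_uln`, and one column per panel marker; the marker names are in
#'   `attr(, "biomarkers")`.
#' @export
generate_controls <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  n <- config$n_controls
  bp <- config$biomarker_params
  panel <- draw_panel(n, bp$control_mean, bp$control_sd, bp$marker,
                      config$biomarker_equicorrelation)
  ctrl <- data.frame(
    control_id = sprintf("C%03d", seq_len(n)),
    gender = draw_categorical(n, c("F", "M"), c(0.44, 0.56)),
    age = round(pmin(pmax(stats::rnorm(n, 65, 10), 30), 88)),
    cga_uln = exp(stats::rnorm(n, config$cga_log_params$control[1],
                               config$cga_log_params$control[2])),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  ctrl <- cbind(ctrl, as.data.frame(panel, check.names = FALSE))
  attr(ctrl, "biomarkers") <- bp$marker
  ctrl
}

#' Generate the patient cohort
#'
#' Outcome labels are assigned first (exactly `round(n * pd_fraction)` PD),
#' then clinical categories, Ki-67 (conditioned on grade), log-CgA, 5-HIAA
#' and the protein panel are drawn per outcome group; planted rules are
#' applied last (see Details).
#'
#' @details
#' For each [planted_rule()], a random `carrier_fraction` of patients has
#' every antecedent variable pushed past its cut-off and the outcome
#' resampled to the planted consequent with probability `penetrance`.
#' Patients outside the carrier set that happen to satisfy the antecedent
#' naturally have one antecedent variable (chosen at random) pushed to the
#' other side of its cut-off, so that antecedent positivity coincides with
#' carrier status and the mined confidence of the planted rule estimates
#' its penetrance.
#'
#' @param config a [cohort_config()].
#' @return data.frame, one row per patient: identifiers, clinical
#'   variables, `cga_uln`, `hiaa_pct_uln`, the panel markers, `outcome`.
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  n_pd <- round(n * config$pd_fraction)
  outcome <- sample(c(rep("PD", n_pd), rep("SD", n - n_pd)))
  is_pd <- outcome == "PD"
  freq <- config$clinical_frequencies

  draw_by_group <- function(spec) {
    out <- character(n)
    for (g in c("SD", "PD")) {
      idx <- which(outcome == g)
      if (length(idx)) out[idx] <- draw_categorical(length(idx), spec$levels, spec[[g]])
    }
    out
  }
  draw_bernoulli <- function(spec) {
    p <- ifelse(is_pd, spec$PD, spec$SD)
    stats::runif(n) < p
  }

  gender <- draw_by_group(freq$gender)
  net_grade <- draw_by_group(freq$net_grade)
  n_status <- draw_by_group(freq$n_status)
  m_status <- draw_by_group(freq$m_status)
  treatment <- draw_by_group(freq$treatment)
  liver <- draw_bernoulli(freq$liver_metastasis)
  diarrhea <- draw_bernoulli(freq$diarrhea)
  flushing <- draw_bernoulli(freq$flushing)
  bronchospasm <- draw_bernoulli(freq$bronchospasm)

  # Ki-67 consistent with WHO grade bands (G1 < 3%, G2 3-20%).
  ki67 <- numeric(n)
  ki67[net_grade == "G1"] <- stats::runif(sum(net_grade == "G1"), 0.2, 2.9)
  ki67[net_grade == "G2"] <- stats::runif(sum(net_grade == "G2"), 3, 19.5)
  ki67[net_grade == "missing"] <- stats::runif(sum(net_grade == "missing"), 1, 15)
  ki67 <- round(ki67, 1)

  n_metastases <- stats::rnbinom(n, size = 2, mu = ifelse(is_pd, 9, 4))

  cga_mu <- ifelse(is_pd, config$cga_log_params$PD[1], config$cga_log_params$SD[1])
  cga_sd <- ifelse(is_pd, config$cga_log_params$PD[2], config$cga_log_params$SD[2])
  cga_uln <- exp(stats::rnorm(n, cga_mu, cga_sd))

  hiaa_mu <- ifelse(is_pd, config$hiaa_log_params$PD[1], config$hiaa_log_params$SD[1])
  hiaa_sd <- ifelse(is_pd, config$hiaa_log_params$PD[2], config$hiaa_log_params$SD[2])
  hiaa <- exp(stats::rnorm(n, hiaa_mu, hiaa_sd))

  bp <- config$biomarker_params
  panel <- matrix(NA_real_, n, config$n_biomarkers,
                  dimnames = list(NULL, bp$marker))
  for (g in c("SD", "PD")) {
    idx <- which(outcome == g)
    if (!length(idx)) next
    mcol <- if (g == "PD") "pd_mean" else "sd_mean"
    scol <- if (g == "PD") "pd_sd" else "sd_sd"
    panel[idx, ] <- draw_panel(length(idx), bp[[mcol]], bp[[scol]],
                               bp$marker, config$biomarker_equicorrelation)
  }

  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    cohort = config$cohort,
    gender = gender,
    age = round(pmin(pmax(stats::rnorm(n, 66, 10), 38), 88)),
    net_grade = net_grade, ki67 = ki67,
    n_status = n_status, m_status = m_status,
    liver_metastasis = liver, n_metastases = n_metastases,
    diarrhea = diarrhea, flushing = flushing, bronchospasm = bronchospasm,
    treatment = treatment,
    cga_uln = cga_uln, hiaa_pct_uln = hiaa,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df <- cbind(df, as.data.frame(panel, check.names = FALSE))
  df$outcome <- outcome

  for (pr in config$planted_rules) df <- apply_planted_rule(df, pr, bp$marker)
  attr(df, "biomarkers") <- bp$marker
  df
}

# ---- planted-rule machinery ------------------------------------------------

# Map an item label to (test, set-positive, set-negative) semantics over
# the cohort data.frame. Errors on labels outside the generator's
# vocabulary, which doubles as config validation.
item_semantics <- function(label, markers) {
  set_col <- function(col, value) function(df, idx) { df[[col]][idx] <- value; df }
  test_col <- function(col, value) function(df) df[[col]] == value

  if (label %in% c("female", "male")) {
    v <- if (label == "female") "F" else "M"
    o <- if (label == "female") "M" else "F"
    return(list(test = test_col("gender", v),
                pos = set_col("gender", v), neg = set_col("gender", o)))
  }
  if (label == "liver metastasis") {
    return(list(test = function(df) df$liver_metastasis,
                pos = set_col("liver_metastasis", TRUE),
                neg = set_col("liver_metastasis", FALSE)))
  }
  if (label %in% CS_SYMPTOMS) {
    return(list(test = function(df) df[[label]],
                pos = set_col(label, TRUE), neg = set_col(label, FALSE)))
  }
  if (label == "no CS symptoms") {
    return(list(
      test = function(df) !(df$diarrhea | df$flushing | df$bronchospasm),
      pos = function(df, idx) {
        df$diarrhea[idx] <- df$flushing[idx] <- df$bronchospasm[idx] <- FALSE
        df
      },
      neg = function(df, idx) { df$diarrhea[idx] <- TRUE; df }
    ))
  }
  if (label %in% c("NET grade 1", "NET grade 2")) {
    v <- if (label == "NET grade 1") "G1" else "G2"
    o <- if (v == "G1") "G2" else "G1"
    return(list(test = test_col("net_grade", v),
                pos = set_col("net_grade", v), neg = set_col("net_grade", o)))
  }
  if (label %in% c("N0", "N1", "Nx")) {
    return(list(test = test_col("n_status", label),
                pos = set_col("n_status", label),
                neg = set_col("n_status", if (label == "N0") "N1" else "N0")))
  }
  if (label %in% c("M0", "M1")) {
    return(list(test = test_col("m_status", label),
                pos = set_col("m_status", label),
                neg = set_col("m_status", if (label == "M0") "M1" else "M0")))
  }

  numeric_sem <- function(col, dir, thr, positive_scale = FALSE) {
    push_above <- function(df, idx) {
      step <- 0.05 * max(1, abs(thr))
      df[[col]][idx] <- thr + step * (1 + stats::rexp(length(idx)))
      df
    }
    push_below <- function(df, idx) {
      k <- length(idx)
      df[[col]][idx] <- if (positive_scale) {
        thr * stats::runif(k, 0.1, 0.9)
      } else {
        thr - 0.05 * max(1, abs(thr)) * (1 + stats::rexp(k))
      }
      df
    }
    if (dir == ">") {
      list(test = function(df) df[[col]] > thr, pos = push_above, neg = push_below)
    } else {
      list(test = function(df) df[[col]] < thr, pos = push_below, neg = push_above)
    }
  }

  m <- regmatches(label, regexec("^CgA > ([0-9.]+) ULN$", label))[[1]]
  if (length(m)) return(numeric_sem("cga_uln", ">", as.numeric(m[2]), TRUE))
  m <- regmatches(label, regexec("^5-HIAA > ([0-9.]+) \\(%ULN\\)$", label))[[1]]
  if (length(m)) return(numeric_sem("hiaa_pct_uln", ">", as.numeric(m[2]), TRUE))
  m <- regmatches(label, regexec("^Ki-67 (>|<=) ([0-9.]+)%$", label))[[1]]
  if (length(m)) {
    thr <- as.numeric(m[3])
    if (m[2] == ">") return(numeric_sem("ki67", ">", thr, TRUE))
    sem <- numeric_sem("ki67", ">", thr, TRUE)  # "<=" is the complement
    return(list(test = function(df) !(df$ki67 > thr), pos = sem$neg, neg = sem$pos))
  }
  m <- regmatches(label, regexec("^> ([0-9]+) metastases$", label))[[1]]
  if (length(m)) {
    thr <- as.integer(m[2])
    return(list(test = function(df) df$n_metastases > thr,
                pos = function(df, idx) { df$n_metastases[idx] <- thr + 1L +
                    stats::rpois(length(idx), 2); df },
                neg = function(df, idx) { df$n_metastases[idx] <-
                    sample.int(thr + 1L, length(idx), replace = TRUE) - 1L; df }))
  }
  m <- regmatches(label, regexec("^(.+) (<|>) ([0-9.]+)$", label))[[1]]
  if (length(m) && m[2] %in% markers) {
    return(numeric_sem(m[2], m[3], as.numeric(m[4])))
  }
  stop("cannot interpret planted antecedent item: '", label, "'")
}

apply_planted_rule <- function(df, rule, markers) {
  n <- nrow(df)
  sems <- lapply(rule$antecedent_items, item_semantics, markers = markers)
  carriers <- sample.int(n, round(rule$carrier_fraction * n))
  for (s in sems) df <- s$pos(df, carriers)
  # Kill natural antecedent carriers outside the carrier set: negate one
  # randomly chosen antecedent variable each.
  sat <- Reduce(`&`, lapply(sems, function(s) s$test(df)))
  stray <- setdiff(which(sat), carriers)
  if (length(stray)) {
    pick <- sample.int(length(sems), length(stray), replace = TRUE)
    for (j in seq_along(sems)) {
      idx <- stray[pick == j]
      if (length(idx)) df <- sems[[j]]$neg(df, idx)
    }
  }
  hit <- stats::runif(length(carriers)) < rule$penetrance
  other <- if (rule$outcome == "PD") "SD" else "PD"
  df$outcome[carriers] <- ifelse(hit, rule$outcome, other)
  df
}
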