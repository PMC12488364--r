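# Independent oracles and fixture builders. The mining oracle enumerates
# every candidate itemset and counts by scanning transactions — no shared
# code with the level-wise miner.

split_items_test <- function(s) strsplit(s, " & ", fixed = TRUE)[[1]]

oracle_frequent <- function(items_list, min_support_count, max_size) {
  catalog <- sort(unique(unlist(items_list)))
  res <- list()
  for (k in seq_len(min(max_size, length(catalog)))) {
    for (sub in utils::combn(catalog, k, simplify = FALSE)) {
      cnt <- sum(vapply(items_list, function(t) all(sub %in% t), logical(1)))
      if (cnt >= min_support_count) {
        res[[length(res) + 1]] <- list(items = sub, support_count = cnt)
      }
    }
  }
  res
}

oracle_count <- function(items_list, itemset) {
  sum(vapply(items_list, function(t) all(itemset %in% t), logical(1)))
}

oracle_rules <- function(items_list, min_support_count, rhs_constraint,
                         max_lhs) {
  N <- length(items_list)
  freq <- oracle_frequent(items_list, min_support_count,
                          max_lhs + max(lengths(rhs_constraint)))
  rows <- list()
  for (f in freq) {
    for (y in rhs_constraint) {
      y <- sort(y)
      if (!all(y %in% f$items)) next
      x <- setdiff(f$items, y)
      if (length(x) < 1 || length(x) > max_lhs) next
      cx <- oracle_count(items_list, x)
      cy <- oracle_count(items_list, y)
      rows[[length(rows) + 1]] <- data.frame(
        lhs = paste(sort(x), collapse = " & "),
        rhs = paste(y, collapse = " & "),
        support_count = f$support_count,
        support_fraction = f$support_count / N,
        confidence = f$support_count / cx,
        lift = (f$support_count / cx) * N / cy,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$rhs, out$lhs), , drop = FALSE]
}

# Random transaction DB over single-letter items, with PD/SD outcome items.
random_items_list <- function(n_tx, n_items, p_item = 0.45) {
  catalog <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i) {
    items <- catalog[stats::runif(n_items) < p_item]
    c(items, sample(c("PD", "SD"), 1))
  })
}

# One-row patient record with a complete schema; fields overridable.
make_record <- function(..., markers = c("CPE", "WISP-1")) {
  rec <- data.frame(
    patient_id = "P0001", cohort = "siNET", gender = "F", age = 65,
    net_grade = "G2", ki67 = 7, n_status = "N1", m_status = "M1",
    liver_metastasis = TRUE, n_metastases = 4,
    diarrhea = FALSE, flushing = FALSE, bronchospasm = FALSE,
    treatment = "SSA", cga_uln = 5.0, hiaa_pct_uln = 100,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (m in markers) rec[[m]] <- 3.0
  rec$outcome <- "PD"
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Hand-built cut-off table (bypasses the control cohort) for unit tests.
make_cutoffs <- function(variables, low, high, label_precision = 2) {
  out <- data.frame(
    variable = variables, low = low, high = high,
    label_low = formatC(round_half_up(low, label_precision),
                        format = "f", digits = label_precision),
    label_high = formatC(round_half_up(high, label_precision),
                         format = "f", digits = label_precision),
    source = "control_ci", n = NA_integer_, mean = NA_real_, sd = NA_real_,
    degenerate = FALSE, stringsAsFactors = FALSE)
  attr(out, "ci_level") <- 0.95
  class(out) <- c("cutoff_table", "data.frame")
  out
}

# Vector with exact sample moments: mean m, sample SD s (n-1 denominator).
exact_moments <- function(n, m, s) {
  z <- scale(stats::rnorm(n))  # exact mean 0, sd 1
  as.numeric(m + s * z)
}

# Small cohort config for fast end-to-end tests.
small_config <- function(seed = 1, n_patients = 60, n_biomarkers = 6,
                         n_controls = 50, ...) {
  cohort_config(n_patients = n_patients, n_biomarkers = n_biomarkers,
                n_controls = n_controls,
                biomarker_params = default_biomarker_params(n_biomarkers),
                seed = seed, ...)
}
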