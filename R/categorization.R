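#' @title Biomarker discretization and transaction encoding
#' @description
#' Association rule mining needs categorical items. Continuous panel
#' markers are discretized against the control cohort: the 95% confidence
#' interval of the control mean defines a reference band, and a patient
#' contributes a `"VAR < low"` or `"VAR > high"` item only when outside
#' that band (values inside emit nothing, matching the vocabulary of the
#' study's printed rules). CgA, 5-HIAA, Ki-67 and metastasis count use
#' fixed clinical thresholds; clinical categoricals pass through as one
#' item per observed category.
#' @name categorization
NULL

#' Fixed clinical discretization thresholds
#'
#' @param cga_uln_multiples numeric vector of ULN multiples; each `k`
#'   yields a `"CgA > k ULN"` item (default 4).
#' @param hiaa_pct_uln 5-HIAA threshold as percent of ULN (default 455).
#' @param ki67_pct Ki-67 split in percent (default 5): emits
#'   `"Ki-67 > 5%"` or `"Ki-67 <= 5%"`.
#' @param n_metastases count above which `"> 10 metastases"` is emitted.
#' @return named list of thresholds.
#' @export
item_thresholds <- function(cga_uln_multiples = 4, hiaa_pct_uln = 455,
                            ki67_pct = 5, n_metastases = 10) {
  list(cga_uln_multiples = cga_uln_multiples, hiaa_pct_uln = hiaa_pct_uln,
       ki67_pct = ki67_pct, n_metastases = n_metastases)
}

#' Derive control-cohort confidence-interval cut-offs
#'
#' For each panel marker, the cut-offs are the z-based confidence bounds
#' of the control mean: `mean -/+ z * SD / sqrt(n)` at `ci_level`
#' coverage. Comparisons downstream use the unrounded bounds; item labels
#' use `label_precision` decimals (the printed labels are rounded, e.g.
#' CPE bounds 3.034/3.145 label as "3.03"/"3.14").
#'
#' @param controls control data.frame from [generate_controls()] (or any
#'   table holding the marker columns).
#' @param ci_level coverage in (0,1); default 0.95.
#' @param variables marker columns to use; defaults to
#'   `attr(controls, "biomarkers")`.
#' @param label_precision decimals for item labels (default 2).
#' @return `cutoff_table`: data.frame with one row per marker (`variable`,
#'   `low`, `high`, `label_low`, `label_high`, `source`, provenance
#'   `n`/`mean`/`sd`, `degenerate` flag); `ci_level` stored as attribute.
#' @export
derive_control_ci_cutoffs <- function(controls, ci_level = 0.95,
                                      variables = attr(controls, "biomarkers"),
                                      label_precision = 2) {
  stopifnot(is.data.frame(controls), nrow(controls) >= 2,
            ci_level > 0, ci_level < 1)
  if (is.null(variables)) stop("no biomarker variables given")
  missing_cols <- setdiff(variables, names(controls))
  if (length(missing_cols)) {
    stop("missing biomarker column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(controls)
  mu <- vapply(variables, function(v) mean(controls[[v]]), numeric(1))
  sdev <- vapply(variables, function(v) stats::sd(controls[[v]]), numeric(1))
  degenerate <- sdev == 0
  if (any(degenerate)) {
    warning("zero variance in control marker(s): ",
            paste(variables[degenerate], collapse = ", "),
            "; cut-offs collapse to the mean")
  }
  z <- stats::qnorm((1 + ci_level) / 2)
  low <- mu - z * sdev / sqrt(n)
  high <- mu + z * sdev / sqrt(n)
  out <- data.frame(
    variable = variables,
    low = low, high = high,
    label_low = formatC(round_half_up(low, label_precision),
                        format = "f", digits = label_precision),
    label_high = formatC(round_half_up(high, label_precision),
                         format = "f", digits = label_precision),
    source = "control_ci",
    n = n, mean = mu, sd = sdev, degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "ci_level") <- ci_level
  class(out) <- c("cutoff_table", "data.frame")
  out
}

# Build the (label, indicator-column) pairs for a cohort data.frame.
# Returns a logical matrix n x L with item labels as column names.
build_item_matrix <- function(records, cutoffs, thresholds) {
  n <- nrow(records)
  cols <- list()
  add <- function(label, mask) cols[[label]] <<- mask

  need <- function(var) {
    if (!var %in% names(records)) stop("missing variable: ", var)
    x <- records[[var]]
    if (anyNA(x)) {
      bad <- records$patient_id[is.na(x)]
      stop("missing value for '", var, "' (patient ",
           paste(utils::head(bad, 3), collapse = ", "), ")")
    }
    x
  }

  # Control-CI biomarker items; strict inequalities on unrounded bounds.
  for (i in seq_len(nrow(cutoffs))) {
    v <- cutoffs$variable[i]
    x <- need(v)
    add(paste0(v, " < ", cutoffs$label_low[i]), x < cutoffs$low[i])
    add(paste0(v, " > ", cutoffs$label_high[i]), x > cutoffs$high[i])
  }

  cga <- need("cga_uln")
  for (k in thresholds$cga_uln_multiples) {
    add(sprintf("CgA > %g ULN", k), cga > k)
  }
  hiaa <- need("hiaa_pct_uln")
  add(sprintf("5-HIAA > %g (%%ULN)", thresholds$hiaa_pct_uln),
      hiaa > thresholds$hiaa_pct_uln)
  ki <- need("ki67")
  add(sprintf("Ki-67 > %g%%", thresholds$ki67_pct), ki > thresholds$ki67_pct)
  add(sprintf("Ki-67 <= %g%%", thresholds$ki67_pct), ki <= thresholds$ki67_pct)

  gender <- need("gender")
  add("female", gender == "F")
  add("male", gender == "M")
  grade <- need("net_grade")
  add("NET grade 1", grade == "G1")
  add("NET grade 2", grade == "G2")
  nst <- need("n_status")
  for (lev in c("N0", "N1", "Nx")) add(lev, nst == lev)
  mst <- need("m_status")
  for (lev in c("M0", "M1")) add(lev, mst == lev)
  add("liver metastasis", need("liver_metastasis"))
  add(sprintf("> %g metastases", thresholds$n_metastases),
      need("n_metastases") > thresholds$n_metastases)
  symptoms <- lapply(CS_SYMPTOMS, need)
  names(symptoms) <- CS_SYMPTOMS
  for (s in CS_SYMPTOMS) add(s, symptoms[[s]])
  add("no CS symptoms", !Reduce(`|`, symptoms))
  tr <- need("treatment")
  for (lev in c("SSA", "SSA and surgery", "other treatment")) add(lev, tr == lev)

  outcome <- need("outcome")
  if (!all(outcome %in% c("PD", "SD"))) stop("outcome must be 'PD' or 'SD'")
  add("PD", outcome == "PD")
  add("SD", outcome == "SD")

  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  mat
}

new_transaction_db <- function(mat, patient_id) {
  mat <- mat[, colSums(mat) > 0, drop = FALSE]           # catalog = observed items
  mat <- mat[, sort_items(colnames(mat)), drop = FALSE]  # canonical column order
  out_cols <- intersect(c("PD", "SD"), colnames(mat))
  outcome_item <- rep(NA_character_, nrow(mat))
  for (oc in out_cols) outcome_item[mat[, oc]] <- oc
  structure(list(mat = mat, patient_id = patient_id,
                 outcome_item = outcome_item,
                 N = nrow(mat), catalog = colnames(mat)),
            class = "transaction_db")
}

#' Build a transaction database from item sets
#'
#' Low-level constructor used by the basket reader and by tests; normal
#' cohort encoding goes through [encode_cohort()].
#'
#' @param items list of character vectors (one item set per transaction).
#' @param patient_id identifiers; defaults to `T1..Tn`.
#' @return object of class `transaction_db` with fields `mat` (logical
#'   incidence matrix, canonical column order), `patient_id`,
#'   `outcome_item`, `N`, `catalog`.
#' @export
transaction_db <- function(items, patient_id = NULL) {
  stopifnot(is.list(items))
  n <- length(items)
  patient_id <- patient_id %||% sprintf("T%d", seq_len(n))
  catalog <- sort_items(unlist(items, use.names = FALSE))
  mat <- matrix(FALSE, n, length(catalog), dimnames = list(NULL, catalog))
  for (i in seq_len(n)) mat[i, unique(items[[i]])] <- TRUE
  if (n == 0) mat <- matrix(FALSE, 0, 0)
  new_transaction_db(mat, patient_id)
}

#' Encode a patient cohort as transactions
#'
#' @param records cohort data.frame from [generate_patients()] (or a CSV
#'   read back with the same schema).
#' @param cutoffs [derive_control_ci_cutoffs()] table.
#' @param thresholds [item_thresholds()] clinical thresholds.
#' @return `transaction_db` with one transaction per record (order
#'   preserved); outcome labels are items too, reserved for the rule
#'   consequent by the miner's RHS constraint rather than removed here.
#' @export
encode_cohort <- function(records, cutoffs, thresholds = item_thresholds()) {
  stopifnot(is.data.frame(records), inherits(cutoffs, "cutoff_table"))
  if (nrow(records) == 0) {
    return(structure(list(mat = matrix(FALSE, 0, 0), patient_id = character(0),
                          outcome_item = character(0), N = 0L,
                          catalog = character(0)),
                     class = "transaction_db"))
  }
  mat <- build_item_matrix(records, cutoffs, thresholds)
  new_transaction_db(mat, records$patient_id)
}

#' Categorize a single patient
#'
#' @param record one-row cohort data.frame.
#' @param cutoffs,thresholds as in [encode_cohort()].
#' @return list of class `transaction` with `patient_id`, `items`
#'   (canonically sorted, includes the outcome item) and `outcome_item`.
#' @export
categorize_patient <- function(record, cutoffs, thresholds = item_thresholds()) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  db <- encode_cohort(record, cutoffs, thresholds)
  structure(list(patient_id = db$patient_id[1],
                 items = db$catalog[db$mat[1, ]],
                 outcome_item = db$outcome_item[1]),
            class = "transaction")
}

#' Item sets of a transaction database
#'
#' @param db a `transaction_db`.
#' @return list of character vectors, one per transaction.
#' @export
db_items <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  lapply(seq_len(db$N), function(i) db$catalog[db$mat[i, ]])
}

#' Support count of an itemset
#'
#' @param db a `transaction_db`.
#' @param items character vector of item labels (must be in the catalog).
#' @return number of transactions containing every item.
#' @export
db_count <- function(db, items) {
  unknown <- setdiff(items, db$catalog)
  if (length(unknown)) stop("item(s) not in catalog: ",
                            paste(unknown, collapse = ", "))
  sum(rowSums(db$mat[, items, drop = FALSE]) == length(items))
}

#' Parse a comparison item label
#'
#' Inverse of the label construction: recovers variable, direction and
#' threshold from labels like `"CPE > 3.14"`, `"CgA > 4 ULN"`,
#' `"Ki-67 <= 5%"`, `"5-HIAA > 455 (%ULN)"`.
#'
#' @param label item label.
#' @return list with `variable`, `direction` (`"<"`, `">"`, `"<="`) and
#'   `threshold`, or `NULL` if the label is not a comparison item.
#' @export
parse_item_label <- function(label) {
  pats <- list(
    c("^CgA > ([0-9.]+) ULN$", "CgA", ">"),
    c("^5-HIAA > ([0-9.]+) \\(%ULN\\)$", "5-HIAA", ">"),
    c("^Ki-67 (>|<=) ([0-9.]+)%$", "Ki-67", NA),
    c("^> ([0-9]+) metastases$", "n_metastases", ">")
  )
  for (p in pats) {
    m <- regmatches(label, regexec(p[1], label))[[1]]
    if (length(m)) {
      dir <- if (is.na(p[3])) m[2] else p[3]
      thr <- as.numeric(m[length(m)])
      return(list(variable = p[2], direction = dir, threshold = thr))
    }
  }
  m <- regmatches(label, regexec("^(.+) (<|>) (-?[0-9.]+)$", label))[[1]]
  if (length(m)) {
    return(list(variable = m[2], direction = m[3], threshold = as.numeric(m[4])))
  }
  NULL
}
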