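#' @title File formats
#' @description
#' Plain-text dialects used by the workflow: cohort/control CSV (header
#' row, '.' decimal separator, UTF-8), basket transactions (one line per
#' patient: `patient_id,item1,item2,...`), rules CSV (machine-readable
#' `" & "` item separator, full precision plus 2-decimal display
#' columns), and JSON for cut-off tables, configs and diagnostics.
#' @name formats
NULL

#' Write / read a cohort or control table
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_cohort_csv` returns the data.frame with the biomarker
#'   name attribute restored from the column set.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  meta <- c("patient_id", "cohort", "gender", "age", "net_grade", "ki67",
            "n_status", "m_status", "liver_metastasis", "n_metastases",
            "diarrhea", "flushing", "bronchospasm", "treatment",
            "cga_uln", "hiaa_pct_uln", "outcome", "control_id")
  attr(x, "biomarkers") <- setdiff(names(x), meta)
  x
}

#' Write transactions in basket format
#'
#' One line per transaction: the patient id, then the item labels,
#' comma-separated.
#'
#' @param db a `transaction_db`.
#' @param path file path.
#' @export
write_basket <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  items <- db_items(db)
  lines <- vapply(seq_len(db$N), function(i) {
    paste(c(db$patient_id[i], items[[i]]), collapse = ",")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read basket-format transactions
#'
#' @param path file path.
#' @return a `transaction_db`. A malformed line (no items after the id)
#'   aborts with the line number.
#' @export
read_basket <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad)) stop("corrupted basket line ", bad[1], " in ", path,
                        ": expected patient_id followed by items")
  transaction_db(items = lapply(fields, `[`, -1),
                 patient_id = vapply(fields, `[`, character(1), 1))
}

#' Write / read a cut-off table as JSON
#'
#' @param cutoffs a `cutoff_table`.
#' @param path file path.
#' @export
write_cutoffs_json <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  payload <- list(ci_level = attr(cutoffs, "ci_level"),
                  specs = as.data.frame(cutoffs))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_cutoffs_json
#' @export
read_cutoffs_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$specs
  attr(out, "ci_level") <- payload$ci_level
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Write / read rules as CSV
#'
#' Items inside `lhs`/`rhs` are joined by `" & "` (ASCII-safe); display
#' columns carry 2-decimal confidence and lift.
#'
#' @param rules a `rule_set`.
#' @param path file path.
#' @export
write_rules_csv <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  out <- as.data.frame(rules)
  out$confidence_2dp <- round_half_up(out$confidence, 2)
  out$lift_2dp <- round_half_up(out$lift, 2)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_rules_csv
#' @export
read_rules_csv <- function(path, N = NULL) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  x$confidence_2dp <- NULL
  x$lift_2dp <- NULL
  attr(x, "N") <- N
  class(x) <- c("rule_set", "data.frame")
  x
}
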