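test_that("control-CI cut-offs match the closed-form z interval", {
  set.seed(42)
  ctrl <- data.frame(control_id = sprintf("C%d", 1:100),
                     gender = "F", age = 60,
                     X = exact_moments(100, 0, 1),
                     stringsAsFactors = FALSE)
  attr(ctrl, "biomarkers") <- "X"
  cut <- derive_control_ci_cutoffs(ctrl, 0.95)
  expect_equal(cut$low, -1.959964 / 10, tolerance = 1e-6)
  expect_equal(cut$high, 1.959964 / 10, tolerance = 1e-6)

  # Published control CPE summary (mean 3.09, SD 0.34, n 143) gives a
  # lower bound of 3.034, labelled "3.03".
  set.seed(43)
  ctrl2 <- data.frame(control_id = sprintf("C%d", 1:143), gender = "F",
                      age = 60, CPE = exact_moments(143, 3.09, 0.34),
                      stringsAsFactors = FALSE)
  attr(ctrl2, "biomarkers") <- "CPE"
  cut2 <- derive_control_ci_cutoffs(ctrl2, 0.95)
  expect_equal(cut2$low, 3.0343, tolerance = 1e-4)
  expect_equal(cut2$label_low, "3.03")
})

test_that("zero-variance markers collapse to the mean with a warning", {
  ctrl <- data.frame(control_id = c("C1", "C2", "C3"), gender = "F",
                     age = 60, X = c(2, 2, 2), stringsAsFactors = FALSE)
  attr(ctrl, "biomarkers") <- "X"
  expect_warning(cut <- derive_control_ci_cutoffs(ctrl), "zero variance")
  expect_equal(cut$low, 2)
  expect_equal(cut$high, 2)
  expect_true(cut$degenerate)
})

test_that("cut-offs are translation-equivariant", {
  set.seed(7)
  x <- rnorm(60, 5, 2)
  mk <- function(v) {
    d <- data.frame(control_id = sprintf("C%d", seq_along(v)), gender = "F",
                    age = 60, X = v, stringsAsFactors = FALSE)
    attr(d, "biomarkers") <- "X"
    derive_control_ci_cutoffs(d)
  }
  a <- mk(x); b <- mk(x + 1.7)
  expect_equal(b$low, a$low + 1.7)
  expect_equal(b$high, a$high + 1.7)
})

test_that("continuous markers emit directional items with strict bounds", {
  cut <- make_cutoffs("CPE", 3.034, 3.1457)  # labels round to 3.03 / 3.15
  tx <- categorize_patient(make_record(CPE = 3.32, markers = "CPE"), cut)
  expect_true("CPE > 3.15" %in% tx$items)
  expect_false(any(grepl("^CPE <", tx$items)))

  # exactly on the lower bound: inside the band, no CPE item
  tx2 <- categorize_patient(make_record(CPE = 3.034, markers = "CPE"), cut)
  expect_false(any(grepl("^CPE", tx2$items)))

  tx3 <- categorize_patient(make_record(CPE = 2.5, markers = "CPE"), cut)
  expect_true("CPE < 3.03" %in% tx3$items)
})

test_that("clinical thresholds and categoricals produce the study vocabulary", {
  cut <- make_cutoffs("CPE", 3.03, 3.14)
  rec <- make_record(CPE = 3.0, cga_uln = 5.0, ki67 = 7, gender = "F",
                     hiaa_pct_uln = 500, n_metastases = 12,
                     diarrhea = TRUE, markers = "CPE")
  tx <- categorize_patient(rec, cut)
  expect_true(all(c("CgA > 4 ULN", "Ki-67 > 5%", "female",
                    "5-HIAA > 455 (%ULN)", "> 10 metastases",
                    "diarrhea", "NET grade 2", "liver metastasis",
                    "M1", "N1", "SSA", "PD") %in% tx$items))
  expect_false("no CS symptoms" %in% tx$items)
  expect_equal(tx$outcome_item, "PD")

  rec2 <- make_record(CPE = 3.0, cga_uln = 0.8, ki67 = 2, gender = "M",
                      net_grade = "missing", liver_metastasis = FALSE,
                      n_metastases = 1, outcome = "SD", markers = "CPE")
  tx2 <- categorize_patient(rec2, cut)
  expect_true(all(c("male", "Ki-67 <= 5%", "no CS symptoms", "SD") %in% tx2$items))
  expect_false(any(grepl("CgA|grade|liver|metastases", tx2$items)))
})

test_that("missing values abort naming the variable", {
  cut <- make_cutoffs("CPE", 3.03, 3.14)
  expect_error(categorize_patient(make_record(CPE = NA, markers = "CPE"), cut),
               "CPE")
  expect_error(categorize_patient(make_record(cga_uln = NA, markers = "CPE"),
                                  cut), "cga_uln")
})

test_that("encode_cohort preserves order and builds the observed catalog", {
  empty <- encode_cohort(make_record(markers = "CPE")[0, ],
                         make_cutoffs("CPE", 3, 3.2))
  expect_equal(empty$N, 0L)
  expect_length(empty$catalog, 0)

  cfg <- small_config(seed = 2)
  pat <- generate_patients(cfg)
  cut <- derive_control_ci_cutoffs(generate_controls(cfg))
  db <- encode_cohort(pat, cut)
  expect_equal(db$N, nrow(pat))
  expect_identical(db$patient_id, pat$patient_id)
  expect_true(all(db$outcome_item %in% c("PD", "SD")))
  expect_identical(db$outcome_item, pat$outcome)
  expect_setequal(db$catalog, unique(unlist(db_items(db))))
})

test_that("each patient carries at most one item per continuous variable", {
  cfg <- small_config(seed = 4, n_patients = 120)
  pat <- generate_patients(cfg)
  cut <- derive_control_ci_cutoffs(generate_controls(cfg))
  db <- encode_cohort(pat, cut)
  for (v in cut$variable) {
    lo <- paste0(v, " < ", cut$label_low[match(v, cut$variable)])
    hi <- paste0(v, " > ", cut$label_high[match(v, cut$variable)])
    both <- intersect(c(lo, hi), db$catalog)
    if (length(both) == 2) {
      expect_equal(max(rowSums(db$mat[, both])), 1)
    }
  }
})

test_that("item labels round-trip to variable, direction and threshold", {
  cases <- list(
    list("CPE > 3.14", "CPE", ">", 3.14),
    list("CPE < 3.03", "CPE", "<", 3.03),
    list("CgA > 4 ULN", "CgA", ">", 4),
    list("5-HIAA > 455 (%ULN)", "5-HIAA", ">", 455),
    list("Ki-67 > 5%", "Ki-67", ">", 5),
    list("Ki-67 <= 5%", "Ki-67", "<=", 5),
    list("> 10 metastases", "n_metastases", ">", 10)
  )
  for (cs in cases) {
    p <- parse_item_label(cs[[1]])
    expect_equal(p$variable, cs[[2]])
    expect_equal(p$direction, cs[[3]])
    expect_equal(p$threshold, cs[[4]])
  }
  expect_null(parse_item_label("female"))
})

test_that("basket files round-trip and corrupted lines abort with position", {
  cfg <- small_config(seed = 6, n_patients = 25)
  pat <- generate_patients(cfg)
  db <- encode_cohort(pat, derive_control_ci_cutoffs(generate_controls(cfg)))
  f <- tempfile(fileext = ".basket")
  write_basket(db, f)
  back <- read_basket(f)
  expect_identical(back$patient_id, db$patient_id)
  expect_identical(db_items(back), db_items(db))

  lines <- readLines(f)
  lines[7] <- "P9999"
  writeLines(lines, f)
  expect_error(read_basket(f), "line 7")
})
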