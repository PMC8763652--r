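## Clinical metadata. All dates are day offsets from surgery (day 0), not
## calendar dates; the analyses only ever use relative times.

.stages <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB")
.adjuvant_levels <- c("none", "chemo", "radio", "radiochemo")
.milestone_rx <- "^(presurgery|intraoperative|postsurgery|followup_[0-9]+)$"

#' Read a clinical metadata table
#'
#' One row per patient, tab-separated, with required columns `patient_id`,
#' `stage` (TNM IA--IIIB), `resection_status` (R0/R1), `adjuvant`
#' (none/chemo/radio/radiochemo), `last_followup_day`, and optional
#' `relapse_day`/`death_day` (empty = event absent, never zero). Columns
#' named `day_<milestone>` give blood-draw day offsets from surgery;
#' milestones are restricted to `presurgery`, `intraoperative`,
#' `postsurgery` and `followup_<k>`.
#'
#' Rows violating an invariant (unknown stage, event after last follow-up)
#' fail loudly with the patient id rather than being skipped.
#'
#' @param path Path to a TSV file.
#' @return data.frame of class `clinical_table`, one row per patient, with
#'   `NA` for absent optional events.
#' @export
read_clinical_table <- function(path) {
  assert_that(file.exists(path), "clinical table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param clinical A `clinical_table` data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a clinical data.frame
#'
#' @param df data.frame in the [read_clinical_table()] schema.
#' @return The validated data.frame, classed `clinical_table`.
#' @export
validate_clinical <- function(df) {
  req <- c("patient_id", "stage", "resection_status", "adjuvant",
           "last_followup_day")
  miss <- setdiff(req, names(df))
  assert_that(length(miss) == 0L, "clinical table missing columns: %s",
              paste(miss, collapse = ", "))
  for (nm in c("relapse_day", "death_day")) if (!nm %in% names(df)) df[[nm]] <- NA_real_
  for (nm in c("relapse_day", "death_day", "last_followup_day")) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  day_cols <- grep("^day_", names(df), value = TRUE)
  bad_ms <- day_cols[!grepl(.milestone_rx, sub("^day_", "", day_cols))]
  assert_that(length(bad_ms) == 0L, "unknown milestone column(s): %s",
              paste(bad_ms, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    id <- df$patient_id[i]
    assert_that(df$stage[i] %in% .stages,
                "patient %s: unknown stage label '%s'", id, df$stage[i])
    assert_that(df$resection_status[i] %in% c("R0", "R1"),
                "patient %s: resection_status must be R0/R1", id)
    assert_that(df$adjuvant[i] %in% .adjuvant_levels,
                "patient %s: unknown adjuvant treatment '%s'", id, df$adjuvant[i])
    assert_that(!is.na(df$last_followup_day[i]),
                "patient %s: last_followup_day is required", id)
    for (nm in c("relapse_day", "death_day")) {
      v <- df[[nm]][i]
      assert_that(is.na(v) || v <= df$last_followup_day[i],
                  "patient %s: %s (%s) after last_followup_day (%s)",
                  id, nm, v, df$last_followup_day[i])
    }
  }
  assert_that(!anyDuplicated(df$patient_id), "duplicate patient_id values")
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Milestone sample days for one patient
#'
#' @param clinical A `clinical_table`.
#' @param patient_id Patient identifier.
#' @return Named numeric vector, milestone -> day offset (absent days dropped).
#' @export
milestone_days <- function(clinical, patient_id) {
  row <- clinical[clinical$patient_id == patient_id, , drop = FALSE]
  assert_that(nrow(row) == 1L, "patient %s not found in clinical table", patient_id)
  day_cols <- grep("^day_", names(clinical), value = TRUE)
  v <- suppressWarnings(as.numeric(row[1, day_cols]))
  names(v) <- sub("^day_", "", day_cols)
  v[!is.na(v)]
}

#' Stage group (I--II vs III) from a TNM stage label
#'
#' @param stage Character vector of stage labels (IA--IIIB).
#' @return Character vector, `"I-II"` or `"III"`.
#' @export
stage_group <- function(stage) {
  ifelse(grepl("^III", stage), "III", "I-II")
}
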