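## Cohort file I/O. One patient = one row; UTF-8, comma-separated CSV with a
## mandatory header; categorical answers as the canonical tokens of
## response_vocabularies(); multiple diseases joined with ";".

mandatory_cohort_cols <- c("name_id", "age", "sex", "height_cm", "weight_kg",
                           "weight_change", "intake_reduction",
                           "diet_texture", "appetite")

#' Read a cohort CSV
#'
#' Reads and validates the canonical cohort layout. Missing mandatory
#' columns are an error; unknown columns are kept with a warning. Rows with
#' invalid categorical tokens are either dropped (`strict = TRUE`) or kept
#' and flagged in a logical `row_valid` column (`strict = FALSE`, the
#' default), with a per-row problem description in `row_problem`.
#'
#' @param path CSV file path.
#' @param strict Drop invalid rows instead of flagging them.
#' @return A data frame; attribute `n_invalid` counts flagged/dropped rows.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(mandatory_cohort_cols, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  known <- c(mandatory_cohort_cols, "timeframe_months", "diseases",
             "rice_g", "meat_g", "milk_ml", "index_at_risk", "ref_at_risk",
             "ref_energy", "app_energy", "ref_protein", "app_protein")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  voc <- response_vocabularies()
  problems <- character(nrow(df))
  check <- function(col, allowed) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% allowed)
    problems[bad] <<- paste0(problems[bad], sprintf("bad %s '%s'; ", col,
                                                    df[[col]][bad]))
  }
  check("sex", c("male", "female"))
  check("weight_change", voc$weight_change)
  check("intake_reduction", voc$intake_reduction)
  check("diet_texture", voc$diet_texture)
  check("appetite", voc$appetite)
  if ("timeframe_months" %in% names(df)) {
    bad <- df$weight_change != "stable_or_gain" &
      (is.na(df$timeframe_months) | !(df$timeframe_months %in% 1:3))
    problems[bad] <- paste0(problems[bad], "missing/invalid timeframe; ")
  }
  valid <- !nzchar(problems)
  n_invalid <- sum(!valid)
  if (strict) {
    df <- df[valid, , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$row_valid <- valid
    df$row_problem <- problems
  }
  attr(df, "n_invalid") <- n_invalid
  df
}

#' @rdname read_cohort
#' @param cohort Data frame in the canonical layout.
#' @export
write_cohort <- function(cohort, path) {
  drop <- intersect(c("row_valid", "row_problem"), names(cohort))
  utils::write.csv(cohort[, setdiff(names(cohort), drop), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full score-assess-validate pipeline
#'
#' Scores both instruments, runs the dietary assessment, and — when the
#' cohort carries reference columns — validates the index flags and paired
#' intakes against them. Writes a per-patient CSV and a cohort-level JSON
#' report stamped with the package version, the scoring-config hash and the
#' seed, so every analytic output is traceable to its configuration.
#'
#' @param cohort Data frame (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param out_csv,out_json Optional output paths; `NULL` skips the write.
#' @param scoring Scoring configuration.
#' @param food_table Food composition table.
#' @param arm Which instrument's flag to validate against `ref_at_risk`
#'   (`"nrs2002"` or `"pgsgasf"`); defaults to the cohort's `arm` attribute,
#'   else `"nrs2002"`.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with `cohort` (scored + assessed per-patient
#'   frame) and `report` (the JSON-ready cohort-level list).
#' @export
run_pipeline <- function(cohort, out_csv = NULL, out_json = NULL,
                         scoring = default_scoring_config(),
                         food_table = default_food_table(),
                         arm = NULL, seed = NA) {
  if (is.null(arm)) arm <- attr(cohort, "arm")
  if (is.null(arm)) arm <- "nrs2002"
  scored <- score_cohort(cohort, scoring)
  assessed <- assess_cohort(scored, food_table)
  report <- list(
    package_version = as.character(utils::packageVersion("nutriscreen")),
    config_hash = scoring_config_hash(scoring),
    food_table_version = food_table$version,
    seed = seed,
    n = nrow(cohort),
    arm = arm)
  if ("ref_at_risk" %in% names(cohort) && nrow(cohort) > 0) {
    idx <- if (arm == "nrs2002") assessed$nrs_at_risk else assessed$pg_at_risk
    val <- screening_validation(idx, cohort$ref_at_risk)
    s <- summary(val)
    report$validation <- c(
      stats::setNames(as.list(s$value), s$metric),
      list(grades = as.list(val$grades),
           table = list(tp = val$table$tp, fp = val$table$fp,
                        fn = val$table$fn, tn = val$table$tn)))
  }
  if (all(c("app_energy", "ref_energy") %in% names(cohort)) &&
      nrow(cohort) >= 3) {
    pa <- paired_agreement(cohort$app_energy, cohort$ref_energy)
    report$energy_agreement <- list(
      mean_difference = pa$mean_difference,
      sd_difference = pa$sd_difference,
      median_relative_difference = pa$median_relative_difference,
      correlation = if (!is.null(pa$correlation)) pa$correlation$estimate
                    else NA_real_,
      test = pa$test$method, p_value = pa$test$p_value)
  }
  if (all(c("app_protein", "ref_protein") %in% names(cohort)) &&
      nrow(cohort) >= 3) {
    pa <- paired_agreement(cohort$app_protein, cohort$ref_protein)
    report$protein_agreement <- list(
      mean_difference = pa$mean_difference,
      sd_difference = pa$sd_difference,
      median_relative_difference = pa$median_relative_difference,
      correlation = if (!is.null(pa$correlation)) pa$correlation$estimate
                    else NA_real_,
      test = pa$test$method, p_value = pa$test$p_value)
  }
  if (!is.null(out_csv)) write_cohort(assessed, out_csv)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(cohort = assessed, report = report))
}
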