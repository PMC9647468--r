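## Scoring engines for the two screening instruments. Both are pure
## functions of (profile, responses, config): no hidden state, so identical
## inputs always reproduce the same RiskScore.

new_risk_score <- function(instrument, components, cutoff) {
  total <- sum(components)
  structure(
    list(instrument = instrument,
         components = components,
         total = as.integer(total),
         cutoff = as.integer(cutoff),
         at_risk = total >= cutoff),
    class = "risk_score"
  )
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("<%s> total %d (cutoff %d) -> %s\n", x$instrument, x$total,
              x$cutoff, if (x$at_risk) "AT RISK" else "not at risk"))
  comp <- paste(sprintf("%s=%d", names(x$components), x$components),
                collapse = ", ")
  cat("  components:", comp, "\n")
  invisible(x)
}

## NRS-2002 subscores --------------------------------------------------------

# Weight-loss subscore per the published worksheet: ~5-15% loss scores 1/2/3
# as the window shortens from 3 to 1 month; >15% loss scores 3 at any
# timeframe (>=15% in 3 months is already the worst row).
nrs_weight_subscore <- function(wt) {
  if (wt$category == "stable_or_gain") return(0L)
  if (wt$category == "loss_over_15pct") return(3L)
  c(`1` = 3L, `2` = 2L, `3` = 1L)[[as.character(wt$timeframe_months)]]
}

# BMI subscore. The published instrument couples low BMI with an "impaired
# general condition" qualifier; for a hospitalized oncology cohort that
# qualifier is taken as satisfied (the questionnaire never asks it).
nrs_bmi_subscore <- function(bmi) {
  if (bmi < 18.5) 3L else if (bmi < 20.5) 2L else 0L
}

# Intake-reduction subscore; the question's reduction bins mirror the
# instrument's "intake at 50-75% / 25-50% / 0-25% of requirement" rows.
nrs_intake_subscore <- function(intake) {
  c(unchanged = 0L, reduction_25_50 = 1L, reduction_50_75 = 2L,
    reduction_75_100 = 3L)[[intake$category]]
}

#' Score the adapted NRS-2002 instrument
#'
#' The final-screening form of the NRS-2002: impaired nutritional status
#' (0-3), disease severity (0-3) and an age point (1 when age >= 70), for a
#' total of 0-7; a total of 3 or more flags nutritional risk. Impaired
#' nutritional status is the worst (maximum) of three indicators: degree of
#' recent weight loss, BMI, and degree of food-intake reduction. The initial
#' four-question screen of the published instrument is deliberately not
#' modelled (standard hospital practice runs the final screening directly).
#'
#' @param profile A [patient_profile()]; supplies BMI and the age point.
#' @param weight_change A [weight_change_response()].
#' @param intake_reduction An [intake_reduction_response()].
#' @param diseases A [disease_selection()]; its severity is the disease
#'   component. Defaults to no scored disease.
#' @param config Scoring configuration; see [default_scoring_config()].
#' @return A `risk_score` with components `nutritional_status`,
#'   `disease_severity`, `age`.
#' @examples
#' p <- patient_profile("p1", age = 72, sex = "female",
#'                      height_cm = 158, weight_kg = 52.4)
#' score_nrs2002(p,
#'   weight_change_response("loss_5_to_15pct", timeframe_months = 1),
#'   intake_reduction_response("reduction_50_75"),
#'   disease_selection("major_abdominal_surgery"))
#' @export
score_nrs2002 <- function(profile, weight_change, intake_reduction,
                          diseases = disease_selection(),
                          config = default_scoring_config()) {
  stopifnot(inherits(profile, "patient_profile"),
            inherits(weight_change, "weight_change_response"),
            inherits(intake_reduction, "intake_reduction_response"),
            inherits(diseases, "disease_selection"))
  bmi <- compute_bmi(profile, warn = FALSE)
  ns <- max(nrs_weight_subscore(weight_change),
            nrs_bmi_subscore(bmi),
            nrs_intake_subscore(intake_reduction))
  comp <- c(nutritional_status = as.integer(ns),
            disease_severity = diseases$severity,
            age = if (profile$age >= 70) 1L else 0L)
  new_risk_score("NRS2002", comp, config$cutoffs$nrs2002)
}

#' Score the reduced PG-SGA-SF instrument
#'
#' The patient-completed short form reduced to its first three boxes: weight
#' history, food intake, and symptoms (appetite). A total of 4 or more flags
#' nutritional risk. Food intake is asked twice (degree of reduction, and
#' diet texture); the box contributes the greater of the two point values,
#' following the published worksheet's greatest-box-score convention. All
#' point values come from configuration ([default_scoring_config()]), since
#' deployed tools differ in their exact maps; the shipped default preserves
#' the published ordering of severities.
#'
#' @param weight_change A [weight_change_response()].
#' @param intake_reduction An [intake_reduction_response()].
#' @param diet_texture A [diet_texture_response()].
#' @param appetite An [appetite_response()].
#' @param config Scoring configuration.
#' @return A `risk_score` with components `weight_history`, `food_intake`,
#'   `symptoms`.
#' @examples
#' score_pgsgasf(weight_change_response("loss_over_15pct", 3),
#'               intake_reduction_response("reduction_75_100"),
#'               diet_texture_response("liquid"),
#'               appetite_response("frequently"))
#' @export
score_pgsgasf <- function(weight_change, intake_reduction, diet_texture,
                          appetite, config = default_scoring_config()) {
  stopifnot(inherits(weight_change, "weight_change_response"),
            inherits(intake_reduction, "intake_reduction_response"),
            inherits(diet_texture, "diet_texture_response"),
            inherits(appetite, "appetite_response"))
  pm <- config$pgsgasf
  wt <- pm$weight_change[[weight_change$category]]
  if (!is.na(weight_change$timeframe_months) &&
      weight_change$timeframe_months == 1L) {
    wt <- wt + pm$one_month_bonus
  }
  food <- max(pm$intake_reduction[[intake_reduction$category]],
              pm$diet_texture[[diet_texture$category]])
  comp <- c(weight_history = as.integer(wt),
            food_intake = as.integer(food),
            symptoms = pm$appetite[[appetite$category]])
  new_risk_score("PGSGASF", comp, config$cutoffs$pgsgasf)
}

#' Score a whole cohort data frame
#'
#' Vectorised driver over a cohort table in the canonical column layout (see
#' [read_cohort()]): scores both instruments per row and appends component
#' scores, totals and at-risk flags.
#'
#' @param cohort Data frame with profile and response columns.
#' @param config Scoring configuration.
#' @return The cohort with columns `nrs_total`, `nrs_at_risk`, `pg_total`,
#'   `pg_at_risk`, `bmi` and the per-instrument component columns appended.
#' @export
score_cohort <- function(cohort, config = default_scoring_config()) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  out <- cohort
  cols <- c("bmi", "nrs_nutritional_status", "nrs_disease_severity",
            "nrs_age_point", "nrs_total", "nrs_at_risk",
            "pg_weight_history", "pg_food_intake", "pg_symptoms",
            "pg_total", "pg_at_risk")
  for (cl in cols) out[[cl]] <- rep(NA, n)
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    prof <- patient_profile(row$name_id, row$age, row$sex,
                            row$height_cm, row$weight_kg)
    wt <- weight_change_response(row$weight_change,
                                 if ("timeframe_months" %in% names(row))
                                   row$timeframe_months else NA)
    ir <- intake_reduction_response(row$intake_reduction)
    dis <- disease_selection(
      if (!is.null(row$diseases) && !is.na(row$diseases) && nzchar(row$diseases))
        strsplit(row$diseases, ";", fixed = TRUE)[[1]] else character(),
      catalogue = config$disease_catalogue)
    nrs <- score_nrs2002(prof, wt, ir, dis, config)
    pg <- score_pgsgasf(wt, ir, diet_texture_response(row$diet_texture),
                        appetite_response(row$appetite), config)
    out$bmi[i] <- round(compute_bmi(prof, warn = FALSE), 1)
    out$nrs_nutritional_status[i] <- nrs$components[["nutritional_status"]]
    out$nrs_disease_severity[i] <- nrs$components[["disease_severity"]]
    out$nrs_age_point[i] <- nrs$components[["age"]]
    out$nrs_total[i] <- nrs$total
    out$nrs_at_risk[i] <- nrs$at_risk
    out$pg_weight_history[i] <- pg$components[["weight_history"]]
    out$pg_food_intake[i] <- pg$components[["food_intake"]]
    out$pg_symptoms[i] <- pg$components[["symptoms"]]
    out$pg_total[i] <- pg$total
    out$pg_at_risk[i] <- pg$at_risk
  }
  attr(out, "config_hash") <- scoring_config_hash(config)
  out
}
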