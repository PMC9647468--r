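#' Estimate daily energy and protein intake from a three-item report
#'
#' The shortened dietary assessment asks only for habitual daily amounts of
#' rice (g), meat (g) and milk (mL) — the dominant sources of energy and
#' protein in the target diet — and maps them linearly through a food
#' composition table:
#'
#' \deqn{E = b_E + \sum_i a_i \frac{x_i}{100} e_i}
#'
#' with amounts \eqn{x_i}, per-100g energy densities \eqn{e_i}, per-item
#' multiplicative adjustments \eqn{a_i} (absorbing unreported foods such as
#' cooking oil and vegetables) and an additive daily intercept \eqn{b_E};
#' protein analogously. Amounts above a plausibility bound (default 2000
#' per item) are flagged with a warning, not rejected.
#'
#' @param rice_g,meat_g,milk_ml Daily amounts; finite and >= 0.
#' @param table A `food_composition_table`; see [default_food_table()].
#' @param plausibility_bound Per-item warning threshold (g or mL per day).
#' @return An `intake_estimate`: list with `energy_kcal`, `protein_g`,
#'   `table_version`.
#' @examples
#' estimate_intake(300, 150, 250)
#' @export
estimate_intake <- function(rice_g, meat_g, milk_ml,
                            table = default_food_table(),
                            plausibility_bound = 2000) {
  table <- validate_food_table(table)
  amounts <- c(rice = rice_g, meat = meat_g, milk = milk_ml)
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("rice/meat/milk amounts must be finite and >= 0", call. = FALSE)
  }
  big <- amounts > plausibility_bound
  if (any(big)) {
    warning("implausibly large daily amount(s): ",
            paste(sprintf("%s=%g", names(amounts)[big], amounts[big]),
                  collapse = ", "), call. = FALSE)
  }
  energy <- table$intercepts$energy
  protein <- table$intercepts$protein
  for (nm in names(amounts)) {
    it <- table$items[[nm]]
    energy <- energy + it$adjustment * amounts[[nm]] / 100 * it$energy_density
    protein <- protein + it$adjustment * amounts[[nm]] / 100 * it$protein_density
  }
  structure(list(energy_kcal = energy, protein_g = protein,
                 table_version = table$version),
            class = "intake_estimate")
}

#' Estimate energy and protein requirements
#'
#' Weight-based requirement estimates in the style of inpatient nutrition
#' guidelines: energy factor in kcal/kg/day and protein factor in g/kg/day,
#' multiplied by current body weight. The defaults (25 kcal/kg/day, 1.2
#' g/kg/day) sit mid-range of standard inpatient guidance and are
#' overridable per call.
#'
#' @param profile A [patient_profile()].
#' @param energy_factor kcal per kg body weight per day; > 0.
#' @param protein_factor g protein per kg body weight per day; > 0.
#' @return A `requirement_estimate`: list with `energy_kcal`, `protein_g`,
#'   `energy_factor`, `protein_factor`.
#' @examples
#' p <- patient_profile("p1", 59, "male", 165, 60)
#' estimate_requirements(p) # 1500 kcal, 72 g
#' @export
estimate_requirements <- function(profile, energy_factor = 25,
                                  protein_factor = 1.2) {
  stopifnot(inherits(profile, "patient_profile"))
  if (!is.finite(energy_factor) || energy_factor <= 0 ||
      !is.finite(protein_factor) || protein_factor <= 0) {
    stop("requirement factors must be strictly positive", call. = FALSE)
  }
  structure(list(energy_kcal = energy_factor * profile$weight_kg,
                 protein_g = protein_factor * profile$weight_kg,
                 energy_factor = energy_factor,
                 protein_factor = protein_factor),
            class = "requirement_estimate")
}

#' Gap between estimated intake and requirement
#'
#' Componentwise difference, sign convention intake minus requirement: a
#' negative gap is a shortfall against the guideline target.
#'
#' @param estimate An `intake_estimate`.
#' @param requirement A `requirement_estimate`.
#' @return An `intake_gap`: list with `energy_kcal`, `protein_g`.
#' @export
intake_gap <- function(estimate, requirement) {
  stopifnot(inherits(estimate, "intake_estimate"),
            inherits(requirement, "requirement_estimate"))
  structure(list(energy_kcal = estimate$energy_kcal - requirement$energy_kcal,
                 protein_g = estimate$protein_g - requirement$protein_g),
            class = "intake_gap")
}

#' @export
print.intake_estimate <- function(x, ...) {
  cat(sprintf("estimated intake: %.0f kcal/day, %.1f g protein/day (table %s)\n",
              x$energy_kcal, x$protein_g, x$table_version))
  invisible(x)
}

#' @export
print.requirement_estimate <- function(x, ...) {
  cat(sprintf("requirement: %.0f kcal/day (%.0f kcal/kg), %.1f g protein/day (%.2f g/kg)\n",
              x$energy_kcal, x$energy_factor, x$protein_g, x$protein_factor))
  invisible(x)
}

#' @export
print.intake_gap <- function(x, ...) {
  cat(sprintf("gap (intake - requirement): %+.0f kcal/day, %+.1f g protein/day\n",
              x$energy_kcal, x$protein_g))
  invisible(x)
}

#' Dietary assessment over a cohort data frame
#'
#' Applies [estimate_intake()], [estimate_requirements()] and [intake_gap()]
#' row by row over the canonical cohort layout.
#'
#' @param cohort Data frame with `rice_g`, `meat_g`, `milk_ml` and profile
#'   columns.
#' @param table Food composition table.
#' @param energy_factor,protein_factor Requirement factors, see
#'   [estimate_requirements()].
#' @return The cohort with `energy_est`, `protein_est`, `energy_req`,
#'   `protein_req`, `energy_gap`, `protein_gap` appended.
#' @export
assess_cohort <- function(cohort, table = default_food_table(),
                          energy_factor = 25, protein_factor = 1.2) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  out <- cohort
  for (cl in c("energy_est", "protein_est", "energy_req", "protein_req",
               "energy_gap", "protein_gap")) {
    out[[cl]] <- rep(NA_real_, n)
  }
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    est <- estimate_intake(row$rice_g, row$meat_g, row$milk_ml, table)
    prof <- patient_profile(row$name_id, row$age, row$sex,
                            row$height_cm, row$weight_kg)
    req <- estimate_requirements(prof, energy_factor, protein_factor)
    gap <- intake_gap(est, req)
    out$energy_est[i] <- est$energy_kcal
    out$protein_est[i] <- est$protein_g
    out$energy_req[i] <- req$energy_kcal
    out$protein_req[i] <- req$protein_g
    out$energy_gap[i] <- gap$energy_kcal
    out$protein_gap[i] <- gap$protein_g
  }
  attr(out, "table_version") <- table$version
  out
}
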