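#' Construct a patient profile
#'
#' Basic demographic and anthropometric record for one patient, as collected
#' at admission: identifier, age in years, sex, height in centimetres and
#' weight in kilograms. Height and weight feed the BMI and the weight-loss
#' option thresholds used by the screening instruments.
#'
#' Ages outside the usual adult inpatient eligibility window (18-80 years)
#' and BMI values outside (10, 60) are accepted but trigger a warning, so
#' that plausible-but-unusual clinical data are flagged rather than refused.
#'
#' @param name_id Opaque patient identifier (coerced to character).
#' @param age Age in completed years; strictly positive.
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in centimetres; strictly positive.
#' @param weight_kg Weight in kilograms; strictly positive.
#'
#' @return An object of class `patient_profile`: a list with fields
#'   `name_id`, `age`, `sex`, `height_cm`, `weight_kg`.
#' @examples
#' p <- patient_profile("p001", age = 59, sex = "male",
#'                      height_cm = 162.5, weight_kg = 58.6)
#' compute_bmi(p)
#' @export
patient_profile <- function(name_id, age, sex, height_cm, weight_kg) {
  stopifnot(length(age) == 1L, length(height_cm) == 1L, length(weight_kg) == 1L)
  if (!is.finite(age) || age <= 0) {
    stop("age must be a strictly positive number of years", call. = FALSE)
  }
  if (!is.finite(height_cm) || height_cm <= 0) {
    stop("height_cm must be strictly positive", call. = FALSE)
  }
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be strictly positive", call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"))
  if (age < 18 || age > 80) {
    warning(sprintf("age %g is outside the usual eligibility window (18-80); scored anyway",
                    age), call. = FALSE)
  }
  p <- structure(
    list(name_id = as.character(name_id), age = as.numeric(age), sex = sex,
         height_cm = as.numeric(height_cm), weight_kg = as.numeric(weight_kg)),
    class = "patient_profile"
  )
  bmi <- unclass(compute_bmi(p, warn = FALSE))
  if (bmi <= 10 || bmi >= 60) {
    warning(sprintf("BMI %.1f kg/m^2 is outside the plausible band (10, 60); check height/weight",
                    bmi), call. = FALSE)
  }
  p
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient %s> age %g, %s, %.1f cm, %.1f kg, BMI %.1f kg/m^2\n",
              x$name_id, x$age, x$sex, x$height_cm, x$weight_kg,
              compute_bmi(x, warn = FALSE)))
  invisible(x)
}

#' Body mass index
#'
#' BMI in kg/m^2: weight in kilograms divided by the square of height in
#' metres. Full precision is returned; round to one decimal for display.
#'
#' @param profile A [patient_profile()].
#' @param warn Warn when the result falls outside the plausible (10, 60) band.
#' @return BMI in kg/m^2 (numeric scalar, full precision).
#' @examples
#' compute_bmi(patient_profile("x", 59, "male", 200, 80)) # 20
#' @export
compute_bmi <- function(profile, warn = TRUE) {
  stopifnot(inherits(profile, "patient_profile"))
  bmi <- profile$weight_kg / (profile$height_cm / 100)^2
  if (warn && (bmi <= 10 || bmi >= 60)) {
    warning(sprintf("BMI %.1f kg/m^2 outside plausible band (10, 60)", bmi),
            call. = FALSE)
  }
  bmi
}

#' Weight-loss thresholds for option labels
#'
#' Absolute weights corresponding to 5% and 15% of current body weight,
#' rounded to one decimal. Screening front-ends render these inside the
#' weight-change option labels ("loss of less than X kg", ...), so that a
#' respondent reasons in kilograms rather than percentages. The rule is a
#' strict percentage of the recorded current weight.
#'
#' @param profile A [patient_profile()].
#' @return Named numeric vector `c(kg_at_5pct=, kg_at_15pct=)`, 1 d.p.
#' @examples
#' weight_loss_thresholds(patient_profile("x", 50, "female", 160, 58))
#' @export
weight_loss_thresholds <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  w <- profile$weight_kg
  c(kg_at_5pct = round(0.05 * w, 1), kg_at_15pct = round(0.15 * w, 1))
}
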