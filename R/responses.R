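## Canonical questionnaire vocabularies. Every categorical answer travels
## through the package as one of these tokens; file readers validate against
## them and the simulator samples from them.

#' Canonical response vocabularies
#'
#' The closed sets of tokens accepted for each questionnaire item.
#'
#' @return A named list of character vectors: `weight_change`,
#'   `timeframe_months`, `intake_reduction`, `diet_texture`, `appetite`.
#' @export
response_vocabularies <- function() {
  list(
    weight_change    = c("stable_or_gain", "loss_5_to_15pct", "loss_over_15pct"),
    timeframe_months = c(1L, 2L, 3L),
    intake_reduction = c("unchanged", "reduction_25_50",
                         "reduction_50_75", "reduction_75_100"),
    diet_texture     = c("normal", "soft", "liquid", "fasting"),
    appetite         = c("never", "occasionally", "frequently")
  )
}

#' Weight-change response
#'
#' Answer to "has your weight changed over the past three months?". A loss
#' category must carry the follow-up timeframe (1, 2 or 3 months); a stable
#' weight must not.
#'
#' @param category One of `"stable_or_gain"`, `"loss_5_to_15pct"`,
#'   `"loss_over_15pct"`.
#' @param timeframe_months 1, 2 or 3 when a loss is reported; `NA` otherwise.
#' @return A `weight_change_response` list.
#' @export
weight_change_response <- function(category, timeframe_months = NA) {
  category <- match.arg(category, response_vocabularies()$weight_change)
  if (category == "stable_or_gain") {
    if (!is.na(timeframe_months)) {
      stop("timeframe_months must be absent when weight is stable", call. = FALSE)
    }
  } else {
    if (is.na(timeframe_months) || !timeframe_months %in% 1:3) {
      stop("a reported weight loss requires timeframe_months in {1, 2, 3}",
           call. = FALSE)
    }
    timeframe_months <- as.integer(timeframe_months)
  }
  structure(list(category = category, timeframe_months = timeframe_months),
            class = "weight_change_response")
}

#' Intake-reduction response
#'
#' Answer to "has there been a reduction in your food intake recently?",
#' binned as roughly none / 25-50% / 50-75% / 75-100% reduction.
#'
#' @param category One of `"unchanged"`, `"reduction_25_50"`,
#'   `"reduction_50_75"`, `"reduction_75_100"`.
#' @export
intake_reduction_response <- function(category) {
  category <- match.arg(category, response_vocabularies()$intake_reduction)
  structure(list(category = category), class = "intake_reduction_response")
}

#' Diet-texture response
#'
#' What the recent diet looks like: normal food, soft food, liquid diet, or
#' fasting.
#'
#' @param category One of `"normal"`, `"soft"`, `"liquid"`, `"fasting"`.
#' @export
diet_texture_response <- function(category) {
  category <- match.arg(category, response_vocabularies()$diet_texture)
  structure(list(category = category), class = "diet_texture_response")
}

#' Appetite (symptom) response
#'
#' Answer to "have you had a bad appetite lately?".
#'
#' @param category One of `"never"`, `"occasionally"`, `"frequently"`.
#' @export
appetite_response <- function(category) {
  category <- match.arg(category, response_vocabularies()$appetite)
  structure(list(category = category), class = "appetite_response")
}

#' Disease selection
#'
#' The diseases a patient reports, drawn from a configurable catalogue that
#' maps each disease code to a severity score 0-3. The effective severity
#' score is the maximum over the selected diseases (0 when none are selected),
#' mirroring the "worst category counts" convention of hospital screening
#' instruments.
#'
#' @param diseases Character vector of disease codes (possibly empty).
#' @param catalogue Named integer vector mapping code -> severity 0-3;
#'   defaults to the catalogue in [default_scoring_config()].
#' @return A `disease_selection` list with fields `diseases` and `severity`.
#' @examples
#' disease_selection(c("solid_tumor", "diabetes"))
#' @export
disease_selection <- function(diseases = character(),
                              catalogue = default_scoring_config()$disease_catalogue) {
  diseases <- as.character(diseases)
  stopifnot(is.numeric(catalogue) || length(catalogue) == 0L)
  unknown <- setdiff(diseases, names(catalogue))
  if (length(unknown)) {
    stop("disease code(s) not in catalogue: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sev <- if (length(diseases)) max(catalogue[diseases]) else 0L
  structure(list(diseases = diseases, severity = as.integer(sev)),
            class = "disease_selection")
}

#' Bundle of screening responses for one patient
#'
#' Convenience container carrying every questionnaire answer the two
#' instruments consume.
#'
#' @param weight_change A [weight_change_response()].
#' @param intake_reduction An [intake_reduction_response()].
#' @param diet_texture A [diet_texture_response()], or `NULL` if only the
#'   NRS-2002 is scored.
#' @param appetite An [appetite_response()], or `NULL`.
#' @param diseases A [disease_selection()], or `NULL`.
#' @export
screening_responses <- function(weight_change, intake_reduction,
                                diet_texture = NULL, appetite = NULL,
                                diseases = NULL) {
  stopifnot(inherits(weight_change, "weight_change_response"),
            inherits(intake_reduction, "intake_reduction_response"))
  if (!is.null(diet_texture)) stopifnot(inherits(diet_texture, "diet_texture_response"))
  if (!is.null(appetite)) stopifnot(inherits(appetite, "appetite_response"))
  if (!is.null(diseases)) stopifnot(inherits(diseases, "disease_selection"))
  structure(list(weight_change = weight_change,
                 intake_reduction = intake_reduction,
                 diet_texture = diet_texture,
                 appetite = appetite,
                 diseases = diseases),
            class = "screening_responses")
}
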