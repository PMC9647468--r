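## Synthetic-cohort generator. Emulates the statistical structure a paired
## index-vs-reference validation study assumes: a reference-positive
## prevalence, an index test with configured sensitivity/specificity
## (misclassification conditionally independent of demographics),
## demographics matched to a hospitalized oncology cohort, and paired
## app-vs-reference intake measurements with configured marginals and
## correlation. Questionnaire responses are sampled so that scoring them
## reproduces the record's index flag exactly.

#' Configuration for a synthetic validation cohort
#'
#' Defaults describe the study conditions the package's validation machinery
#' is exercised under: a 244-patient hospitalized oncology cohort (age
#' median 59, IQR 51-68; weight 58.6 kg, SD 8.9; BMI 22.2, SD 2.9; 63.9%
#' male), an NRS-2002 arm with reference prevalence 0.172 and index
#' sensitivity/specificity 0.810/0.767, a PG-SGA-SF arm with 0.238 and
#' 0.845/0.645, and paired daily energy intakes with reference mean 1434.1
#' kcal (SD 528.8), app mean 1578.3 kcal (SD 468.4) and correlation 0.59
#' (the implied app-minus-reference difference is then mean 144.2, SD ~455).
#' Protein intakes are lognormal, matched to reference median 61.7 g (IQR
#' 43.0-82.8) and app median 79.0 g (IQR 62.7-95.3) with target correlation
#' 0.47 on the log scale.
#'
#' @param arm `"nrs2002"` or `"pgsgasf"`: which instrument's index/reference
#'   flag structure the cohort carries (the two are simulated as separate
#'   arms; their within-patient joint distribution is not modelled).
#' @param n Cohort size.
#' @param prevalence,sensitivity,specificity Reference-positive prevalence
#'   and index-test operating characteristics; `NULL` picks the arm default.
#' @param age_median,age_iqr,age_range Age distribution (lognormal matched
#'   to median/IQR, truncated to the eligibility range).
#' @param weight_mean,weight_sd,weight_min Weight (kg), normal truncated
#'   below at `weight_min`.
#' @param bmi_mean,bmi_sd BMI (kg/m^2), normal; height is derived from
#'   weight and BMI so the triplet stays consistent.
#' @param male_fraction Probability of male sex.
#' @param energy_ref_mean,energy_ref_sd,energy_app_mean,energy_app_sd,energy_correlation
#'   Bivariate-normal daily energy intake model (kcal/day), truncated to
#'   positive pairs.
#' @param protein_ref_median,protein_ref_iqr,protein_app_median,protein_app_iqr,protein_correlation
#'   Lognormal daily protein model (g/day).
#' @param seed Optional default seed carried in the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(arm = c("nrs2002", "pgsgasf"),
                          n = 244,
                          prevalence = NULL,
                          sensitivity = NULL,
                          specificity = NULL,
                          age_median = 59, age_iqr = c(51, 68),
                          age_range = c(18, 80),
                          weight_mean = 58.6, weight_sd = 8.9, weight_min = 30,
                          bmi_mean = 22.2, bmi_sd = 2.9,
                          male_fraction = 0.639,
                          energy_ref_mean = 1434.1, energy_ref_sd = 528.8,
                          energy_app_mean = 1578.3, energy_app_sd = 468.4,
                          energy_correlation = 0.59,
                          protein_ref_median = 61.7,
                          protein_ref_iqr = c(43.0, 82.8),
                          protein_app_median = 79.0,
                          protein_app_iqr = c(62.7, 95.3),
                          protein_correlation = 0.47,
                          seed = NULL) {
  arm <- match.arg(arm)
  arm_defaults <- list(
    nrs2002 = c(prevalence = 0.172, sensitivity = 0.810, specificity = 0.767),
    pgsgasf = c(prevalence = 0.238, sensitivity = 0.845, specificity = 0.645))
  d <- arm_defaults[[arm]]
  if (is.null(prevalence)) prevalence <- d[["prevalence"]]
  if (is.null(sensitivity)) sensitivity <- d[["sensitivity"]]
  if (is.null(specificity)) specificity <- d[["specificity"]]
  probs <- c(prevalence, sensitivity, specificity)
  if (any(probs < 0 | probs > 1)) {
    stop("prevalence/sensitivity/specificity must lie in [0, 1]", call. = FALSE)
  }
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  stopifnot(weight_sd >= 0, bmi_sd >= 0, energy_ref_sd >= 0, energy_app_sd >= 0,
            abs(energy_correlation) <= 1, abs(protein_correlation) <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# lognormal parameters from a (median, IQR) summary: mu from the median,
# sigma from the IQR ratio (the two printed constraints cannot in general
# be satisfied simultaneously; the median wins)
lnorm_pars <- function(med, iqr) {
  list(mu = log(med), sigma = (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75)))
}

rtrunc <- function(n, rfun, ok, max_tries = 1000) {
  out <- rfun(n)
  for (i in seq_len(max_tries)) {
    bad <- !ok(out)
    if (!any(bad)) return(out)
    out[bad] <- rfun(sum(bad))
  }
  stop("truncated sampling failed to converge", call. = FALSE)
}

## Finite response-space enumeration ----------------------------------------

# Every (weight-change, timeframe) pair as a 7-row frame, shared by both
# instruments' enumerations.
weight_options <- function() {
  data.frame(
    weight_change = c("stable_or_gain", rep("loss_5_to_15pct", 3),
                      rep("loss_over_15pct", 3)),
    timeframe_months = c(NA, 3, 2, 1, 3, 2, 1),
    stringsAsFactors = FALSE)
}

#' Enumerate the finite questionnaire response space
#'
#' Every combination of questionnaire answers an instrument can receive,
#' with its component subscores precomputed. For the NRS-2002 the total
#' additionally depends on the patient's BMI band and age point, which are
#' supplied at scoring time; the returned frame carries the response-driven
#' subscores only.
#'
#' @param instrument `"nrs2002"` or `"pgsgasf"`.
#' @param config Scoring configuration.
#' @return A data frame, one row per response combination. For `"nrs2002"`:
#'   columns `weight_change`, `timeframe_months`, `intake_reduction`,
#'   `disease`, `weight_sub`, `intake_sub`, `disease_sub`. For `"pgsgasf"`:
#'   `weight_change`, `timeframe_months`, `intake_reduction`,
#'   `diet_texture`, `appetite`, `total`.
#' @export
enumerate_responses <- function(instrument = c("nrs2002", "pgsgasf"),
                                config = default_scoring_config()) {
  instrument <- match.arg(instrument)
  wo <- weight_options()
  voc <- response_vocabularies()
  if (instrument == "nrs2002") {
    grid <- expand.grid(w = seq_len(nrow(wo)),
                        intake_reduction = voc$intake_reduction,
                        disease = names(config$disease_catalogue),
                        stringsAsFactors = FALSE)
    out <- cbind(wo[grid$w, , drop = FALSE],
                 grid[, c("intake_reduction", "disease")])
    rownames(out) <- NULL
    out$weight_sub <- mapply(function(cat, tf) {
      nrs_weight_subscore(list(category = cat, timeframe_months = tf))
    }, out$weight_change, out$timeframe_months)
    out$intake_sub <- vapply(out$intake_reduction, function(cat) {
      nrs_intake_subscore(list(category = cat))
    }, integer(1))
    out$disease_sub <- unname(config$disease_catalogue[out$disease])
    out
  } else {
    grid <- expand.grid(w = seq_len(nrow(wo)),
                        intake_reduction = voc$intake_reduction,
                        diet_texture = voc$diet_texture,
                        appetite = voc$appetite,
                        stringsAsFactors = FALSE)
    out <- cbind(wo[grid$w, , drop = FALSE],
                 grid[, c("intake_reduction", "diet_texture", "appetite")])
    rownames(out) <- NULL
    pm <- config$pgsgasf
    wt <- unname(pm$weight_change[out$weight_change]) +
      ifelse(!is.na(out$timeframe_months) & out$timeframe_months == 1,
             pm$one_month_bonus, 0L)
    food <- pmax(unname(pm$intake_reduction[out$intake_reduction]),
                 unname(pm$diet_texture[out$diet_texture]))
    out$total <- as.integer(wt + food + unname(pm$appetite[out$appetite]))
    out
  }
}

# NRS totals for an enumeration frame given a patient's BMI and age.
nrs_totals_for_profile <- function(enum, bmi, age) {
  bmi_sub <- nrs_bmi_subscore(bmi)
  age_pt <- if (age >= 70) 1L else 0L
  pmax(enum$weight_sub, bmi_sub, enum$intake_sub) + enum$disease_sub + age_pt
}

#' Sample questionnaire responses consistent with an index flag
#'
#' Draws one response combination uniformly from the set of combinations
#' whose instrument score falls on the requested side of the at-risk cutoff,
#' guaranteeing that re-scoring the returned answers reproduces the flag.
#' For the NRS-2002 the satisfying set depends on the profile (BMI band and
#' age point); a profile for which no combination can realize the flag (for
#' flag 0: BMI below 18.5 together with age 70 or over already meets the
#' cutoff) raises an error.
#'
#' @param flag Logical: should the scored instrument flag risk?
#' @param profile A [patient_profile()] (required for `"nrs2002"`).
#' @param instrument `"nrs2002"` or `"pgsgasf"`.
#' @param config Scoring configuration.
#' @param enum Optional precomputed [enumerate_responses()] frame (for
#'   repeated sampling).
#' @param seed Optional seed for this single draw.
#' @return One row of the enumeration frame (a data frame).
#' @export
responses_for_flag <- function(flag, profile = NULL,
                               instrument = c("nrs2002", "pgsgasf"),
                               config = default_scoring_config(),
                               enum = NULL, seed = NULL) {
  instrument <- match.arg(instrument)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(enum)) enum <- enumerate_responses(instrument, config)
  if (instrument == "nrs2002") {
    stopifnot(inherits(profile, "patient_profile"))
    totals <- nrs_totals_for_profile(enum, compute_bmi(profile, warn = FALSE),
                                     profile$age)
    cutoff <- config$cutoffs$nrs2002
  } else {
    totals <- enum$total
    cutoff <- config$cutoffs$pgsgasf
  }
  sat <- which(if (flag) totals >= cutoff else totals < cutoff)
  if (!length(sat)) {
    stop("no response combination can realize this flag for this profile",
         call. = FALSE)
  }
  enum[sat[sample.int(length(sat), 1L)], , drop = FALSE]
}

## Cohort generation ---------------------------------------------------------

# Vectorised demographics. For the NRS-2002 arm a patient flagged not-at-risk
# must have BMI subscore + age point <= 2 (BMI < 18.5 alone already meets the
# cutoff under the shipped rules, as does BMI in [18.5, 20.5) at age >= 70);
# profiles violating that for a flag-0 patient are redrawn, a mild truncation
# of the joint demographic distribution among index-negatives.
sample_profiles <- function(n, config, must_allow_negative = rep(FALSE, n)) {
  ap <- lnorm_pars(config$age_median, config$age_iqr)
  draw <- function(k) {
    age <- round(rtrunc(k, function(m) stats::rlnorm(m, ap$mu, ap$sigma),
                        function(x) x >= config$age_range[1] &
                                    x <= config$age_range[2]))
    weight <- rtrunc(k, function(m) stats::rnorm(m, config$weight_mean,
                                                 config$weight_sd),
                     function(x) x > config$weight_min)
    bmi <- rtrunc(k, function(m) stats::rnorm(m, config$bmi_mean, config$bmi_sd),
                  function(x) x > 10 & x < 60)
    list(age = age, weight = weight, bmi = bmi)
  }
  p <- draw(n)
  for (i in 1:100) {
    bmi_sub <- ifelse(p$bmi < 18.5, 3L, ifelse(p$bmi < 20.5, 2L, 0L))
    bad <- must_allow_negative & (bmi_sub + (p$age >= 70) >= 3)
    if (!any(bad)) break
    redo <- draw(sum(bad))
    p$age[bad] <- redo$age; p$weight[bad] <- redo$weight
    p$bmi[bad] <- redo$bmi
    if (i == 100) stop("could not realize index flags", call. = FALSE)
  }
  p$height <- 100 * sqrt(p$weight / p$bmi)
  p$sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  p
}

# Paired positive bivariate-normal energy intakes (ref, app) with the
# configured marginals and correlation; nonpositive pairs are redrawn jointly.
sample_energy_pairs <- function(n, config) {
  r <- config$energy_correlation
  draw <- function(k) {
    ref <- stats::rnorm(k, config$energy_ref_mean, config$energy_ref_sd)
    app <- config$energy_app_mean +
      r * config$energy_app_sd / config$energy_ref_sd *
        (ref - config$energy_ref_mean) +
      stats::rnorm(k, 0, config$energy_app_sd * sqrt(1 - r^2))
    cbind(ref = ref, app = app)
  }
  out <- draw(n)
  for (i in 1:1000) {
    bad <- out[, 1] <= 0 | out[, 2] <= 0
    if (!any(bad)) return(out)
    out[bad, ] <- draw(sum(bad))
  }
  stop("energy sampling failed to converge", call. = FALSE)
}

sample_protein_pairs <- function(n, config) {
  pr <- lnorm_pars(config$protein_ref_median, config$protein_ref_iqr)
  pa <- lnorm_pars(config$protein_app_median, config$protein_app_iqr)
  r <- config$protein_correlation
  lr <- stats::rnorm(n, pr$mu, pr$sigma)
  la <- pa$mu + r * pa$sigma / pr$sigma * (lr - pr$mu) +
    stats::rnorm(n, 0, pa$sigma * sqrt(1 - r^2))
  cbind(ref = exp(lr), app = exp(la))
}

# Invert the app's energy estimate into plausible rice/meat/milk amounts:
# random shares (Dirichlet around typical contributions) of the energy that
# the composition table must explain, so that estimate_intake() on the
# amounts reproduces the app energy through the shipped table.
amounts_from_energy <- function(app_energy, food_table) {
  n <- length(app_energy)
  conc <- c(rice = 10, meat = 7, milk = 3) # Dirichlet concentration
  g <- matrix(stats::rgamma(3 * n, shape = rep(conc, each = n)), n, 3)
  shares <- g / rowSums(g)
  energy_to_split <- pmax(0, app_energy - food_table$intercepts$energy)
  per_gram <- vapply(names(conc), function(nm) {
    it <- food_table$items[[nm]]
    it$adjustment * it$energy_density / 100
  }, numeric(1))
  amts <- shares * energy_to_split / rep(per_gram, each = n)
  colnames(amts) <- names(conc)
  amts
}

#' Generate a synthetic validation cohort
#'
#' Draws `n` patients under a [cohort_config()]: reference at-risk flags
#' from the prevalence, index flags conditionally on the reference flag with
#' the configured sensitivity/specificity, demographics from the stated
#' distributions, questionnaire responses sampled (via
#' [responses_for_flag()]) so the configured instrument re-scores to the
#' index flag, paired app/reference energy and protein intakes, and
#' rice/meat/milk amounts that reproduce the app's energy estimate through
#' the food-composition table. NRS-2002 profiles that cannot realize a
#' negative index flag (BMI < 18.5 with age >= 70) are redrawn.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`); the cohort is a
#'   deterministic function of (config, seed).
#' @param scoring Scoring configuration.
#' @param food_table Food composition table.
#' @return A data frame, one row per patient, in the canonical cohort
#'   layout consumed by [score_cohort()], [assess_cohort()] and
#'   [read_cohort()]; carries `index_at_risk`, `ref_at_risk`, intake pairs
#'   and an `arm` attribute.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 20), seed = 1)
#' table(coh$index_at_risk, coh$ref_at_risk)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            scoring = default_scoring_config(),
                            food_table = default_food_table()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  if (n == 0) {
    out <- empty_cohort()
    attr(out, "arm") <- config$arm
    return(out)
  }
  enum <- enumerate_responses(config$arm, scoring)
  voc <- response_vocabularies()
  ref <- stats::runif(n) < config$prevalence
  idx <- ifelse(ref, stats::runif(n) < config$sensitivity,
                stats::runif(n) >= config$specificity)
  prof <- sample_profiles(n, config,
                          must_allow_negative = (config$arm == "nrs2002") & !idx)
  # responses: sample uniformly within each (satisfying-set) group
  pick <- integer(n)
  if (config$arm == "nrs2002") {
    bmi_sub <- ifelse(prof$bmi < 18.5, 3L, ifelse(prof$bmi < 20.5, 2L, 0L))
    age_pt <- as.integer(prof$age >= 70)
    grp <- interaction(bmi_sub, age_pt, idx, drop = TRUE)
    for (g in levels(grp)) {
      rows_g <- which(grp == g)
      i1 <- rows_g[1]
      totals <- pmax(enum$weight_sub, bmi_sub[i1], enum$intake_sub) +
        enum$disease_sub + age_pt[i1]
      sat <- which(if (idx[i1]) totals >= scoring$cutoffs$nrs2002
                   else totals < scoring$cutoffs$nrs2002)
      if (!length(sat)) stop("empty satisfying set", call. = FALSE)
      pick[rows_g] <- sat[sample.int(length(sat), length(rows_g),
                                     replace = TRUE)]
    }
  } else {
    for (fl in c(FALSE, TRUE)) {
      rows_g <- which(idx == fl)
      if (!length(rows_g)) next
      sat <- which(if (fl) enum$total >= scoring$cutoffs$pgsgasf
                   else enum$total < scoring$cutoffs$pgsgasf)
      pick[rows_g] <- sat[sample.int(length(sat), length(rows_g),
                                     replace = TRUE)]
    }
  }
  resp <- enum[pick, , drop = FALSE]
  # items the configured instrument does not constrain are drawn uniformly
  if (config$arm == "nrs2002") {
    texture <- sample(voc$diet_texture, n, replace = TRUE)
    appet <- sample(voc$appetite, n, replace = TRUE)
    disease <- resp$disease
  } else {
    texture <- resp$diet_texture
    appet <- resp$appetite
    disease <- sample(names(scoring$disease_catalogue), n, replace = TRUE)
  }
  en <- sample_energy_pairs(n, config)
  pro <- sample_protein_pairs(n, config)
  amts <- amounts_from_energy(en[, "app"], food_table)
  out <- data.frame(
    name_id = sprintf("sim%04d", seq_len(n)), age = prof$age, sex = prof$sex,
    height_cm = prof$height, weight_kg = prof$weight,
    weight_change = resp$weight_change,
    timeframe_months = resp$timeframe_months,
    intake_reduction = resp$intake_reduction,
    diet_texture = texture, appetite = appet, diseases = disease,
    rice_g = amts[, "rice"], meat_g = amts[, "meat"], milk_ml = amts[, "milk"],
    index_at_risk = idx, ref_at_risk = ref,
    ref_energy = en[, "ref"], app_energy = en[, "app"],
    ref_protein = pro[, "ref"], app_protein = pro[, "app"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "arm") <- config$arm
  out
}

empty_cohort <- function() {
  data.frame(name_id = character(), age = numeric(), sex = character(),
             height_cm = numeric(), weight_kg = numeric(),
             weight_change = character(), timeframe_months = numeric(),
             intake_reduction = character(), diet_texture = character(),
             appetite = character(), diseases = character(),
             rice_g = numeric(), meat_g = numeric(), milk_ml = numeric(),
             index_at_risk = logical(), ref_at_risk = logical(),
             ref_energy = numeric(), app_energy = numeric(),
             ref_protein = numeric(), app_protein = numeric(),
             stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment
#'
#' Generates `n_reps` independent cohorts under one configuration, runs the
#' validation statistics on each (2x2 table from the index/reference flags;
#' paired energy agreement), and summarises how well the configured
#' operating characteristics are recovered — the package's own calibration
#' check for the whole simulate-score-validate loop.
#'
#' @param config A [cohort_config()].
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A `recovery_experiment` list: `replicates` (data frame with one
#'   row per replicate: `sensitivity`, `specificity`, `prevalence`, `kappa`,
#'   `energy_bias`, `energy_cor`), `summary` (mean and SD per column),
#'   `config`, `n_reps`.
#' @examples
#' rec <- recovery_experiment(cohort_config(n = 60), n_reps = 5, seed = 1)
#' rec$summary
#' @export
recovery_experiment <- function(config = cohort_config(), n_reps = 100,
                                seed = 1) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(config, seed = rep_seeds[r])
    tab <- table_from_pairs(coh$index_at_risk, coh$ref_at_risk)
    kap <- cohens_kappa(tab)
    sens <- if (tab$tp + tab$fn > 0) tab$tp / (tab$tp + tab$fn) else NA_real_
    spec <- if (tab$tn + tab$fp > 0) tab$tn / (tab$tn + tab$fp) else NA_real_
    reps[[r]] <- data.frame(
      sensitivity = sens, specificity = spec,
      prevalence = (tab$tp + tab$fn) / tab$n,
      kappa = if (kap$defined) kap$kappa else NA_real_,
      energy_bias = mean(coh$app_energy - coh$ref_energy),
      energy_cor = stats::cor(coh$app_energy, coh$ref_energy))
  }
  replicates <- do.call(rbind, reps)
  summ <- data.frame(
    statistic = names(replicates),
    mean = vapply(replicates, mean, numeric(1), na.rm = TRUE),
    sd = vapply(replicates, stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  structure(list(replicates = replicates, summary = summ, config = config,
                 n_reps = n_reps),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("recovery experiment: %d replicates of n = %d (%s arm)\n",
              x$n_reps, x$config$n, x$config$arm))
  print(x$summary, digits = 3)
  invisible(x)
}
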