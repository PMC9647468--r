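# Independent oracles, written as literal table lookups / brute-force
# enumerations so they share no code path with the implementation.

# NRS-2002 scored by explicit lookup rows (worksheet transcription).
oracle_nrs_total <- function(bmi, age, weight_change, timeframe,
                             intake_reduction, disease_severity) {
  wl_rows <- list(
    c("stable_or_gain", NA, 0), c("loss_5_to_15pct", 3, 1),
    c("loss_5_to_15pct", 2, 2), c("loss_5_to_15pct", 1, 3),
    c("loss_over_15pct", 3, 3), c("loss_over_15pct", 2, 3),
    c("loss_over_15pct", 1, 3))
  wl <- NA
  for (r in wl_rows) {
    if (r[1] == weight_change &&
        (is.na(r[2]) && is.na(timeframe) ||
         !is.na(r[2]) && !is.na(timeframe) && as.numeric(r[2]) == timeframe)) {
      wl <- as.numeric(r[3])
    }
  }
  bmi_s <- if (bmi < 18.5) 3 else if (bmi < 20.5) 2 else 0
  in_s <- switch(intake_reduction, unchanged = 0, reduction_25_50 = 1,
                 reduction_50_75 = 2, reduction_75_100 = 3)
  max(wl, bmi_s, in_s) + disease_severity + (if (age >= 70) 1 else 0)
}

# PG-SGA-SF under the shipped default point map, literal arithmetic.
oracle_pg_total <- function(weight_change, timeframe, intake_reduction,
                            diet_texture, appetite) {
  wt <- switch(weight_change, stable_or_gain = 0, loss_5_to_15pct = 3,
               loss_over_15pct = 4)
  if (!is.na(timeframe) && timeframe == 1) wt <- wt + 1
  red <- switch(intake_reduction, unchanged = 0, reduction_25_50 = 1,
                reduction_50_75 = 2, reduction_75_100 = 3)
  tex <- switch(diet_texture, normal = 0, soft = 1, liquid = 2, fasting = 4)
  sym <- switch(appetite, never = 0, occasionally = 1, frequently = 3)
  wt + max(red, tex) + sym
}

# Brute-force 2x2 tally over pairs.
oracle_tally <- function(idx, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(idx)) {
    if (idx[i] && ref[i]) tp <- tp + 1L
    else if (idx[i] && !ref[i]) fp <- fp + 1L
    else if (!idx[i] && ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# From-first-principles metric recomputation for a 2x2 table.
oracle_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(accuracy = po,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn),
       kappa = (po - pe) / (1 - pe))
}

# Two-sided exact binomial p at p = 1/2 by full enumeration: sum of all
# outcome probabilities not exceeding the observed one.
oracle_exact_binom_p <- function(b, n) {
  probs <- sapply(0:n, function(k) choose(n, k) * 0.5^n)
  sum(probs[probs <= probs[b + 1] * (1 + 1e-10)])
}

# Spearman by rank-then-Pearson.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Random 2x2 table with all margins positive.
random_table <- function() {
  repeat {
    cells <- stats::rmultinom(1, size = sample(20:400, 1),
                              prob = stats::runif(4, 0.05, 1))[, 1]
    if ((cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0 &&
        (cells[1] + cells[2]) > 0 && (cells[3] + cells[4]) > 0) {
      return(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}

# Standard test patient.
test_profile <- function(age = 59, weight = 58.6, height = 162.5,
                         sex = "male", id = "t1") {
  patient_profile(id, age = age, sex = sex, height_cm = height,
                  weight_kg = weight)
}
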