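## Diagnostic-accuracy and agreement statistics for a paired index-test vs
## reference-test design: one patient, two binary classifications (or two
## continuous intake estimates). The 2x2 cell convention throughout is
##   tp = index+ / reference+     fp = index+ / reference-
##   fn = index- / reference+     tn = index- / reference-

#' Construct a paired 2x2 contingency table
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts (see convention above).
#' @return A `contingency_2x2` with fields `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' contingency_2x2(34, 47, 8, 155)
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("table must contain at least one observation", call. = FALSE)
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
                 n = as.integer(n)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  cat("n =", x$n, "\n")
  invisible(x)
}

#' Tally a 2x2 table from paired classification vectors
#'
#' @param index_flags,reference_flags Equal-length logical (or 0/1) vectors,
#'   one element per patient; no missing values.
#' @return A [contingency_2x2()].
#' @export
table_from_pairs <- function(index_flags, reference_flags) {
  index_flags <- as.logical(index_flags)
  reference_flags <- as.logical(reference_flags)
  if (length(index_flags) != length(reference_flags)) {
    stop("index and reference vectors must have equal length", call. = FALSE)
  }
  if (length(index_flags) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(index_flags) || anyNA(reference_flags)) {
    stop("missing values in classification vectors", call. = FALSE)
  }
  contingency_2x2(sum(index_flags & reference_flags),
                  sum(index_flags & !reference_flags),
                  sum(!index_flags & reference_flags),
                  sum(!index_flags & !reference_flags))
}

## Proportion CIs ------------------------------------------------------------

# Clopper-Pearson (exact) via the beta quantiles that binom.test uses;
# Wilson score interval as the asymptotic alternative.
proportion_ci <- function(x, n, method = c("clopper-pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  }
}

# One metric = point estimate + CI + definedness flag.
metric_entry <- function(x, n, ci_method, level = 0.95) {
  if (n == 0) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                numerator = x, denominator = n, defined = FALSE))
  }
  list(estimate = x / n, ci = proportion_ci(x, n, ci_method, level),
       numerator = as.integer(x), denominator = as.integer(n), defined = TRUE)
}

#' Diagnostic-accuracy metrics from a 2x2 table
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' values, each with a two-sided 95% confidence interval. A metric whose
#' denominator is empty is reported as undefined with an explicit flag —
#' never as a silent `NaN`.
#'
#' @param table A [contingency_2x2()].
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param level Confidence level.
#' @return A `diagnostic_metrics` list: one entry per metric, each holding
#'   `estimate` (proportion), `ci`, `numerator`, `denominator`, `defined`.
#' @examples
#' diagnostic_metrics(contingency_2x2(34, 47, 8, 155))
#' @export
diagnostic_metrics <- function(table, ci_method = c("clopper-pearson", "wilson"),
                               level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  ci_method <- match.arg(ci_method)
  out <- list(
    accuracy    = metric_entry(table$tp + table$tn, table$n, ci_method, level),
    sensitivity = metric_entry(table$tp, table$tp + table$fn, ci_method, level),
    specificity = metric_entry(table$tn, table$tn + table$fp, ci_method, level),
    ppv         = metric_entry(table$tp, table$tp + table$fp, ci_method, level),
    npv         = metric_entry(table$tn, table$tn + table$fn, ci_method, level)
  )
  structure(c(out, list(table = table, ci_method = ci_method, level = level)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    m <- x[[nm]]
    if (m$defined) {
      cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f) [%d/%d]\n", nm,
                  100 * m$estimate, 100 * m$ci[1], 100 * m$ci[2],
                  m$numerator, m$denominator))
    } else {
      cat(sprintf("  %-12s undefined (empty denominator)\n", nm))
    }
  }
  invisible(x)
}

#' Cohen's kappa for a paired 2x2 table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (tp+tn)/n} and expected agreement
#' \eqn{p_e} from the table margins. The confidence interval uses the
#' large-sample (Fleiss-Cohen-Everitt) standard error. Degenerate margins
#' with \eqn{p_e = 1} leave kappa undefined, flagged explicitly.
#'
#' @param table A [contingency_2x2()].
#' @param level Confidence level.
#' @return A `kappa_estimate` list: `kappa`, `ci`, `se`, `p_o`, `p_e`,
#'   `defined`.
#' @examples
#' cohens_kappa(contingency_2x2(34, 47, 8, 155)) # ~0.42
#' @export
cohens_kappa <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  n <- table$n
  if (n < 2) stop("kappa requires n >= 2", call. = FALSE)
  p <- matrix(c(table$tp, table$fp, table$fn, table$tn), 2, 2,
              byrow = TRUE) / n
  po <- p[1, 1] + p[2, 2]
  rows <- rowSums(p); cols <- colSums(p)
  pe <- sum(rows * cols)
  if (isTRUE(all.equal(pe, 1))) {
    return(structure(list(kappa = NA_real_, ci = c(NA_real_, NA_real_),
                          se = NA_real_, p_o = po, p_e = pe, defined = FALSE),
                     class = "kappa_estimate"))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance
  a <- sum(diag(p) * (1 - (rows + cols) * (1 - kappa))^2)
  b <- (1 - kappa)^2 * (p[1, 2] * (cols[1] + rows[2])^2 +
                        p[2, 1] * (cols[2] + rows[1])^2)
  cc <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, a + b - cc) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(kappa = kappa, ci = c(kappa - z * se, min(1, kappa + z * se)),
                 se = se, p_o = po, p_e = pe, defined = TRUE),
            class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("kappa %.2f (%.2f-%.2f)\n", x$kappa, x$ci[1], x$ci[2]))
  } else {
    cat("kappa undefined (degenerate margins)\n")
  }
  invisible(x)
}

#' McNemar's test for paired binary classifications
#'
#' Tests marginal homogeneity of the two raters using only the discordant
#' cells: \eqn{\chi^2 = (|fp - fn| - c)^2/(fp + fn)} on 1 df, with
#' continuity correction \eqn{c \in \{0, 1\}}. When the discordant total is
#' below `exact_threshold` the two-sided exact binomial test (fp successes
#' in fp+fn trials at p = 1/2) replaces the asymptotic statistic. No
#' discordant pairs at all gives statistic 0 and p = 1.
#'
#' @param table A [contingency_2x2()].
#' @param continuity_correction Apply the correction to the chi-squared
#'   variant (default `FALSE`).
#' @param exact_threshold Discordant total below which the exact binomial
#'   p-value is used (default 25).
#' @return A `mcnemar_result` list: `statistic`, `p_value`, `method`
#'   (`"asymptotic"` or `"exact-binomial"`), `discordant`.
#' @examples
#' mcnemar_test(contingency_2x2(34, 47, 8, 155)) # chi^2 ~ 27.65, p < .001
#' @export
mcnemar_test <- function(table, continuity_correction = FALSE,
                         exact_threshold = 25) {
  stopifnot(inherits(table, "contingency_2x2"))
  b <- table$fp; c_ <- table$fn
  disc <- b + c_
  if (disc == 0) {
    return(structure(list(statistic = 0, p_value = 1, method = "degenerate",
                          discordant = 0L), class = "mcnemar_result"))
  }
  cc <- if (continuity_correction) 1 else 0
  stat <- (max(0, abs(b - c_) - cc))^2 / disc
  if (disc < exact_threshold) {
    p <- stats::binom.test(b, disc, p = 0.5)$p.value
    method <- "exact-binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "asymptotic"
  }
  structure(list(statistic = stat, p_value = p, method = method,
                 discordant = as.integer(disc)),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar chi^2 = %.3f (%s, %d discordant), p = %.3g\n",
              x$statistic, x$method, x$discordant, x$p_value))
  invisible(x)
}

## Correlation ---------------------------------------------------------------

# Lilliefors-corrected Kolmogorov-Smirnov normality screen. Constant vectors
# and samples too small to screen (< 5) count as non-normal, steering tiny
# samples to the rank-based procedures.
is_normalish <- function(x, alpha = 0.05) {
  if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value >= alpha
}

#' Correlation with a Fisher-z confidence interval
#'
#' Pearson or Spearman correlation; `method = "auto"` picks Pearson when both
#' margins pass a Kolmogorov-Smirnov (Lilliefors) normality screen at
#' alpha = .05 and Spearman otherwise, mirroring the usual screen-then-test
#' convention of validation studies. The CI uses the Fisher z-transform
#' (for Spearman this is an approximation, tagged as such). A margin with
#' zero variance leaves the correlation undefined, flagged.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @param method `"pearson"`, `"spearman"` or `"auto"`.
#' @param level Confidence level.
#' @return A `correlation_estimate` list: `estimate`, `ci`, `method`,
#'   `p_value`, `n`, `defined`.
#' @export
correlation <- function(x, y, method = c("auto", "pearson", "spearman"),
                        level = 0.95) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                          method = method, p_value = NA_real_,
                          n = length(x), defined = FALSE),
                     class = "correlation_estimate"))
  }
  if (method == "auto") {
    method <- if (is_normalish(x) && is_normalish(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  n <- length(x)
  ci <- if (abs(r) < 1 && n > 3) {
    z <- atanh(r)
    zse <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    tanh(c(z - q * zse, z + q * zse))
  } else {
    c(r, r)
  }
  structure(list(estimate = r, ci = ci, method = method,
                 p_value = ct$p.value, n = n, defined = TRUE),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("CC %.2f (%.2f-%.2f), %s, n = %d, p = %.3g\n", x$estimate,
                x$ci[1], x$ci[2], x$method, x$n, x$p_value))
  } else {
    cat("correlation undefined (zero variance)\n")
  }
  invisible(x)
}

#' Paired agreement summary for continuous measurements
#'
#' Agreement of an index (app) measurement against a reference, per the
#' standard paired-difference summary: differences d = app - ref with mean
#' and SD; per-pair relative differences 100*d/ref (pairs with ref <= 0 are
#' excluded and the exclusion count logged); median and IQR of the relative
#' differences; a paired test of zero difference (paired t when d passes the
#' normality screen, Wilcoxon signed-rank otherwise); and the app-vs-ref
#' correlation via [correlation()].
#'
#' @param app_values,ref_values Equal-length numeric vectors, length >= 2.
#' @param cor_method Passed to [correlation()].
#' @return A `paired_agreement` list: `n`, `mean_difference`, `sd_difference`,
#'   `median_relative_difference`, `iqr_relative_difference` (length-2),
#'   `excluded_pairs`, `test` (`method`, `statistic`, `p_value`),
#'   `correlation`, `defined`.
#' @examples
#' paired_agreement(c(110, 90, 105), c(100, 100, 100))
#' @export
paired_agreement <- function(app_values, ref_values, cor_method = "auto") {
  if (length(app_values) != length(ref_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(app_values) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- app_values - ref_values
  ok <- ref_values > 0
  excluded <- sum(!ok)
  if (all(!ok)) {
    return(structure(list(n = length(d), excluded_pairs = excluded,
                          defined = FALSE), class = "paired_agreement"))
  }
  rel <- 100 * d[ok] / ref_values[ok]
  qs <- stats::quantile(rel, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (stats::sd(d) > 0 && is_normalish(d)) {
    tt <- stats::t.test(app_values, ref_values, paired = TRUE)
    test <- list(method = "paired-t", statistic = unname(tt$statistic),
                 p_value = tt$p.value)
  } else if (all(d == 0)) {
    test <- list(method = "degenerate", statistic = 0, p_value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(app_values, ref_values,
                                              paired = TRUE))
    test <- list(method = "wilcoxon-signed-rank",
                 statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  corr <- if (length(app_values) >= 3 && stats::sd(app_values) > 0 &&
              stats::sd(ref_values) > 0) {
    correlation(app_values, ref_values, cor_method)
  } else NULL
  structure(list(n = length(d),
                 mean_difference = mean(d),
                 sd_difference = stats::sd(d),
                 median_relative_difference = qs[2],
                 iqr_relative_difference = c(qs[1], qs[3]),
                 excluded_pairs = as.integer(excluded),
                 test = test, correlation = corr, defined = TRUE),
            class = "paired_agreement")
}

#' @export
print.paired_agreement <- function(x, ...) {
  if (!x$defined) {
    cat("paired agreement undefined (all pairs excluded)\n")
    return(invisible(x))
  }
  cat(sprintf("n = %d pairs (%d excluded, ref <= 0)\n", x$n, x$excluded_pairs))
  cat(sprintf("  difference: mean %.1f (SD %.1f)\n",
              x$mean_difference, x$sd_difference))
  cat(sprintf("  relative difference: median %.1f%% (IQR %.1f-%.1f)\n",
              x$median_relative_difference, x$iqr_relative_difference[1],
              x$iqr_relative_difference[2]))
  cat(sprintf("  %s p = %.3g\n", x$test$method, x$test$p_value))
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

## Validity grading ----------------------------------------------------------

#' Grade validity against conventional cutoffs
#'
#' Categorical good/fair/poor grades per criterion: sensitivity+specificity
#' (good: both exceed 80%; poor: either below 50%; fair otherwise),
#' correlation coefficient (good >= 0.75, fair >= 0.4, else poor) and kappa
#' (good >= 0.6, fair >= 0.4, else poor). Grades are reported per criterion
#' and never merged. Undefined inputs grade as `"undetermined"`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]` (or `NA`).
#' @param cc Correlation coefficient (or `NA`).
#' @param kappa Kappa value (or `NA`).
#' @return Named character vector with entries `sens_spec`, `cc`, `kappa`.
#' @examples
#' grade_validity(sensitivity = 0.810, specificity = 0.767,
#'                cc = 0.62, kappa = 0.42)
#' @export
grade_validity <- function(sensitivity = NA, specificity = NA,
                           cc = NA, kappa = NA) {
  gss <- if (is.na(sensitivity) || is.na(specificity)) {
    "undetermined"
  } else if (sensitivity > 0.8 && specificity > 0.8) {
    "good"
  } else if (sensitivity < 0.5 || specificity < 0.5) {
    "poor"
  } else "fair"
  gcc <- if (is.na(cc)) "undetermined"
         else if (cc >= 0.75) "good" else if (cc >= 0.4) "fair" else "poor"
  gk <- if (is.na(kappa)) "undetermined"
        else if (kappa >= 0.6) "good" else if (kappa >= 0.4) "fair" else "poor"
  c(sens_spec = gss, cc = gcc, kappa = gk)
}

#' Full screening-validation report for one instrument
#'
#' One-stop wrapper: builds the 2x2 table from paired flags (or accepts one
#' directly), computes the proportion metrics, kappa, McNemar's test, an
#' optional score-scale correlation, and the validity grades.
#'
#' @param index_flags,reference_flags Paired binary classifications, or pass
#'   `table` directly.
#' @param table Optional [contingency_2x2()]; overrides the flag vectors.
#' @param index_scores,reference_scores Optional paired numeric scores for
#'   the correlation (flags are used when scores are absent).
#' @param ci_method,continuity_correction Passed through.
#' @return A `screening_validation` list bundling `table`, `metrics`,
#'   `kappa`, `mcnemar`, `correlation` (may be `NULL`), `grades`.
#' @examples
#' screening_validation(table = contingency_2x2(34, 47, 8, 155))
#' @export
screening_validation <- function(index_flags = NULL, reference_flags = NULL,
                                 table = NULL, index_scores = NULL,
                                 reference_scores = NULL,
                                 ci_method = "clopper-pearson",
                                 continuity_correction = FALSE) {
  if (is.null(table)) {
    table <- table_from_pairs(index_flags, reference_flags)
  }
  metrics <- diagnostic_metrics(table, ci_method)
  kap <- cohens_kappa(table)
  mcn <- mcnemar_test(table, continuity_correction)
  corr <- if (!is.null(index_scores) && !is.null(reference_scores)) {
    correlation(index_scores, reference_scores, "auto")
  } else if (!is.null(index_flags) && length(index_flags) >= 3 &&
             stats::sd(as.numeric(index_flags)) > 0 &&
             stats::sd(as.numeric(reference_flags)) > 0) {
    correlation(as.numeric(index_flags), as.numeric(reference_flags), "pearson")
  } else NULL
  grades <- grade_validity(
    sensitivity = if (metrics$sensitivity$defined) metrics$sensitivity$estimate else NA,
    specificity = if (metrics$specificity$defined) metrics$specificity$estimate else NA,
    cc = if (!is.null(corr) && corr$defined) corr$estimate else NA,
    kappa = if (kap$defined) kap$kappa else NA)
  structure(list(table = table, metrics = metrics, kappa = kap,
                 mcnemar = mcn, correlation = corr, grades = grades),
            class = "screening_validation")
}

#' @export
print.screening_validation <- function(x, ...) {
  cat("Screening validation (index vs reference)\n")
  print(x$table)
  print(x$metrics)
  print(x$kappa)
  print(x$mcnemar)
  if (!is.null(x$correlation)) print(x$correlation)
  cat("grades:", paste(sprintf("%s=%s", names(x$grades), x$grades),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.screening_validation <- function(object, ...) {
  m <- object$metrics
  est <- function(e) if (e$defined) 100 * e$estimate else NA_real_
  data.frame(
    metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "kappa", "mcnemar_p"),
    value = c(est(m$accuracy), est(m$sensitivity), est(m$specificity),
              est(m$ppv), est(m$npv),
              if (object$kappa$defined) object$kappa$kappa else NA_real_,
              object$mcnemar$p_value)
  )
}
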