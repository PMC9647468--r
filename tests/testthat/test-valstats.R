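# Validation-statistics tests: cell conventions, oracle agreement,
# structural invariants, and the test variants.

test_that("table_from_pairs tallies every index/reference combination", {
  t1 <- table_from_pairs(TRUE, TRUE)
  expect_equal(c(t1$tp, t1$fp, t1$fn, t1$tn), c(1L, 0L, 0L, 0L))
  # vectors realizing the NRS validation table
  idx <- rep(c(TRUE, TRUE, FALSE, FALSE), c(34, 47, 8, 155))
  ref <- rep(c(TRUE, FALSE, TRUE, FALSE), c(34, 47, 8, 155))
  tt <- table_from_pairs(idx, ref)
  expect_equal(c(tt$tp, tt$fp, tt$fn, tt$tn), c(34L, 47L, 8L, 155L))
  expect_equal(tt$n, 244L)
  # brute-force oracle on random vectors
  set.seed(11)
  for (i in 1:20) {
    a <- runif(50) < 0.4; b <- runif(50) < 0.3
    got <- table_from_pairs(a, b)
    want <- oracle_tally(a, b)
    expect_equal(c(got$tp, got$fp, got$fn, got$tn), unname(want),
                 ignore_attr = TRUE)
  }
  expect_error(table_from_pairs(c(TRUE, FALSE), TRUE), "length")
  expect_error(table_from_pairs(logical(), logical()), "empty")
})

test_that("contingency_2x2 rejects invalid cells", {
  expect_error(contingency_2x2(-1, 0, 0, 5), "nonnegative")
  expect_error(contingency_2x2(1.5, 0, 0, 5), "nonnegative")
  expect_error(contingency_2x2(0, 0, 0, 0), "at least one")
})

test_that("perfect and degenerate tables behave explicitly", {
  for (km in list(c(3, 8), c(1, 1), c(50, 2))) {
    m <- diagnostic_metrics(contingency_2x2(km[1], 0, 0, km[2]))
    for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      expect_equal(m[[nm]]$estimate, 1)
    }
    expect_equal(cohens_kappa(contingency_2x2(km[1], 0, 0, km[2]))$kappa, 1)
  }
  # empty reference-positive margin: sensitivity undefined, flagged
  m0 <- diagnostic_metrics(contingency_2x2(0, 5, 0, 10))
  expect_false(m0$sensitivity$defined)
  expect_true(is.na(m0$sensitivity$estimate))
  expect_true(m0$specificity$defined)
  # degenerate margins: kappa undefined, flagged
  k0 <- cohens_kappa(contingency_2x2(7, 0, 0, 0))
  expect_false(k0$defined)
})

test_that("metrics match a from-first-principles oracle on random tables", {
  set.seed(101)
  for (i in 1:200) {
    tab <- random_table()
    m <- diagnostic_metrics(tab)
    k <- cohens_kappa(tab)
    want <- oracle_metrics(tab$tp, tab$fp, tab$fn, tab$tn)
    expect_equal(m$accuracy$estimate, want$accuracy, tolerance = 1e-12)
    expect_equal(m$sensitivity$estimate, want$sensitivity, tolerance = 1e-12)
    expect_equal(m$specificity$estimate, want$specificity, tolerance = 1e-12)
    expect_equal(m$ppv$estimate, want$ppv, tolerance = 1e-12)
    expect_equal(m$npv$estimate, want$npv, tolerance = 1e-12)
    expect_equal(k$kappa, want$kappa, tolerance = 1e-12)
    # accuracy * n = tp + tn exactly
    expect_equal(m$accuracy$estimate * tab$n, tab$tp + tab$tn)
    # Bayes consistency: ppv from (sens, spec, prevalence)
    prev <- (tab$tp + tab$fn) / tab$n
    ppv_bayes <- want$sensitivity * prev /
      (want$sensitivity * prev + (1 - want$specificity) * (1 - prev))
    expect_equal(m$ppv$estimate, ppv_bayes, tolerance = 1e-12)
    # CIs contain their point estimates
    for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      e <- m[[nm]]
      expect_true(e$ci[1] <= e$estimate && e$estimate <= e$ci[2])
    }
  }
})

test_that("kappa is symmetric in the raters and agrees with e1071", {
  set.seed(7)
  for (i in 1:25) {
    tab <- random_table()
    swapped <- contingency_2x2(tab$tp, tab$fn, tab$fp, tab$tn) # transpose
    expect_equal(cohens_kappa(tab)$kappa, cohens_kappa(swapped)$kappa,
                 tolerance = 1e-12)
    m <- matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2, 2)
    expect_equal(cohens_kappa(tab)$kappa, e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("confidence intervals tighten when counts are scaled up tenfold", {
  tab <- contingency_2x2(34, 47, 8, 155)
  big <- contingency_2x2(340, 470, 80, 1550)
  for (cim in c("clopper-pearson", "wilson")) {
    m1 <- diagnostic_metrics(tab, cim)
    m2 <- diagnostic_metrics(big, cim)
    for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      expect_lt(diff(m2[[nm]]$ci), diff(m1[[nm]]$ci))
    }
  }
  expect_lt(diff(cohens_kappa(big)$ci), diff(cohens_kappa(tab)$ci))
})

test_that("McNemar depends only on the discordant cells", {
  res <- mcnemar_test(contingency_2x2(34, 47, 8, 155))
  expect_equal(res$statistic, (47 - 8)^2 / 55)
  expect_lt(res$p_value, 0.001)
  # swapping concordant cells changes nothing
  res2 <- mcnemar_test(contingency_2x2(155, 47, 8, 34))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p_value, res$p_value)
  # symmetric discordance: statistic 0, p = 1
  sym <- mcnemar_test(contingency_2x2(5, 9, 9, 5))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  # no discordance at all
  none <- mcnemar_test(contingency_2x2(5, 0, 0, 5))
  expect_equal(none$p_value, 1)
})

test_that("McNemar exact and asymptotic variants match their oracles", {
  # small discordant count: exact two-sided binomial by full enumeration
  small <- mcnemar_test(contingency_2x2(10, 3, 1, 10))
  expect_equal(small$method, "exact-binomial")
  expect_equal(small$p_value, oracle_exact_binom_p(3, 4), tolerance = 1e-12)
  # asymptotic variants against stats::mcnemar.test
  tab <- contingency_2x2(34, 47, 8, 155)
  m <- matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2, 2)
  expect_equal(mcnemar_test(tab, continuity_correction = FALSE)$p_value,
               stats::mcnemar.test(m, correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(mcnemar_test(tab, continuity_correction = TRUE)$p_value,
               stats::mcnemar.test(m, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("correlation handles exact, automatic and degenerate cases", {
  x <- c(1, 3, 2, 8, 5, 7, 4)
  expect_equal(correlation(x, x, "pearson")$estimate, 1)
  expect_equal(correlation(x, -x, "pearson")$estimate, -1)
  expect_error(correlation(1:2, 1:2), "at least 3")
  expect_error(correlation(1:5, 1:4), "equal length")
  z <- correlation(rep(1, 5), 1:5)
  expect_false(z$defined)
  # Spearman fixture vs rank-then-Pearson oracle
  set.seed(33)
  a <- rlnorm(20); b <- a + rlnorm(20)
  sp <- correlation(a, b, "spearman")
  expect_equal(sp$estimate, oracle_spearman(a, b), tolerance = 1e-12)
  # auto picks Spearman for heavily skewed margins, Pearson for normal ones
  expect_equal(correlation(a, b, "auto")$method, "spearman")
  set.seed(34)
  g1 <- rnorm(60); g2 <- g1 + rnorm(60)
  expect_equal(correlation(g1, g2, "auto")$method, "pearson")
  ci <- correlation(g1, g2, "pearson")
  expect_true(ci$ci[1] <= ci$estimate && ci$estimate <= ci$ci[2])
})

test_that("paired agreement summarises differences as documented", {
  id <- paired_agreement(c(5, 5, 5), c(5, 5, 5))
  expect_equal(id$mean_difference, 0)
  expect_equal(id$sd_difference, 0)
  expect_equal(id$median_relative_difference, 0)
  sym <- paired_agreement(c(110, 90), c(100, 100))
  expect_equal(sym$mean_difference, 0)
  expect_equal(sym$median_relative_difference, 0)
  expect_equal(sym$iqr_relative_difference, c(-5, 5)) # quartiles of (+10,-10)
  # ref = 0 pairs excluded with logged count
  ex <- paired_agreement(c(10, 10, 10, 10), c(0, 10, 20, 5))
  expect_equal(ex$excluded_pairs, 1L)
  all_ex <- paired_agreement(c(1, 2), c(0, 0))
  expect_false(all_ex$defined)
  expect_equal(all_ex$excluded_pairs, 2L)
  # normal differences -> paired t; the test detects a real shift
  set.seed(55)
  ref <- rnorm(80, 100, 10)
  app <- ref + rnorm(80, 5, 4)
  pa <- paired_agreement(app, ref)
  expect_equal(pa$test$method, "paired-t")
  expect_lt(pa$test$p_value, 0.01)
  expect_equal(pa$mean_difference, mean(app - ref))
  expect_equal(pa$sd_difference, sd(app - ref))
})

test_that("validity grading applies the published cutoffs per criterion", {
  g <- grade_validity(sensitivity = 0.810, specificity = 0.767,
                      cc = 0.62, kappa = 0.42)
  expect_equal(unname(g), c("fair", "fair", "fair"))
  expect_equal(unname(grade_validity(0.85, 0.85)["sens_spec"]), "good")
  expect_equal(unname(grade_validity(0.845, 0.645)["sens_spec"]), "fair")
  expect_equal(unname(grade_validity(0.9, 0.45)["sens_spec"]), "poor")
  expect_equal(unname(grade_validity(cc = 0.76)["cc"]), "good")
  expect_equal(unname(grade_validity(cc = 0.39)["cc"]), "poor")
  expect_equal(unname(grade_validity(kappa = 0.42)["kappa"]), "fair")
  expect_equal(unname(grade_validity(kappa = 0.37)["kappa"]), "poor")
  expect_equal(unname(grade_validity(kappa = 0.61)["kappa"]), "good")
  expect_equal(unname(grade_validity()["sens_spec"]), "undetermined")
})
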