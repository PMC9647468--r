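# Scoring-engine tests: hand-scored cases, response validation, and
# exhaustive agreement with an independently written lookup oracle over the
# full finite response space.

test_that("response constructors enforce the timeframe invariant", {
  expect_error(weight_change_response("loss_5_to_15pct"), "timeframe")
  expect_error(weight_change_response("loss_over_15pct", 4), "timeframe")
  expect_error(weight_change_response("stable_or_gain", 2), "absent")
  expect_silent(weight_change_response("stable_or_gain"))
  expect_silent(weight_change_response("loss_over_15pct", 1))
  expect_error(intake_reduction_response("a_lot"))
  expect_error(diet_texture_response("crunchy"))
  expect_error(appetite_response("always"))
})

test_that("disease selection takes the worst severity, empty scores zero", {
  expect_equal(disease_selection()$severity, 0L)
  expect_equal(disease_selection("solid_tumor")$severity, 1L)
  expect_equal(disease_selection(c("solid_tumor", "intensive_care"))$severity, 3L)
  expect_equal(disease_selection(c("diabetes", "stroke"))$severity, 2L)
  expect_error(disease_selection("not_a_disease"), "catalogue")
})

test_that("NRS-2002 hand-scored cases match", {
  # all-zero case: healthy-weight 59-year-old, nothing reported
  s0 <- score_nrs2002(test_profile(age = 59),
                      weight_change_response("stable_or_gain"),
                      intake_reduction_response("unchanged"))
  expect_equal(s0$total, 0L)
  expect_false(s0$at_risk)
  expect_equal(unname(s0$components),
               c(0L, 0L, 0L))
  # 72-year-old, 5-15% loss in 1 month, 50-75% intake reduction, BMI 21,
  # disease severity 2: nutritional status 3 (worst of 3/0/2), +2 +1 = 6
  p <- test_profile(age = 72, weight = 60, height = 169.03)
  expect_equal(round(compute_bmi(p), 1), 21.0)
  s <- score_nrs2002(p, weight_change_response("loss_5_to_15pct", 1),
                     intake_reduction_response("reduction_50_75"),
                     disease_selection("major_abdominal_surgery"))
  expect_equal(s$components[["nutritional_status"]], 3L)
  expect_equal(s$components[["disease_severity"]], 2L)
  expect_equal(s$components[["age"]], 1L)
  expect_equal(s$total, 6L)
  expect_true(s$at_risk)
})

test_that("PG-SGA-SF hand-scored cases match", {
  s0 <- score_pgsgasf(weight_change_response("stable_or_gain"),
                      intake_reduction_response("unchanged"),
                      diet_texture_response("normal"),
                      appetite_response("never"))
  expect_equal(s0$total, 0L)
  expect_false(s0$at_risk)
  # severe everything: 4 (weight) + max(3, 2) + 3 = 10 under the default map
  s <- score_pgsgasf(weight_change_response("loss_over_15pct", 3),
                     intake_reduction_response("reduction_75_100"),
                     diet_texture_response("liquid"),
                     appetite_response("frequently"))
  expect_true(s$at_risk)
  expect_gte(s$total, 4L)
  expect_equal(s$total, 10L)
})

test_that("exhaustive enumeration agrees with the lookup oracle (NRS-2002)", {
  enum <- enumerate_responses("nrs2002")
  cfg <- default_scoring_config()
  for (bmi_target in c(17, 19.5, 22.2)) {
    for (age in c(50, 75)) {
      prof <- test_profile(age = age, weight = bmi_target * 1.70^2,
                           height = 170)
      for (i in seq_len(nrow(enum))) {
        r <- enum[i, ]
        s <- score_nrs2002(
          prof,
          weight_change_response(r$weight_change, r$timeframe_months),
          intake_reduction_response(r$intake_reduction),
          disease_selection(r$disease))
        want <- oracle_nrs_total(compute_bmi(prof), age, r$weight_change,
                                 r$timeframe_months, r$intake_reduction,
                                 cfg$disease_catalogue[[r$disease]])
        expect_identical(s$total, as.integer(want))
        # boundedness and cutoff consistency at every point
        expect_true(s$total >= 0L && s$total <= 7L)
        expect_true(all(s$components >= 0L) &&
                      s$components[["nutritional_status"]] <= 3L &&
                      s$components[["disease_severity"]] <= 3L &&
                      s$components[["age"]] <= 1L)
        expect_identical(s$at_risk, s$total >= 3L)
      }
    }
  }
})

test_that("exhaustive enumeration agrees with the lookup oracle (PG-SGA-SF)", {
  enum <- enumerate_responses("pgsgasf")
  for (i in seq_len(nrow(enum))) {
    r <- enum[i, ]
    s <- score_pgsgasf(weight_change_response(r$weight_change, r$timeframe_months),
                       intake_reduction_response(r$intake_reduction),
                       diet_texture_response(r$diet_texture),
                       appetite_response(r$appetite))
    want <- oracle_pg_total(r$weight_change, r$timeframe_months,
                            r$intake_reduction, r$diet_texture, r$appetite)
    expect_identical(s$total, as.integer(want))
    expect_identical(s$total, as.integer(r$total)) # enumeration self-consistent
    expect_identical(s$at_risk, s$total >= 4L)
  }
})

test_that("worsening any single response never decreases either total", {
  # severity ladders; each consecutive pair is a single-item worsening
  wc_ladder <- list(c("stable_or_gain", NA), c("loss_5_to_15pct", 3),
                    c("loss_5_to_15pct", 2), c("loss_5_to_15pct", 1),
                    c("loss_over_15pct", 1))
  ir_ladder <- c("unchanged", "reduction_25_50", "reduction_50_75",
                 "reduction_75_100")
  tex_ladder <- c("normal", "soft", "liquid", "fasting")
  app_ladder <- c("never", "occasionally", "frequently")
  prof <- test_profile(age = 75, weight = 19.5 * 1.7^2, height = 170)
  nrs_tot <- function(w, ir) {
    score_nrs2002(prof, weight_change_response(w[[1]], w[[2]]),
                  intake_reduction_response(ir))$total
  }
  pg_tot <- function(w, ir, tex, app) {
    score_pgsgasf(weight_change_response(w[[1]], w[[2]]),
                  intake_reduction_response(ir),
                  diet_texture_response(tex), appetite_response(app))$total
  }
  for (k in seq_len(length(wc_ladder) - 1)) {
    for (ir in ir_ladder) {
      expect_lte(nrs_tot(wc_ladder[[k]], ir), nrs_tot(wc_ladder[[k + 1]], ir))
      expect_lte(pg_tot(wc_ladder[[k]], ir, "soft", "occasionally"),
                 pg_tot(wc_ladder[[k + 1]], ir, "soft", "occasionally"))
    }
  }
  for (k in seq_len(length(ir_ladder) - 1)) {
    for (w in wc_ladder) {
      expect_lte(nrs_tot(w, ir_ladder[k]), nrs_tot(w, ir_ladder[k + 1]))
      expect_lte(pg_tot(w, ir_ladder[k], "normal", "never"),
                 pg_tot(w, ir_ladder[k + 1], "normal", "never"))
    }
  }
  for (k in seq_len(length(tex_ladder) - 1)) {
    expect_lte(pg_tot(wc_ladder[[2]], "reduction_25_50", tex_ladder[k], "never"),
               pg_tot(wc_ladder[[2]], "reduction_25_50", tex_ladder[k + 1], "never"))
  }
  for (k in seq_len(length(app_ladder) - 1)) {
    expect_lte(pg_tot(wc_ladder[[2]], "unchanged", "normal", app_ladder[k]),
               pg_tot(wc_ladder[[2]], "unchanged", "normal", app_ladder[k + 1]))
  }
})

test_that("scoring is deterministic and configuration round-trips via YAML", {
  p <- test_profile(age = 72)
  args <- list(p, weight_change_response("loss_5_to_15pct", 2),
               intake_reduction_response("reduction_25_50"),
               disease_selection("stroke"))
  expect_identical(do.call(score_nrs2002, args), do.call(score_nrs2002, args))

  cfg <- default_scoring_config()
  tf <- tempfile(fileext = ".yaml")
  write_scoring_config(cfg, tf)
  cfg2 <- read_scoring_config(tf)
  expect_identical(scoring_config_hash(cfg), scoring_config_hash(cfg2))
  s1 <- score_pgsgasf(weight_change_response("loss_5_to_15pct", 1),
                      intake_reduction_response("reduction_50_75"),
                      diet_texture_response("soft"),
                      appetite_response("frequently"), config = cfg2)
  expect_equal(s1$total, 4L + 2L + 3L)
  # a changed cutoff changes the hash and the flag
  cfg3 <- cfg
  cfg3$cutoffs$pgsgasf <- 99L
  expect_false(scoring_config_hash(cfg3) == scoring_config_hash(cfg))
  expect_false(score_pgsgasf(weight_change_response("loss_over_15pct", 1),
                             intake_reduction_response("reduction_75_100"),
                             diet_texture_response("fasting"),
                             appetite_response("frequently"),
                             config = cfg3)$at_risk)
})
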