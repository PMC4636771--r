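test_that("single-smear branch probabilities match closed-form products", {
  p <- means
  dev <- device_profile("spatula", p)
  perf <- test_performance(p)
  flow <- flow_params(p)

  # perfect test: abnormality always reported
  p1 <- perfect_params()
  out <- round_outcome("HSIL", device_profile("spatula", p1),
                       test_performance(p1), flow_params(p1), "guidelines")
  expect_equal(out[["reported_abnormal"]], 1.0)

  # true negative, full adequacy: recall only via lacking endocervical cells
  pf <- mod_params(p, satisfactory = 1)
  out2 <- round_outcome("negative", device_profile("spatula", pf),
                        test_performance(pf), flow_params(pf), "guidelines")
  expect_equal(out2[["recall"]], 0.84 * 0.47, tolerance = 1e-12)
  out3 <- round_outcome("negative", device_profile("spatula", pf),
                        test_performance(pf), flow_params(pf), "typical")
  expect_equal(out3[["recall"]], 0)

  # probabilities over the three outcomes sum to 1 across states/practices
  for (st in c("negative", "ASC-US", "LSIL", "HSIL")) {
    for (pr in c("guidelines", "typical")) {
      o <- round_outcome(st, dev, perf, flow, pr)
      expect_equal(sum(o), 1, tolerance = 1e-12)
      expect_true(all(o >= 0))
    }
  }
  expect_error(round_outcome("AGC", dev, perf, flow, "guidelines"), "unknown")
})

test_that("degenerate limits of the cohort expectation are exact", {
  p1 <- perfect_params()
  for (pr in c("guidelines", "typical")) {
    o <- evaluate_cohort(p1, "spatula", pr)
    expect_equal(o$detected_abnormal_total, o$n_women * 0.73, tolerance = 1e-12)
    expect_equal(o$expected_smears_per_woman, 1, tolerance = 1e-12)
    expect_equal(o$false_positives, 0)
    expect_equal(o$lost_to_care, 0)
  }

  # nobody returns: everyone recalled on round 1 is lost
  p0 <- mod_params(means, lost_to_follow_up = 1)
  dev <- device_profile("spatula", p0)
  o <- evaluate_cohort(p0, dev, "guidelines")
  flow <- flow_params(p0)
  perf <- test_performance(p0)
  mix <- grade_mix(p0)
  w <- c(negative = mix$f_negative, `ASC-US` = mix$f_ascus,
         LSIL = mix$f_lsil, HSIL = mix$f_hsil)
  recall1 <- sum(vapply(names(w), function(s) {
    w[[s]] * round_outcome(s, dev, perf, flow, "guidelines")[["recall"]]
  }, numeric(1)))
  expect_equal(o$lost_to_care, o$n_women * recall1, tolerance = 1e-9)
})

test_that("expected rounds follow the geometric series", {
  expect_equal(expected_rounds(perfect_params(), "spatula", "guidelines"), 1.0)

  # constant per-round recall-and-repeat probability r gives 1/(1-r):
  # typical practice recalls exactly the unsatisfactory fraction
  pr <- mod_params(means, satisfactory = 0.75, lost_to_follow_up = 0,
                   repeat_done = 1)
  expect_equal(expected_rounds(pr, "spatula", "typical", max_rounds = Inf),
               4 / 3, tolerance = 1e-12)

  # spatula under guidelines at the tabled means: about a quarter of women
  # need one repeat
  er <- expected_rounds(means, "spatula", "guidelines")
  expect_gt(er, 1.2)
  expect_lt(er, 1.35)
})

test_that("terminal counts conserve the cohort", {
  for (tr in 0:14) {
    ps <- sample_parameters(default_reg, seed = 42, trial = tr)
    for (prc in c("guidelines", "typical")) {
      for (dv in c("spatula", "broom")) {
        for (mr in c(1, 2, 5, Inf)) {
          o <- evaluate_cohort(ps, dv, prc, max_rounds = mr)
          total <- sum(o$detected_by_grade) + o$false_positives +
            o$true_negative_diagnosed + o$false_negatives_reported +
            o$lost_to_care
          expect_equal(total, o$n_women, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("more endocervical cells never hurt detection under guidelines", {
  # monotonicity holds for true-positive detections; the false-positive
  # count moves the other way (fewer recalls mean fewer re-testing chances
  # for true negatives), so it is excluded here
  grid <- seq(0.3, 0.95, by = 0.05)
  det <- vapply(grid, function(pe) {
    evaluate_cohort(mod_params(means, endocervical_spatula = pe),
                    "spatula", "guidelines",
                    fp_in_detected = FALSE)$detected_abnormal_total
  }, numeric(1))
  rounds <- vapply(grid, function(pe) {
    expected_rounds(mod_params(means, endocervical_spatula = pe),
                    "spatula", "guidelines")
  }, numeric(1))
  expect_true(all(diff(det) >= -1e-9))
  expect_true(all(diff(rounds) <= 1e-9))
})

test_that("guidelines practice detects at least as much as typical practice", {
  for (tr in 0:9) {
    ps <- sample_parameters(default_reg, seed = 3, trial = tr)
    for (dv in c("spatula", "broom")) {
      g <- evaluate_cohort(ps, dv, "guidelines")
      t <- evaluate_cohort(ps, dv, "typical")
      expect_gte(g$detected_abnormal_total, t$detected_abnormal_total)
      expect_gte(g$expected_smears_per_woman, t$expected_smears_per_woman)
    }
  }
})

test_that("devices coincide when adequacy and sensitivity differences vanish", {
  pe <- mod_params(means,
                   endocervical_broom = means[["endocervical_spatula"]],
                   sens_no_endocervical = means[["sens_endocervical"]],
                   sens_no_endocervical_hsil = means[["sens_endocervical"]])
  for (prc in c("guidelines", "typical")) {
    s <- evaluate_cohort(pe, "spatula", prc)
    b <- evaluate_cohort(pe, "broom", prc)
    for (f in c("detected_abnormal_total", "false_positives",
                "false_negatives_reported", "lost_to_care",
                "expected_smears_per_woman")) {
      expect_equal(s[[f]], b[[f]], tolerance = 1e-12)
    }
    cs <- cost_set(pe)
    es <- cost_cohort(s, cs, device_profile("spatula", pe))
    eb <- cost_cohort(b, cs, device_profile("broom", pe))
    expect_equal(eb$cost_per_woman - es$cost_per_woman,
                 (0.22 - 0.02) * s$expected_smears_per_woman,
                 tolerance = 1e-9)
  }
})

test_that("the recall loop cap is respected and absorption matches deep caps", {
  o_inf <- evaluate_cohort(means, "spatula", "guidelines", max_rounds = Inf)
  o_deep <- evaluate_cohort(means, "spatula", "guidelines", max_rounds = 200)
  expect_equal(o_deep$expected_smears_per_woman,
               o_inf$expected_smears_per_woman, tolerance = 1e-10)
  expect_equal(o_deep$lost_to_care, o_inf$lost_to_care, tolerance = 1e-4)

  # a never-absorbing loop is rejected rather than iterated forever
  stuck <- mod_params(means, satisfactory = 0, lost_to_follow_up = 0,
                      repeat_done = 1)
  expect_error(evaluate_cohort(stuck, "spatula", "typical", max_rounds = Inf),
               "converge")
})
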