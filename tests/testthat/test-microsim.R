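test_that("single-woman trajectories follow forced paths", {
  # perfect test, all-HSIL prevalence: one smear, diagnosed
  p1 <- mod_params(perfect_params(), hsil_fraction = 1, lsil_fraction = 0,
                   ascus_fraction = 0, abnormal_fraction = 1)
  rec <- simulate_cohort(p1, "spatula", "guidelines", n_women = 1, seed = 4)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$disposition, "diagnosed")
  expect_equal(rec$reported_result, "abnormal")
  expect_equal(rec$true_grade, "HSIL")

  # a true negative with no endocervical cells and nobody returning:
  # guidelines recall, then lost, in a single record
  p0 <- mod_params(means, hsil_fraction = 0, lsil_fraction = 0,
                   ascus_fraction = 0, endocervical_spatula = 0,
                   specificity = 1, satisfactory = 1, lost_to_follow_up = 1)
  rec0 <- simulate_cohort(p0, "spatula", "guidelines", n_women = 5, seed = 4)
  expect_equal(nrow(rec0), 5)
  expect_true(all(rec0$disposition == "lost"))
  expect_true(all(rec0$reported_result == "normal"))
  expect_true(all(!rec0$endocervical_present))
})

test_that("record streams are reproducible and internally consistent", {
  a <- simulate_cohort(means, "broom", "guidelines", n_women = 4000, seed = 77)
  b <- simulate_cohort(means, "broom", "guidelines", n_women = 4000, seed = 77)
  expect_identical(a, b)
  d <- simulate_cohort(means, "broom", "guidelines", n_women = 4000, seed = 78)
  expect_false(identical(a, d))

  # every round > 1 record is preceded by a recall for the same woman
  later <- a[a$round > 1, ]
  expect_gt(nrow(later), 0)
  recalled <- paste(a$woman_id[a$disposition == "recalled"],
                    a$round[a$disposition == "recalled"])
  expect_true(all(paste(later$woman_id, later$round - 1) %in% recalled))

  # tally_records rejects corrupted streams
  bad <- a
  bad$disposition[bad$disposition == "recalled"][1] <- "lost"
  attr(bad, "n_women") <- attr(a, "n_women")
  expect_error(tally_records(bad), "inconsistent")
})

test_that("tallies of trivial inputs are exact", {
  empty <- simulate_cohort(means, "spatula", "typical", n_women = 1, seed = 1)[0, ]
  attr(empty, "n_women") <- 0
  t0 <- tally_records(empty)
  expect_equal(t0$n_women, 0)
  expect_equal(t0$detected_abnormal_total, 0)

  p1 <- mod_params(perfect_params(), hsil_fraction = 1, lsil_fraction = 0,
                   ascus_fraction = 0, abnormal_fraction = 1)
  one <- tally_records(simulate_cohort(p1, "spatula", "typical", 1, seed = 2))
  expect_equal(one$detected_by_grade[["HSIL"]], 1)
  expect_equal(one$false_positives, 0)
})

test_that("empirical rates invert the generator", {
  n <- 2e5
  rec <- simulate_cohort(means, "broom", "typical", n_women = n, seed = 31)
  est <- estimate_parameters_from_records(rec)
  n_smears <- nrow(rec)
  for (chk in list(c("p_endocervical", 0.83), c("p_satisfactory", 0.98))) {
    se <- sqrt(as.numeric(chk[2]) * (1 - as.numeric(chk[2])) / n_smears)
    expect_lt(abs(est[[chk[1]]] - as.numeric(chk[2])), 4 * se, label = chk[1])
  }
  # degenerate generator: all rates exactly one
  pd <- mod_params(perfect_params(), hsil_fraction = 1, lsil_fraction = 0,
                   ascus_fraction = 0, abnormal_fraction = 1)
  est1 <- estimate_parameters_from_records(
    simulate_cohort(pd, "spatula", "typical", 500, seed = 6))
  expect_equal(est1[["p_endocervical"]], 1)
  expect_equal(est1[["p_satisfactory"]], 1)
  expect_equal(est1[["p_reported_abnormal"]], 1)
})

test_that("an independently hand-coded sampler agrees with the tree engine", {
  n <- 20000
  for (prc in c("guidelines", "typical")) {
    counts <- naive_branch_tally(means, "spatula", prc, n, seed = 101)
    ex <- evaluate_cohort(means, "spatula", prc)
    probs <- c(
      tp_hsil = ex$detected_by_grade[["HSIL"]],
      tp_lsil = ex$detected_by_grade[["LSIL"]],
      tp_ascus = ex$detected_by_grade[["ASC-US"]],
      fp = ex$false_positives,
      tn = ex$true_negative_diagnosed,
      fn = ex$false_negatives_reported,
      lost = ex$lost_to_care
    ) / ex$n_women
    for (nm in names(probs)) {
      expect_within_4se(counts[[nm]], probs[[nm]], n, paste(prc, nm))
    }
    # expected smears per woman as a mean of per-woman counts
    se_smears <- 0.75 / sqrt(n) # generous bound on sd of a 1-2 smear count
    expect_lt(abs(counts[["smears"]] / n - ex$expected_smears_per_woman),
              4 * se_smears)
  }
})

test_that("slide records export to CSV with the documented header", {
  rec <- simulate_cohort(means, "spatula", "typical", n_women = 50, seed = 8)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_slide_records(rec, tf)
  back <- utils::read.csv(tf)
  expect_equal(names(back),
               c("woman_id", "round", "hiv_status", "true_grade",
                 "endocervical_present", "satisfactory", "reported_result",
                 "disposition"))
  expect_equal(nrow(back), nrow(rec))
})
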