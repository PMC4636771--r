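# Independent brute-force sampler: a direct, scalar transcription of the
# screening branch rules, sharing no probability code with the package.
# Used as a double-check of both the tree algebra and the vectorized
# microsimulation on small scenarios.
naive_branch_tally <- function(params, device_name, practice, n, seed,
                               max_rounds = 2) {
  set.seed(seed)
  p_endo <- if (device_name == "spatula") params[["endocervical_spatula"]] else params[["endocervical_broom"]]
  p_sat <- params[["satisfactory"]]
  se <- params[["sens_endocervical"]]
  sn <- params[["sens_no_endocervical"]]
  sh <- params[["sens_no_endocervical_hsil"]]
  sp <- params[["specificity"]]
  p_ret <- 1 - params[["lost_to_follow_up"]]
  p_rep <- params[["repeat_done"]]
  w <- c(params[["hsil_fraction"]], params[["lsil_fraction"]],
         params[["ascus_fraction"]])
  counts <- c(tp_hsil = 0, tp_lsil = 0, tp_ascus = 0, fp = 0, tn = 0,
              fn = 0, lost = 0, smears = 0)
  for (i in seq_len(n)) {
    u <- runif(1)
    grade <- if (u < w[1]) "HSIL" else if (u < w[1] + w[2]) "LSIL" else
      if (u < sum(w)) "ASC-US" else "negative"
    rnd <- 1
    repeat {
      counts[["smears"]] <- counts[["smears"]] + 1
      endo <- runif(1) < p_endo
      sat <- runif(1) < p_sat
      abnormal_seen <- FALSE
      if (sat) {
        pd <- if (grade == "negative") {
          1 - sp
        } else if (endo) {
          se
        } else if (grade == "HSIL") sh else sn
        abnormal_seen <- runif(1) < pd
      }
      if (abnormal_seen) {
        key <- switch(grade, HSIL = "tp_hsil", LSIL = "tp_lsil",
                      `ASC-US` = "tp_ascus", negative = "fp")
        counts[[key]] <- counts[[key]] + 1
        break
      }
      needs_recall <- if (practice == "guidelines") !sat || !endo else !sat
      if (!needs_recall) {
        counts[[if (grade == "negative") "tn" else "fn"]] <-
          counts[[if (grade == "negative") "tn" else "fn"]] + 1
        break
      }
      if (rnd >= max_rounds) {
        counts[["lost"]] <- counts[["lost"]] + 1
        break
      }
      came_back <- runif(1) < p_ret
      got_repeat <- came_back && runif(1) < p_rep
      if (!got_repeat) {
        counts[["lost"]] <- counts[["lost"]] + 1
        break
      }
      rnd <- rnd + 1
    }
  }
  counts
}

# 4-standard-error binomial comparison of an observed count against an
# expected probability.
expect_within_4se <- function(obs, p_expected, n, label) {
  se <- sqrt(n * p_expected * (1 - p_expected))
  expect_lt(abs(obs - n * p_expected), 4 * se + 1e-9,
            label = sprintf("%s: obs %.0f vs expected %.1f (4se = %.1f)",
                            label, obs, n * p_expected, 4 * se))
}
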