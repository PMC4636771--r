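## Monte Carlo probabilistic sensitivity analysis -----------------------------

#' Mean with 95% confidence interval (and percentile interval)
#'
#' Returns the mean with its 95% confidence interval
#' (`mean +/- 1.959964 * sd / sqrt(n)`) and, as an alternate interval, the
#' empirical 2.5th/97.5th percentiles of the values.
#'
#' @param trial_values Numeric vector, length >= 2 (`NA`s dropped).
#' @return Named numeric: `mean`, `ci_low`, `ci_high`, `pct_low`,
#'   `pct_high`, `n`.
#' @examples
#' summarize_mean_ci(rep(c(0, 1), each = 5000))
#' @export
summarize_mean_ci <- function(trial_values) {
  x <- trial_values[!is.na(trial_values)]
  if (length(x) < 2) stop("summarize_mean_ci requires at least 2 values")
  m <- mean(x)
  half <- .z975 * stats::sd(x) / sqrt(length(x))
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = m, ci_low = m - half, ci_high = m + half,
    pct_low = q[1], pct_high = q[2], n = length(x))
}

#' Run the probabilistic sensitivity analysis
#'
#' For each trial, one parameter set is drawn and both devices are evaluated
#' against it (common random numbers: the arms are paired within a trial),
#' costed, and compared. Per-trial draws are retained; metric means are
#' summarized with CI-of-mean and percentile intervals. Trials in which a
#' ratio metric is undefined (no HSIL case detected in an arm) are excluded
#' from the ratio-metric summaries and counted in `n_excluded_ratio`.
#'
#' @param reg A `cea_registry`.
#' @param practice `"guidelines"` or `"typical"`.
#' @param n_trials Number of Monte Carlo trials (default 10,000).
#' @param seed Integer seed; identical `(seed, n_trials)` reproduce the
#'   summary exactly.
#' @param max_rounds Recall-loop cap passed to [evaluate_cohort()].
#' @param fp_in_detected Passed to [evaluate_cohort()].
#' @param verbose Log progress at trial milestones.
#' @return A `psa_summary`: `summary` (data frame: `metric`, `arm`, `mean`,
#'   `ci_low`, `ci_high`, `pct_low`, `pct_high`), `draws` (one row per
#'   trial), `n_trials`, `seed`, `practice`, `n_excluded_ratio`.
#' @export
run_psa <- function(reg, practice = c("guidelines", "typical"),
                    n_trials = 10000, seed = 1, max_rounds = 2,
                    fp_in_detected = TRUE, verbose = FALSE) {
  practice <- match.arg(practice)
  if (n_trials < 1) stop("n_trials must be >= 1")
  cols <- c(paste0("spatula_", .metric_names), paste0("broom_", .metric_names),
            paste0("incr_", .metric_names), "n_women",
            "spatula_smears_per_woman", "broom_smears_per_woman")
  draws <- matrix(NA_real_, nrow = n_trials, ncol = length(cols),
                  dimnames = list(NULL, cols))
  milestones <- unique(round(seq(0.25, 1, by = 0.25) * n_trials))
  for (trial in seq_len(n_trials)) {
    ps <- sample_parameters(reg, seed, trial - 1)
    costs <- cost_set(ps)
    arm <- lapply(c("spatula", "broom"), function(dev) {
      d <- device_profile(dev, ps)
      cost_cohort(evaluate_cohort(ps, d, practice, max_rounds, fp_in_detected),
                  costs, d)
    })
    names(arm) <- c("spatula", "broom")
    ms <- .econ_metrics(arm$spatula)
    mb <- .econ_metrics(arm$broom)
    draws[trial, ] <- c(ms, mb, mb - ms,
                        arm$spatula$outcome$n_women,
                        arm$spatula$outcome$expected_smears_per_woman,
                        arm$broom$outcome$expected_smears_per_woman)
    if (verbose && trial %in% milestones) {
      message(sprintf("PSA (%s): %d/%d trials", practice, trial, n_trials))
    }
  }
  draws <- as.data.frame(draws)
  ratio_cols <- grep("cost_per_hsil_detected", cols, value = TRUE)
  degenerate <- Reduce(`|`, lapply(ratio_cols, function(cl) is.na(draws[[cl]])))
  n_excluded <- sum(degenerate)
  summary <- NULL
  if (n_trials >= 2) {
    summary <- do.call(rbind, lapply(cols, function(cl) {
      vals <- draws[[cl]]
      if (cl %in% ratio_cols) vals <- vals[!degenerate]
      s <- if (sum(!is.na(vals)) >= 2) {
        summarize_mean_ci(vals)
      } else {
        c(mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          pct_low = NA_real_, pct_high = NA_real_, n = sum(!is.na(vals)))
      }
      arm <- sub("_.*", "", cl)
      data.frame(metric = sub("^(spatula|broom|incr)_", "", cl),
                 arm = if (arm %in% c("spatula", "broom", "incr")) arm else "cohort",
                 mean = s[["mean"]], ci_low = s[["ci_low"]], ci_high = s[["ci_high"]],
                 pct_low = s[["pct_low"]], pct_high = s[["pct_high"]],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(summary = summary, draws = draws, n_trials = n_trials,
                 seed = seed, practice = practice, max_rounds = max_rounds,
                 fp_in_detected = fp_in_detected,
                 n_excluded_ratio = n_excluded),
            class = "psa_summary")
}

#' Extract a summarized PSA metric
#'
#' @param psa A `psa_summary`.
#' @param metric One of the metric names (e.g. `"programme_cost"`,
#'   `"hsil_detected"`).
#' @param arm `"spatula"`, `"broom"` or `"incr"`.
#' @return Named numeric row (`mean`, `ci_low`, `ci_high`, `pct_low`,
#'   `pct_high`).
#' @export
psa_metric <- function(psa, metric, arm = c("spatula", "broom", "incr")) {
  arm <- match.arg(arm)
  row <- psa$summary[psa$summary$metric == metric & psa$summary$arm == arm, ]
  if (nrow(row) != 1) stop("no such metric/arm: ", metric, "/", arm)
  unlist(row[, c("mean", "ci_low", "ci_high", "pct_low", "pct_high")])
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA: %d trials, %s practice, seed %d (%d excluded from ratio metrics)\n",
              x$n_trials, x$practice, x$seed, x$n_excluded_ratio))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 6)
  invisible(x)
}
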