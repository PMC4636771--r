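## Screening tree: per-round branch probabilities and cohort expectations ----

.grades <- c("negative", "ASC-US", "LSIL", "HSIL")

#' Collection-device profile
#'
#' @param name `"spatula"` or `"broom"`.
#' @param params A `cea_params` realization (see [sample_parameters()],
#'   [param_means()]).
#' @return A list with `name`, `unit_cost` (USD) and `p_endocervical`, the
#'   probability that a smear taken with this device contains endocervical
#'   cells.
#' @export
device_profile <- function(name = c("spatula", "broom"), params) {
  name <- match.arg(name)
  if (name == "spatula") {
    list(name = "spatula",
         unit_cost = unname(params[["cost_spatula"]]),
         p_endocervical = unname(params[["endocervical_spatula"]]))
  } else {
    list(name = "broom",
         unit_cost = unname(params[["cost_broom"]]),
         p_endocervical = unname(params[["endocervical_broom"]]))
  }
}

#' Cytology test performance
#' @param params A `cea_params` realization.
#' @return List with `sens_endo`, `sens_no_endo`, `sens_no_endo_hsil`,
#'   `specificity`.
#' @export
test_performance <- function(params) {
  list(sens_endo = unname(params[["sens_endocervical"]]),
       sens_no_endo = unname(params[["sens_no_endocervical"]]),
       sens_no_endo_hsil = unname(params[["sens_no_endocervical_hsil"]]),
       specificity = unname(params[["specificity"]]))
}

#' Patient-flow probabilities
#' @param params A `cea_params` realization.
#' @param max_rounds Maximum number of smears per woman (`Inf` for an
#'   uncapped recall loop). Default 2: the initial smear plus at most one
#'   repeat.
#' @return List with `p_satisfactory`, `p_return` (1 - lost to follow-up),
#'   `p_repeat_given_return`, `max_rounds`.
#' @export
flow_params <- function(params, max_rounds = 2) {
  if (!(is.infinite(max_rounds) || (max_rounds >= 1 && max_rounds == floor(max_rounds)))) {
    stop("max_rounds must be a positive integer or Inf")
  }
  list(p_satisfactory = unname(params[["satisfactory"]]),
       p_return = 1 - unname(params[["lost_to_follow_up"]]),
       p_repeat_given_return = unname(params[["repeat_done"]]),
       max_rounds = max_rounds)
}

#' Grade mix of true cytological status
#' @param params A `cea_params` realization.
#' @return List with per-grade fractions of all women and the implied
#'   negative fraction. The sampled grade fractions define the mix directly;
#'   `p_abnormal` is their sum.
#' @export
grade_mix <- function(params) {
  h <- unname(params[["hsil_fraction"]])
  l <- unname(params[["lsil_fraction"]])
  a <- unname(params[["ascus_fraction"]])
  neg <- 1 - (h + l + a)
  if (neg < 0) stop("grade fractions exceed 1")
  list(f_hsil = h, f_lsil = l, f_ascus = a, p_abnormal = h + l + a,
       f_negative = neg)
}

#' Single-smear outcome probabilities
#'
#' One round of the screening tree for a woman of a given true status.
#' An unsatisfactory smear (probability `1 - p_satisfactory`) cannot be
#' evaluated and triggers a recall under both practice models. A
#' satisfactory smear is read: true abnormalities are reported with
#' `sens_endo` when endocervical cells are present and with `sens_no_endo`
#' (or `sens_no_endo_hsil` for HSIL) when absent — detected abnormalities
#' are always reported, adequate slide or not; true negatives are reported
#' abnormal with `1 - specificity`. A smear read as negative is final under
#' typical practice, while guidelines practice recalls it when it lacks
#' endocervical cells.
#'
#' @param true_state One of `"negative"`, `"ASC-US"`, `"LSIL"`, `"HSIL"`.
#' @param device A [device_profile()].
#' @param perf A [test_performance()].
#' @param flow A [flow_params()].
#' @param practice `"guidelines"` or `"typical"`.
#' @return Named numeric vector `c(reported_abnormal, final_negative,
#'   recall)`; the three probabilities sum to 1.
#' @examples
#' reg <- load_parameters(); p <- param_means(reg)
#' round_outcome("negative", device_profile("spatula", p),
#'               test_performance(p), flow_params(p), "guidelines")
#' @export
round_outcome <- function(true_state, device, perf, flow,
                          practice = c("guidelines", "typical")) {
  practice <- match.arg(practice)
  if (!true_state %in% .grades) stop("unknown true state: ", true_state)
  p_e <- device$p_endocervical
  p_s <- flow$p_satisfactory
  if (true_state == "negative") {
    det_e <- det_ne <- 1 - perf$specificity
  } else if (true_state == "HSIL") {
    det_e <- perf$sens_endo
    det_ne <- perf$sens_no_endo_hsil
  } else {
    det_e <- perf$sens_endo
    det_ne <- perf$sens_no_endo
  }
  reported <- p_s * (p_e * det_e + (1 - p_e) * det_ne)
  miss_endo <- p_s * p_e * (1 - det_e)
  miss_no_endo <- p_s * (1 - p_e) * (1 - det_ne)
  unsat <- 1 - p_s
  recall <- if (practice == "guidelines") unsat + miss_no_endo else unsat
  final_neg <- 1 - reported - recall
  c(reported_abnormal = reported, final_negative = final_neg, recall = recall)
}

# Absorption of the recall loop for one true state. Each recalled woman
# re-enters with probability c = p_return * p_repeat (one fresh smear, all
# draws independent of earlier rounds) and is otherwise lost to care. With a
# finite cap K, a woman whose K-th smear still triggers a recall has no
# diagnosis and is lost to care.
.absorb <- function(out, flow) {
  a <- out[["reported_abnormal"]]
  f <- out[["final_negative"]]
  r <- out[["recall"]]
  cc <- flow$p_return * flow$p_repeat_given_return
  q <- r * cc
  K <- flow$max_rounds
  if (is.infinite(K)) {
    if (q >= 1) stop("recall loop does not converge (recall * continuation = 1)")
    S <- 1 / (1 - q)
    list(p_reported = a * S, p_final_negative = f * S,
         p_lost = r * (1 - cc) * S, e_smears = S)
  } else {
    if (q == 1) {
      S <- K
      S1 <- K - 1
    } else {
      S <- (1 - q^K) / (1 - q)          # sum_{j=0}^{K-1} q^j
      S1 <- (1 - q^(K - 1)) / (1 - q)   # sum_{j=0}^{K-2} q^j
    }
    list(p_reported = a * S, p_final_negative = f * S,
         p_lost = r * (1 - cc) * S1 + r * q^(K - 1), e_smears = S)
  }
}

#' Expected cohort outcome under one device and practice model
#'
#' Propagates the annual HIV-infected screening cohort (`women_tested_annual
#' * hiv_positive_fraction`) through the screening tree, iterating the
#' recall/repeat loop to `max_rounds` (or to absorption when `Inf`). Repeat
#' smears draw endocervical presence and satisfactoriness independently of
#' earlier rounds. Expected counts are real-valued; rounding happens only at
#' report rendering.
#'
#' @param params A `cea_params` realization.
#' @param device A [device_profile()] or a device name.
#' @param practice `"guidelines"` or `"typical"`.
#' @param max_rounds Maximum smears per woman; default 2, `Inf` for
#'   absorption.
#' @param fp_in_detected Count false positives in `detected_abnormal_total`
#'   (default `TRUE`, matching laboratory reporting of abnormal smears).
#' @return A `cohort_outcome` list: `n_women`, `detected_by_grade` (HSIL,
#'   LSIL, ASC-US true positives), `detected_abnormal_total`,
#'   `false_positives`, `true_negative_diagnosed`,
#'   `false_negatives_reported`, `lost_to_care`,
#'   `expected_smears_per_woman`, `expected_visits_per_woman`.
#' @export
evaluate_cohort <- function(params, device, practice = c("guidelines", "typical"),
                            max_rounds = 2, fp_in_detected = TRUE) {
  practice <- match.arg(practice)
  if (is.character(device)) device <- device_profile(device, params)
  perf <- test_performance(params)
  flow <- flow_params(params, max_rounds)
  mix <- grade_mix(params)
  n_women <- unname(params[["women_tested_annual"]] * params[["hiv_positive_fraction"]])

  w <- c(negative = mix$f_negative, `ASC-US` = mix$f_ascus,
         LSIL = mix$f_lsil, HSIL = mix$f_hsil)
  abs_by_state <- lapply(names(w), function(s) {
    .absorb(round_outcome(s, device, perf, flow, practice), flow)
  })
  names(abs_by_state) <- names(w)

  # terminal probabilities must sum to 1 per state before scaling
  for (s in names(w)) {
    tot <- abs_by_state[[s]]$p_reported + abs_by_state[[s]]$p_final_negative +
      abs_by_state[[s]]$p_lost
    if (abs(tot - 1) > 1e-9) {
      stop("terminal probabilities for state ", s, " sum to ", tot)
    }
  }

  tp <- vapply(c("HSIL", "LSIL", "ASC-US"),
               function(s) n_women * w[[s]] * abs_by_state[[s]]$p_reported,
               numeric(1))
  fp <- n_women * w[["negative"]] * abs_by_state[["negative"]]$p_reported
  tn <- n_women * w[["negative"]] * abs_by_state[["negative"]]$p_final_negative
  fn <- sum(vapply(c("HSIL", "LSIL", "ASC-US"),
                   function(s) n_women * w[[s]] * abs_by_state[[s]]$p_final_negative,
                   numeric(1)))
  lost <- sum(vapply(names(w),
                     function(s) n_women * w[[s]] * abs_by_state[[s]]$p_lost,
                     numeric(1)))
  smears <- sum(vapply(names(w),
                       function(s) w[[s]] * abs_by_state[[s]]$e_smears,
                       numeric(1)))

  structure(list(
    n_women = n_women,
    detected_by_grade = tp,
    detected_abnormal_total = sum(tp) + if (fp_in_detected) fp else 0,
    false_positives = fp,
    true_negative_diagnosed = tn,
    false_negatives_reported = fn,
    lost_to_care = lost,
    expected_smears_per_woman = smears,
    expected_visits_per_woman = smears,
    device = device$name,
    practice = practice,
    max_rounds = max_rounds,
    fp_in_detected = fp_in_detected
  ), class = "cohort_outcome")
}

#' Expected number of smears per woman entering the programme
#'
#' Always >= 1; equals the geometric-series closed form `1 / (1 - r c)` of
#' the per-round recall-and-repeat probability when `max_rounds` is
#' unbounded.
#'
#' @inheritParams evaluate_cohort
#' @return Expected smears per woman.
#' @export
expected_rounds <- function(params, device, practice = c("guidelines", "typical"),
                            max_rounds = 2) {
  evaluate_cohort(params, device, practice,
                  max_rounds = max_rounds)$expected_smears_per_woman
}

#' Human-readable dump of the tree branches
#'
#' Audit aid: per true state, the single-smear branch probabilities and the
#' absorbed terminal-state probabilities.
#'
#' @inheritParams evaluate_cohort
#' @return A data frame with one row per (state, quantity).
#' @export
tree_outline <- function(params, device, practice = c("guidelines", "typical"),
                         max_rounds = 2) {
  practice <- match.arg(practice)
  if (is.character(device)) device <- device_profile(device, params)
  perf <- test_performance(params)
  flow <- flow_params(params, max_rounds)
  rows <- lapply(.grades, function(s) {
    out <- round_outcome(s, device, perf, flow, practice)
    ab <- .absorb(out, flow)
    data.frame(state = s,
               reported_abnormal = out[["reported_abnormal"]],
               final_negative = out[["final_negative"]],
               recall = out[["recall"]],
               p_reported = ab$p_reported,
               p_final_negative = ab$p_final_negative,
               p_lost = ab$p_lost,
               e_smears = ab$e_smears)
  })
  do.call(rbind, rows)
}

#' @export
print.cohort_outcome <- function(x, ...) {
  cat(sprintf("Cohort outcome (%s, %s practice, max_rounds=%s)\n",
              x$device, x$practice, format(x$max_rounds)))
  cat(sprintf("  women screened:        %12.0f\n", x$n_women))
  cat(sprintf("  abnormal detected:     %12.0f (HSIL %0.0f, LSIL %0.0f, ASC-US %0.0f; FP %0.0f)\n",
              x$detected_abnormal_total, x$detected_by_grade[["HSIL"]],
              x$detected_by_grade[["LSIL"]], x$detected_by_grade[["ASC-US"]],
              x$false_positives))
  cat(sprintf("  false negatives:       %12.0f\n", x$false_negatives_reported))
  cat(sprintf("  true negatives:        %12.0f\n", x$true_negative_diagnosed))
  cat(sprintf("  lost to care:          %12.0f\n", x$lost_to_care))
  cat(sprintf("  smears per woman:      %12.4f\n", x$expected_smears_per_woman))
  invisible(x)
}
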