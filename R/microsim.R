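## Individual-level microsimulation: synthetic records and brute-force oracle -

#' Simulate an individual-level screening cohort
#'
#' Draws women one at a time through the same branch probabilities as the
#' cohort-expectation engine ([round_outcome()] semantics): true grade from
#' the grade mix, then per round endocervical presence, satisfactoriness,
#' the reported result, and — on recall — return and repeat events. Because
#' the branch probabilities are shared with the tree engine, tallies of these
#' records validate the expectation algebra (recursion/absorption), not the
#' branch probabilities themselves.
#'
#' @param params A `cea_params` realization.
#' @param device A [device_profile()] or device name.
#' @param practice `"guidelines"` or `"typical"`.
#' @param n_women Number of women to simulate.
#' @param seed Integer seed; identical seeds reproduce identical record
#'   streams.
#' @param max_rounds Maximum smears per woman (`Inf` iterates to exhaustion,
#'   with a hard cap of 10,000 rounds).
#' @return A `slide_records` data frame, one row per smear: `woman_id`,
#'   `round`, `hiv_status`, `true_grade`, `endocervical_present`,
#'   `satisfactory`, `reported_result` (`normal`/`abnormal`), `disposition`
#'   (`diagnosed`, `final_negative`, `recalled`, `lost`). Attribute
#'   `n_women` records the cohort size.
#' @export
simulate_cohort <- function(params, device, practice = c("guidelines", "typical"),
                            n_women, seed, max_rounds = 2) {
  practice <- match.arg(practice)
  if (n_women < 1) stop("n_women must be >= 1")
  if (is.character(device)) device <- device_profile(device, params)
  perf <- test_performance(params)
  flow <- flow_params(params, max_rounds)
  mix <- grade_mix(params)

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(seed, 0))

  cuts <- cumsum(c(mix$f_negative, mix$f_ascus, mix$f_lsil, mix$f_hsil))
  grade <- .grades[findInterval(stats::runif(n_women), c(0, cuts),
                                rightmost.closed = TRUE)]
  sens_ne <- ifelse(grade == "HSIL", perf$sens_no_endo_hsil,
                    ifelse(grade == "negative", 1 - perf$specificity,
                           perf$sens_no_endo))
  sens_e <- ifelse(grade == "negative", 1 - perf$specificity, perf$sens_endo)

  hard_cap <- if (is.infinite(max_rounds)) 10000L else as.integer(max_rounds)
  active <- seq_len(n_women)
  round_i <- 1L
  recs <- vector("list", 16L)
  n_chunks <- 0L
  while (length(active) > 0) {
    if (round_i > hard_cap && is.infinite(max_rounds)) {
      stop("recall loop did not absorb within 10,000 rounds")
    }
    n_a <- length(active)
    endo <- stats::runif(n_a) < device$p_endocervical
    sat <- stats::runif(n_a) < flow$p_satisfactory
    p_det <- ifelse(endo, sens_e[active], sens_ne[active])
    reported <- sat & (stats::runif(n_a) < p_det)
    recall <- if (practice == "guidelines") {
      !sat | (!reported & sat & !endo)
    } else {
      !sat
    }
    recall <- recall & !reported
    final_neg <- !reported & !recall

    last_round <- round_i >= hard_cap
    cont <- rep(FALSE, n_a)
    if (!last_round && any(recall)) {
      n_r <- sum(recall)
      returns <- stats::runif(n_r) < flow$p_return
      repeats <- stats::runif(n_r) < flow$p_repeat_given_return
      cont[recall] <- returns & repeats
    }
    disposition <- ifelse(reported, "diagnosed",
                          ifelse(final_neg, "final_negative",
                                 ifelse(cont, "recalled", "lost")))
    n_chunks <- n_chunks + 1L
    if (n_chunks > length(recs)) recs <- c(recs, vector("list", length(recs)))
    recs[[n_chunks]] <- data.frame(
      woman_id = active,
      round = round_i,
      hiv_status = "positive",
      true_grade = grade[active],
      endocervical_present = endo,
      satisfactory = sat,
      reported_result = ifelse(reported, "abnormal", "normal"),
      disposition = disposition,
      stringsAsFactors = FALSE
    )
    active <- active[recall & cont]
    round_i <- round_i + 1L
  }
  out <- do.call(rbind, recs[seq_len(n_chunks)])
  out <- out[order(out$woman_id, out$round), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_women") <- n_women
  class(out) <- c("slide_records", "data.frame")
  out
}

#' Tally synthetic slide records into a cohort outcome
#'
#' Counts per-woman terminal dispositions into the same shape the tree
#' engine emits, so microsimulation tallies and [evaluate_cohort()]
#' expectations are directly comparable.
#'
#' @param records A `slide_records` data frame from one [simulate_cohort()]
#'   call.
#' @param fp_in_detected Count false positives in `detected_abnormal_total`.
#' @return A `cohort_outcome` with observed counts.
#' @export
tally_records <- function(records, fp_in_detected = TRUE) {
  n_women <- attr(records, "n_women")
  if (is.null(n_women)) n_women <- length(unique(records$woman_id))
  if (nrow(records) == 0) {
    return(structure(list(
      n_women = 0, detected_by_grade = c(HSIL = 0, LSIL = 0, `ASC-US` = 0),
      detected_abnormal_total = 0, false_positives = 0,
      true_negative_diagnosed = 0, false_negatives_reported = 0,
      lost_to_care = 0, expected_smears_per_woman = NaN,
      expected_visits_per_woman = NaN, device = NA_character_,
      practice = NA_character_, max_rounds = NA, fp_in_detected = fp_in_detected
    ), class = "cohort_outcome"))
  }
  later <- records[records$round > 1, c("woman_id", "round")]
  if (nrow(later) > 0) {
    recalled_keys <- paste(records$woman_id[records$disposition == "recalled"],
                           records$round[records$disposition == "recalled"])
    need <- paste(later$woman_id, later$round - 1)
    if (!all(need %in% recalled_keys)) {
      stop("inconsistent record stream: round > 1 without a prior recall")
    }
  }
  final <- records[records$disposition != "recalled", , drop = FALSE]
  if (anyDuplicated(final$woman_id)) {
    stop("inconsistent record stream: multiple terminal records per woman")
  }
  abn <- final$true_grade != "negative"
  diag <- final$disposition == "diagnosed"
  fneg <- final$disposition == "final_negative"
  tp <- vapply(c("HSIL", "LSIL", "ASC-US"),
               function(g) sum(diag & final$true_grade == g), numeric(1))
  fp <- sum(diag & !abn)
  structure(list(
    n_women = n_women,
    detected_by_grade = tp,
    detected_abnormal_total = sum(tp) + if (fp_in_detected) fp else 0,
    false_positives = fp,
    true_negative_diagnosed = sum(fneg & !abn),
    false_negatives_reported = sum(fneg & abn),
    lost_to_care = sum(final$disposition == "lost"),
    expected_smears_per_woman = nrow(records) / n_women,
    expected_visits_per_woman = nrow(records) / n_women,
    device = NA_character_, practice = NA_character_, max_rounds = NA,
    fp_in_detected = fp_in_detected
  ), class = "cohort_outcome")
}

#' Empirical rates from synthetic slide records
#'
#' Inverts the generator for the proportions it draws directly; used in
#' parameter-recovery tests.
#'
#' @param records A `slide_records` data frame.
#' @return Named numeric: `p_endocervical`, `p_satisfactory`,
#'   `p_reported_abnormal` (per smear), and `p_continue_after_recall` (the
#'   fraction of non-final recalls that led to a repeat smear, `NaN` when no
#'   smear was recalled).
#' @export
estimate_parameters_from_records <- function(records) {
  recalled <- records$disposition %in% c("recalled", "lost") &
    records$reported_result == "normal"
  # among recalls eligible for continuation (i.e. excluding horizon-capped
  # rounds there is no marker; use observed continuations / all recalls
  # below the max observed round)
  cont <- sum(records$disposition == "recalled")
  n_recall <- sum(recalled)
  c(p_endocervical = mean(records$endocervical_present),
    p_satisfactory = mean(records$satisfactory),
    p_reported_abnormal = mean(records$reported_result == "abnormal"),
    p_continue_after_recall = if (n_recall > 0) cont / n_recall else NaN)
}

#' Write slide records to CSV
#'
#' The package's synthetic stand-in for national laboratory registry
#' extracts: one row per smear with the documented header
#' `woman_id,round,hiv_status,true_grade,endocervical_present,satisfactory,reported_result,disposition`.
#'
#' @param records A `slide_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_slide_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
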