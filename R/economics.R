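## Programme costs and incremental comparisons --------------------------------

#' Unit-cost set
#' @param params A `cea_params` realization.
#' @return List with `visit` (USD per outpatient visit) and `lab` (USD per
#'   cytology test, excluding the collection device).
#' @export
cost_set <- function(params) {
  list(visit = unname(params[["cost_visit"]]),
       lab = unname(params[["cost_lab"]]))
}

#' Cost a cohort outcome
#'
#' Every smear taken (first or repeat) incurs one outpatient visit, one
#' laboratory test and one collection device; no other costs accrue. Women
#' lost before a repeat smear incur no partial visit cost.
#'
#' @param outcome A [evaluate_cohort()] result.
#' @param costs A [cost_set()].
#' @param device A [device_profile()] (supplies the per-device unit cost).
#' @return An `econ_result` list: `programme_cost` (USD/year),
#'   `cost_per_woman`, `cost_per_hsil_detected` (`NA` when no HSIL case is
#'   detected), and the originating `outcome`.
#' @export
cost_cohort <- function(outcome, costs, device) {
  per_smear <- costs$visit + costs$lab + device$unit_cost
  programme <- outcome$n_women * outcome$expected_smears_per_woman * per_smear
  hsil <- outcome$detected_by_grade[["HSIL"]]
  structure(list(
    programme_cost = programme,
    cost_per_woman = programme / outcome$n_women,
    cost_per_hsil_detected = if (hsil > 0) programme / hsil else NA_real_,
    cost_per_smear = per_smear,
    outcome = outcome
  ), class = "econ_result")
}

.metric_names <- c("programme_cost", "cost_per_woman", "cost_per_hsil_detected",
                   "abnormal_detected", "hsil_detected", "false_negatives",
                   "lost_to_care")

.econ_metrics <- function(res) {
  o <- res$outcome
  c(programme_cost = res$programme_cost,
    cost_per_woman = res$cost_per_woman,
    cost_per_hsil_detected = res$cost_per_hsil_detected,
    abnormal_detected = o$detected_abnormal_total,
    hsil_detected = o$detected_by_grade[["HSIL"]],
    false_negatives = o$false_negatives_reported,
    lost_to_care = o$lost_to_care)
}

#' Incremental comparison of two costed cohorts
#'
#' Differences (`alt - base`) and percent changes for the programme-cost and
#' outcome metrics, with a dominance classification: the alternative is
#' `dominant` when it both costs less and detects more HSIL cases;
#' `dominated` in the opposite case; otherwise `trade-off`. The
#' per-HSIL-cost increment is the difference of the two cost-per-HSIL
#' ratios; an incremental cost-effectiveness ratio (ICER,
#' delta cost / delta HSIL) is reported alongside, labelled as such.
#'
#' @param base,alt `econ_result` objects computed from the same practice
#'   model and parameter set.
#' @return An `incremental_result`: data frame `table` with columns `metric`,
#'   `base`, `alt`, `difference`, `pct_change`, plus `classification` and
#'   `icer_cost_per_hsil`.
#' @export
incremental <- function(base, alt) {
  if (!identical(base$outcome$practice, alt$outcome$practice)) {
    stop("incremental comparison across different practice models")
  }
  b <- .econ_metrics(base)
  a <- .econ_metrics(alt)
  diff <- a - b
  pct <- ifelse(b != 0, diff / b, NA_real_)
  d_cost <- diff[["programme_cost"]]
  d_hsil <- diff[["hsil_detected"]]
  classification <- if (d_cost < 0 && d_hsil > 0) {
    "dominant"
  } else if (d_cost > 0 && d_hsil < 0) {
    "dominated"
  } else {
    "trade-off"
  }
  structure(list(
    table = data.frame(metric = .metric_names, base = unname(b), alt = unname(a),
                       difference = unname(diff), pct_change = unname(pct),
                       stringsAsFactors = FALSE),
    classification = classification,
    icer_cost_per_hsil = if (d_hsil != 0) d_cost / d_hsil else NA_real_,
    practice = base$outcome$practice
  ), class = "incremental_result")
}

#' @export
print.econ_result <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("Economics (%s, %s practice)\n", o$device, o$practice))
  cat(sprintf("  annual programme cost:  $%14.2f\n", x$programme_cost))
  cat(sprintf("  cost per woman:         $%14.2f\n", x$cost_per_woman))
  cat(sprintf("  cost per HSIL detected: $%14.2f\n", x$cost_per_hsil_detected))
  invisible(x)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result (%s practice): %s\n", x$practice,
              x$classification))
  print(x$table, row.names = FALSE)
  cat(sprintf("ICER (delta cost / delta HSIL): %s\n",
              format(x$icer_cost_per_hsil)))
  invisible(x)
}
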