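## Reporting: analysis driver, rendered tables, manifest ----------------------

#' Analysis run configuration
#'
#' @param practice `"guidelines"`, `"typical"` or `"both"`.
#' @param devices Devices to evaluate (both by default; the incremental
#'   columns require both).
#' @param n_trials Monte Carlo trials per practice model (default 10,000).
#' @param seed Integer seed.
#' @param max_rounds Recall-loop cap (default 2; `Inf` for absorption).
#' @param interval_mode `"ci_of_mean"` (default) or `"percentile"` interval
#'   rendering.
#' @param fp_in_detected Count false positives among detected abnormal
#'   smears.
#' @param output_dir Directory for rendered outputs.
#' @param params_file Parameter configuration path (packaged default when
#'   `NULL`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(practice = "both", devices = c("spatula", "broom"),
                       n_trials = 10000, seed = 1, max_rounds = 2,
                       interval_mode = c("ci_of_mean", "percentile"),
                       fp_in_detected = TRUE, output_dir = tempfile("cytocea-"),
                       params_file = NULL) {
  interval_mode <- match.arg(interval_mode)
  if (!practice %in% c("guidelines", "typical", "both")) {
    stop("practice must be one of guidelines/typical/both")
  }
  if (length(devices) == 0 || !all(devices %in% c("spatula", "broom"))) {
    stop("devices must be a non-empty subset of {spatula, broom}")
  }
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(practice = practice, devices = devices,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 max_rounds = max_rounds, interval_mode = interval_mode,
                 fp_in_detected = fp_in_detected, output_dir = output_dir,
                 params_file = params_file),
            class = "run_config")
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  fields <- config[c("practice", "devices", "n_trials", "seed", "max_rounds",
                     "interval_mode", "fp_in_detected")]
  fields$max_rounds <- format(fields$max_rounds)
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE), tf)
  unname(tools::md5sum(tf))
}

.summary_table <- function(psa, interval_mode) {
  lo_col <- if (interval_mode == "ci_of_mean") "ci_low" else "pct_low"
  hi_col <- if (interval_mode == "ci_of_mean") "ci_high" else "pct_high"
  rows <- lapply(.metric_names, function(m) {
    sp <- psa_metric(psa, m, "spatula")
    br <- psa_metric(psa, m, "broom")
    inc <- psa_metric(psa, m, "incr")
    data.frame(metric = m, spatula = sp[["mean"]], broom = br[["mean"]],
               incremental = inc[["mean"]],
               pct_change = if (sp[["mean"]] != 0) inc[["mean"]] / sp[["mean"]] else NA_real_,
               ci_low = inc[[lo_col]], ci_high = inc[[hi_col]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.render_summary_text <- function(tbl, practice) {
  is_cost <- grepl("cost", tbl$metric)
  fmt_val <- function(v, cost) {
    ifelse(cost, sprintf("$ %.2f", v), sprintf("%.0f", round(v)))
  }
  lines <- c(sprintf("Model results: %s practice", practice),
             sprintf("%-28s %14s %14s %14s %6s %26s", "Metric", "Spatula",
                     "Broom", "Incremental", "%", "95% CI"))
  for (i in seq_len(nrow(tbl))) {
    lines <- c(lines, sprintf(
      "%-28s %14s %14s %14s %5.0f%% %12s to %12s",
      tbl$metric[i],
      fmt_val(tbl$spatula[i], is_cost[i]), fmt_val(tbl$broom[i], is_cost[i]),
      fmt_val(tbl$incremental[i], is_cost[i]), 100 * tbl$pct_change[i],
      fmt_val(tbl$ci_low[i], is_cost[i]), fmt_val(tbl$ci_high[i], is_cost[i])))
  }
  lines
}

#' Run the full analysis and write a report bundle
#'
#' Runs the PSA for the configured practice model(s), producing per practice
#' a summary table shaped like the published results table (annual programme
#' cost, cost per woman screened, cost per HSIL case detected, abnormal and
#' HSIL smears detected, false negatives, lost to care; spatula, broom and
#' incremental columns), a per-trial CSV, a rendered text table, and a run
#' manifest (seed, configuration hash, package version) from which the run
#' can be re-executed exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-practice `psa_summary` objects,
#'   summary tables, and the manifest; files are written under
#'   `config$output_dir`.
#' @export
run_analysis <- function(config = run_config()) {
  reg <- load_parameters(config$params_file)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir)) {
    stop("unwritable output path: ", config$output_dir)
  }
  practices <- if (config$practice == "both") c("guidelines", "typical") else config$practice
  if (config$n_trials == 1) {
    warning("n_trials = 1: confidence intervals are undefined and left empty")
  }
  results <- list()
  tables <- list()
  for (pr in practices) {
    psa <- run_psa(reg, pr, n_trials = config$n_trials, seed = config$seed,
                   max_rounds = config$max_rounds,
                   fp_in_detected = config$fp_in_detected, verbose = TRUE)
    results[[pr]] <- psa
    utils::write.csv(psa$draws,
                     file.path(config$output_dir, paste0("trials_", pr, ".csv")),
                     row.names = FALSE)
    if (!is.null(psa$summary)) {
      tbl <- .summary_table(psa, config$interval_mode)
    } else {
      one <- psa$draws
      tbl <- data.frame(metric = .metric_names,
                        spatula = unlist(one[1, paste0("spatula_", .metric_names)]),
                        broom = unlist(one[1, paste0("broom_", .metric_names)]),
                        incremental = unlist(one[1, paste0("incr_", .metric_names)]),
                        pct_change = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE)
      rownames(tbl) <- NULL
    }
    tables[[pr]] <- tbl
    writeLines(.render_summary_text(tbl, pr),
               file.path(config$output_dir, paste0("summary_", pr, ".txt")))
  }
  manifest <- list(
    package = "cytocea",
    version = as.character(utils::packageVersion("cytocea")),
    seed = config$seed, n_trials = config$n_trials,
    practice = config$practice, devices = config$devices,
    max_rounds = format(config$max_rounds),
    interval_mode = config$interval_mode,
    fp_in_detected = config$fp_in_detected,
    params_file = if (is.null(config$params_file)) "packaged default" else config$params_file,
    config_hash = .config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(lapply(tables, function(t) t),
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(psa = results, tables = tables, manifest = manifest,
                 output_dir = config$output_dir))
}

#' Rebuild a run configuration from a manifest
#'
#' A run can be re-executed exactly from its manifest alone (the manifest
#' carries seed, trial count, loop depth and interval mode).
#'
#' @param path Path to a `manifest.json` written by [run_analysis()].
#' @param output_dir Output directory for the re-run.
#' @return A [run_config()].
#' @export
config_from_manifest <- function(path, output_dir = tempfile("cytocea-")) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(practice = m$practice, devices = m$devices,
             n_trials = m$n_trials, seed = m$seed,
             max_rounds = if (m$max_rounds %in% c("Inf", "inf")) Inf else as.numeric(m$max_rounds),
             interval_mode = m$interval_mode, fp_in_detected = m$fp_in_detected,
             output_dir = output_dir,
             params_file = if (identical(m$params_file, "packaged default")) NULL else m$params_file)
}

#' Render the parameter registry as a readable table
#'
#' @param reg A `cea_registry` (possibly empty).
#' @return Character vector of table lines (header plus one row per
#'   parameter: mean, bounds, distribution, source).
#' @export
render_parameter_table <- function(reg) {
  lines <- sprintf("%-28s %12s %12s %12s %-12s %-10s",
                   "Parameter", "Mean", "Low95", "High95", "Distribution",
                   "Source")
  for (i in seq_len(nrow(reg))) {
    p <- reg[i, ]
    lines <- c(lines, sprintf(
      "%-28s %12.6g %12s %12s %-12s %-10s", p$name, p$mean,
      if (is.na(p$low95)) "" else sprintf("%.6g", p$low95),
      if (is.na(p$high95)) "" else sprintf("%.6g", p$high95),
      p$distribution, p$source))
  }
  lines
}
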