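#' @keywords internal
"_PACKAGE"

## Parameter registry ---------------------------------------------------------

# Every quantity the model consumes, with its distribution family and 95%
# interval bounds. Proportions are fractions in [0,1]; costs are 2014 USD.
.required_parameters <- c(
  "women_tested_annual", "or_endocervical_broom", "or_detection_endocervical",
  "or_detection_severe", "hiv_positive_fraction", "hiv_women_tested_annual",
  "abnormal_fraction", "hsil_fraction", "lsil_fraction", "ascus_fraction",
  "endocervical_spatula", "endocervical_broom", "sens_endocervical",
  "sens_no_endocervical", "sens_no_endocervical_hsil", "repeat_done",
  "satisfactory", "specificity", "lost_to_follow_up",
  "usd_zar_rate", "cost_spatula", "cost_broom", "cost_visit", "cost_lab"
)

.z975 <- stats::qnorm(0.975)  # 1.959964
.z95 <- stats::qnorm(0.95)    # 1.644854

#' Path to the packaged default parameter configuration
#'
#' @return Path to the YAML file holding the default parameter registry
#'   (screening volumes, device effects, test performance, flow
#'   probabilities, unit costs).
#' @export
default_parameter_file <- function() {
  system.file("extdata", "parameters.yaml", package = "cytocea", mustWork = TRUE)
}

#' Load the model parameter registry
#'
#' Reads a structured YAML (or JSON) configuration with one entry per
#' parameter: `name`, `distribution` (`normal`, `proportion` or `point`),
#' `mean`, optional `low95`/`high95` bounds, `units` and `source`. The
#' packaged default reproduces the published input tables value for value.
#'
#' @param path Path to a configuration file; the packaged default when `NULL`.
#' @return A `cea_registry`: a data frame with one row per parameter and
#'   columns `name`, `distribution`, `mean`, `low95`, `high95`, `units`,
#'   `source`.
#' @examples
#' reg <- load_parameters()
#' reg[reg$name == "or_endocervical_broom", c("mean", "low95", "high95")]
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) path <- default_parameter_file()
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$parameters
  if (is.null(entries)) stop("configuration lacks a 'parameters' list")
  reg <- do.call(rbind, lapply(entries, function(e) {
    data.frame(
      name = as.character(e$name),
      distribution = as.character(e$distribution),
      mean = as.numeric(e$mean),
      low95 = if (is.null(e$low95)) NA_real_ else as.numeric(e$low95),
      high95 = if (is.null(e$high95)) NA_real_ else as.numeric(e$high95),
      units = if (is.null(e$units)) "" else as.character(e$units),
      source = if (is.null(e$source)) "" else as.character(e$source),
      stringsAsFactors = FALSE
    )
  }))
  class(reg) <- c("cea_registry", "data.frame")
  validate_registry(reg)
  reg
}

#' Validate a parameter registry
#'
#' Checks completeness against the model's required parameter names, bound
#' ordering (`low95 <= mean <= high95`), proportion support in \[0, 1\],
#' absence of bounds on point parameters, and that the grade-mix fractions
#' (HSIL + LSIL + ASC-US) sum to the abnormal fraction within 0.005 at the
#' means.
#'
#' @param reg A `cea_registry`.
#' @return `reg`, invisibly, if valid; otherwise an error naming the
#'   offending parameter.
#' @export
validate_registry <- function(reg) {
  missing <- setdiff(.required_parameters, reg$name)
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$name)) {
    stop("duplicated parameter(s): ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  }
  for (i in seq_len(nrow(reg))) {
    p <- reg[i, ]
    if (!p$distribution %in% c("normal", "proportion", "point")) {
      stop("unknown distribution for '", p$name, "': ", p$distribution)
    }
    has_bounds <- !is.na(p$low95) && !is.na(p$high95)
    if (p$distribution == "point") {
      if (has_bounds) stop("point parameter '", p$name, "' must not carry bounds")
      next
    }
    if (!has_bounds) stop("parameter '", p$name, "' lacks 95% bounds")
    if (!(p$low95 <= p$mean && p$mean <= p$high95)) {
      stop("bound violation for '", p$name, "': requires low95 <= mean <= high95")
    }
    if (p$distribution == "proportion" && (p$low95 < 0 || p$high95 > 1)) {
      stop("proportion parameter '", p$name, "' has support outside [0, 1]")
    }
  }
  mix <- vapply(c("hsil_fraction", "lsil_fraction", "ascus_fraction"),
                function(nm) reg$mean[reg$name == nm], numeric(1))
  ab <- reg$mean[reg$name == "abnormal_fraction"]
  if (abs(sum(mix) - ab) > 0.005) {
    stop("grade-mix fractions sum to ", sum(mix),
         ", inconsistent with abnormal_fraction ", ab)
  }
  invisible(reg)
}

#' Write a registry back to YAML
#'
#' Round-trips with [load_parameters()]: reloading the written file yields an
#' identical registry.
#'
#' @param reg A `cea_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(reg, path) {
  entries <- lapply(seq_len(nrow(reg)), function(i) {
    p <- as.list(reg[i, , drop = FALSE])
    p <- lapply(p, function(x) x[[1]])
    if (is.na(p$low95)) p$low95 <- NULL
    if (is.na(p$high95)) p$high95 <- NULL
    p
  })
  yaml::write_yaml(list(parameters = entries), path)
  invisible(path)
}

#' Convert a 95% interval to a normal standard deviation
#'
#' The input tables report means with 95% interval bounds; sampling needs a
#' scale. Under a symmetric (normal-shaped) distribution the standard
#' deviation is `(high95 - low95) / (2 * 1.959964)`. Setting
#' `quantiles = "p5p95"` reinterprets the bounds as 5th/95th percentiles
#' (divisor `2 * 1.644854`) for sensitivity analyses.
#'
#' @param low95,high95 Interval bounds, `low95 < high95`.
#' @param quantiles `"p2.5p97.5"` (default) or `"p5p95"`.
#' @return The implied standard deviation.
#' @examples
#' interval_to_sd(1.44, 1.70) # 0.06633
#' @export
interval_to_sd <- function(low95, high95, quantiles = c("p2.5p97.5", "p5p95")) {
  quantiles <- match.arg(quantiles)
  if (!all(low95 < high95)) stop("interval_to_sd requires low95 < high95")
  z <- if (quantiles == "p2.5p97.5") .z975 else .z95
  (high95 - low95) / (2 * z)
}

#' Apply an odds ratio to a baseline probability
#'
#' Utility for sensitivity analyses: converts `p_base` to odds, multiplies by
#' `odds_ratio`, and converts back. The default model uses the tabled
#' probabilities directly (the published derivation of e.g. the broom's
#' endocervical-cell rate from the odds ratio is unstated), so this is
#' exposed as a documented helper only.
#'
#' @param p_base Baseline probability, strictly inside (0, 1).
#' @param odds_ratio Positive odds ratio.
#' @return The transformed probability.
#' @examples
#' or_apply(0.53, 1.57) # 0.639
#' @export
or_apply <- function(p_base, odds_ratio) {
  if (any(p_base <= 0 | p_base >= 1)) {
    stop("or_apply requires 0 < p_base < 1")
  }
  if (any(odds_ratio <= 0)) stop("or_apply requires odds_ratio > 0")
  odds <- odds_ratio * p_base / (1 - p_base)
  odds / (1 + odds)
}

## Sampling -------------------------------------------------------------------

# Deterministic per-(seed, trial) stream: a distinct sub-seed per call keeps
# sample_parameters(specs, seed, trial) reproducible without carrying RNG
# state between calls. R seeds are 32-bit, so combine in double precision.
.derive_seed <- function(seed, trial) {
  s <- (abs(as.double(seed)) %% 2147483647)
  as.integer((s * 1000003 + as.double(trial) * 7919 + 1) %% 2147483647)
}

# Truncated-normal draw via inverse CDF so the stream stays deterministic
# (no rejection loops).
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw one realization of every parameter
#'
#' Normal parameters are drawn from `Normal(mean, interval_to_sd(...))`
#' truncated below at zero (counts, odds ratios and costs are non-negative);
#' proportion parameters from the same symmetric shape truncated to \[0, 1\]
#' (the printed intervals are symmetric about their means, so a
#' moment-matched beta is not used); point parameters are returned as-is.
#' Identical `(seed, trial)` pairs reproduce identical sets.
#'
#' @param reg A `cea_registry`.
#' @param seed Integer base seed.
#' @param trial Trial index (>= 0).
#' @param quantiles Bound interpretation passed to [interval_to_sd()].
#' @return A named numeric vector of realized values (class `cea_params`)
#'   with a `provenance` attribute `"sampled(seed,trial)"`.
#' @export
sample_parameters <- function(reg, seed, trial = 0,
                              quantiles = c("p2.5p97.5", "p5p95")) {
  quantiles <- match.arg(quantiles)
  if (trial < 0) stop("trial index must be >= 0")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(seed, trial))
  vals <- numeric(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    p <- reg[i, ]
    vals[i] <- switch(p$distribution,
      point = p$mean,
      normal = .rtruncnorm(1, p$mean, interval_to_sd(p$low95, p$high95, quantiles),
                           0, Inf),
      proportion = .rtruncnorm(1, p$mean, interval_to_sd(p$low95, p$high95, quantiles),
                               0, 1)
    )
  }
  names(vals) <- reg$name
  structure(vals, class = "cea_params",
            provenance = sprintf("sampled(%d,%d)", as.integer(seed), as.integer(trial)))
}

#' Parameter set at the registry means
#'
#' @param reg A `cea_registry`.
#' @return A named numeric vector (class `cea_params`) with provenance
#'   `"means"`.
#' @export
param_means <- function(reg) {
  vals <- reg$mean
  names(vals) <- reg$name
  structure(vals, class = "cea_params", provenance = "means")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cea_registry <- function(x, ...) {
  cat("Parameter registry:", nrow(x), "parameters\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
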