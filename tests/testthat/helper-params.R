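# Shared fixtures: the default registry and convenience modifiers.

default_reg <- load_parameters()
means <- param_means(default_reg)

# Override values in a realized parameter set (keeps class/provenance).
mod_params <- function(params, ...) {
  over <- list(...)
  for (nm in names(over)) {
    stopifnot(nm %in% names(params))
    params[[nm]] <- over[[nm]]
  }
  params
}

# A degenerate "perfect screening" parameter set: every smear adequate,
# perfect test, nobody lost.
perfect_params <- function(base = means) {
  mod_params(base,
             sens_endocervical = 1, sens_no_endocervical = 1,
             sens_no_endocervical_hsil = 1, specificity = 1,
             satisfactory = 1, endocervical_spatula = 1,
             endocervical_broom = 1, lost_to_follow_up = 0, repeat_done = 1)
}

# Registry with every parameter collapsed to its mean as a point mass.
point_registry <- function(reg = default_reg) {
  reg$distribution <- "point"
  reg$low95 <- NA_real_
  reg$high95 <- NA_real_
  reg
}
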