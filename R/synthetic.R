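# Synthetic cohort generator.
#
# The generator emulates the statistical structure the analysis assumes: a
# cohort of n = 341 female hospital nurses with seven departments and two
# shift patterns at the published proportions, four job-characteristic
# scales and three burnout subscales with the published means/SDs and 8x8
# correlation structure (the moderator entering through its log), and a
# strongly right-skewed lognormal hair-cortisol moderator (median 3.3
# pg/mg).  An interaction regime can be planted by regenerating one outcome
# from a moderated linear predictor with a configurable crossover location.

continuous_block <- function() {
  c("job_control", "psych_demands", "supervisor_support", "coworker_support",
    "log_hcc", "ee", "dp", "pe")
}

#' Published-cohort default marginals and correlations
#'
#' @description
#' `default_scale_means()` / `default_scale_sds()` give the published means
#' and SDs of the seven scales; `default_correlation()` the published 8x8
#' Pearson correlation matrix over the scales and the log moderator;
#' `default_department_probs()` / `default_shift_probs()` the demographic
#' category proportions.
#'
#' @return Named numeric vector or matrix.
#' @export
default_scale_means <- function() {
  c(job_control = 62.38, psych_demands = 33.69, supervisor_support = 11.84,
    coworker_support = 12.51, ee = 3.42, dp = 2.45, pe = 4.12)
}

#' @rdname default_scale_means
#' @export
default_scale_sds <- function() {
  c(job_control = 8.38, psych_demands = 6.93, supervisor_support = 1.84,
    coworker_support = 1.50, ee = 1.51, dp = 1.33, pe = 1.24)
}

#' @rdname default_scale_means
#' @export
default_department_probs <- function() {
  c(ICU = 0.1525, EICU = 0.0762, emergency = 0.3255, radiotherapy = 0.0792,
    psychology = 0.0880, rehabilitation = 0.1202, other = 0.1584)
}

#' @rdname default_scale_means
#' @export
default_shift_probs <- function() {
  c(three_shift_8h = 0.9003, two_shift_12h = 0.0997)
}

#' @rdname default_scale_means
#' @export
default_correlation <- function() {
  v <- continuous_block()
  r <- diag(8)
  dimnames(r) <- list(v, v)
  set <- function(a, b, val) {
    r[a, b] <<- val
    r[b, a] <<- val
  }
  set("psych_demands", "job_control", -0.202)
  set("supervisor_support", "job_control", 0.404)
  set("supervisor_support", "psych_demands", -0.075)
  set("coworker_support", "job_control", 0.268)
  set("coworker_support", "psych_demands", 0.061)
  set("coworker_support", "supervisor_support", 0.510)
  set("log_hcc", "job_control", 0.079)
  set("log_hcc", "psych_demands", -0.040)
  set("log_hcc", "supervisor_support", 0.039)
  set("log_hcc", "coworker_support", 0.000)
  set("ee", "job_control", -0.250)
  set("ee", "psych_demands", 0.470)
  set("ee", "supervisor_support", -0.147)
  set("ee", "coworker_support", -0.089)
  set("ee", "log_hcc", -0.045)
  set("dp", "job_control", -0.315)
  set("dp", "psych_demands", 0.298)
  set("dp", "supervisor_support", -0.223)
  set("dp", "coworker_support", -0.179)
  set("dp", "log_hcc", -0.040)
  set("dp", "ee", 0.658)
  set("pe", "job_control", 0.240)
  set("pe", "psych_demands", -0.062)
  set("pe", "supervisor_support", 0.116)
  set("pe", "coworker_support", 0.120)
  set("pe", "log_hcc", 0.034)
  set("pe", "ee", -0.034)
  set("pe", "dp", -0.163)
  r
}

#' Declare a synthetic cohort
#'
#' Builds a validated `synthetic_spec`: the full generative description of
#' a cohort (marginals, correlation structure, moderator lognormal
#' parameters, demographic proportions, planted interaction regime, MCAR
#' rate, seed).  Defaults reproduce the published cohort's structure.
#' `hcc_logsd = 0.334` (log10 units) is the moderator spread consistent
#' with the published simple-slope separations via
#' `slope_high - slope_low = 2 * b_int * SD_mod`.
#'
#' @param n cohort size (default 341).
#' @param department_probs,shift_probs category proportions (must sum to 1).
#' @param scale_means,scale_sds named moments for the seven scales.
#' @param correlation 8x8 symmetric unit-diagonal PSD target over
#'   `continuous_block()` order (scales, log moderator, outcomes).
#' @param hcc_logmean,hcc_logsd lognormal (base-10) moderator parameters;
#'   defaults give median 3.3 pg/mg.
#' @param pattern planted regime: `"null"`, `"differential_susceptibility"`,
#'   `"vantage_sensitivity"` or `"diathesis_stress"`.
#' @param env_variable,outcome_variable the pair carrying the planted
#'   interaction.
#' @param coefficients optional `c(b0, b_env, b_mod, b_int)` on centered
#'   raw-unit predictors; usually filled by [plant_interaction()].
#' @param noise_sd residual SD of the planted outcome (default 1.2,
#'   comparable to the published burnout-subscale SDs).
#' @param missing_rate MCAR fraction applied by [generate_cohort()].
#' @param seed integer RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 341L,
                           department_probs = default_department_probs(),
                           shift_probs = default_shift_probs(),
                           scale_means = default_scale_means(),
                           scale_sds = default_scale_sds(),
                           correlation = default_correlation(),
                           hcc_logmean = log10(3.3),
                           hcc_logsd = 0.334,
                           pattern = "null",
                           env_variable = "job_control",
                           outcome_variable = "pe",
                           coefficients = NULL,
                           noise_sd = 1.2,
                           missing_rate = 0,
                           seed = 1L) {
  if (!is_count(n) || n < 1) {
    rosmod_abort("rosmod_invalid_spec", "n must be a positive count")
  }
  check_probs <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      rosmod_abort("rosmod_invalid_spec",
                   sprintf("%s must be %d probabilities summing to 1", what, k))
    }
  }
  check_probs(department_probs, 7L, "department_probs")
  check_probs(shift_probs, 2L, "shift_probs")
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10)) ||
      any(abs(diag(correlation) - 1) > 1e-10) ||
      any(abs(correlation) > 1)) {
    rosmod_abort("rosmod_invalid_spec",
                 "correlation must be symmetric with unit diagonal and |r| <= 1")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    rosmod_abort("rosmod_not_psd",
                 sprintf("correlation matrix not positive semi-definite (smallest eigenvalue %.4g)",
                         min(ev)),
                 smallest_eigenvalue = min(ev))
  }
  patterns <- c("null", "differential_susceptibility", "vantage_sensitivity",
                "diathesis_stress")
  if (!pattern %in% patterns) {
    rosmod_abort("rosmod_invalid_spec",
                 paste0("unknown pattern '", pattern, "'"))
  }
  if (!env_variable %in% scale_variables() ||
      !outcome_variable %in% outcome_variables()) {
    rosmod_abort("rosmod_invalid_spec", "unknown env or outcome variable")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    rosmod_abort("rosmod_invalid_spec", "noise_sd must be > 0")
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    rosmod_abort("rosmod_invalid_spec", "missing_rate must lie in [0, 0.5)")
  }
  structure(list(
    n = as.integer(n), department_probs = department_probs,
    shift_probs = shift_probs, scale_means = scale_means,
    scale_sds = scale_sds, correlation = correlation,
    hcc_logmean = hcc_logmean, hcc_logsd = hcc_logsd,
    pattern = pattern, env_variable = env_variable,
    outcome_variable = outcome_variable, coefficients = coefficients,
    noise_sd = noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Coding direction of environment and outcome variables
#'
#' @description
#' `env_polarity()` is `+1` when higher scores mean a more supportive
#' environment (job control, both supports) and `-1` when higher scores
#' mean more adversity (psychological demands).  `outcome_polarity()` is
#' `+1` when higher is better (professional efficiency) and `-1` when
#' higher is worse (emotional exhaustion, depersonalization).
#'
#' @param variable a scale or outcome name.
#' @return `+1` or `-1`.
#' @export
env_polarity <- function(variable) {
  if (!variable %in% scale_variables()) {
    rosmod_abort("rosmod_missing_polarity",
                 paste0("no environment polarity declared for ", variable))
  }
  if (variable == "psych_demands") -1 else 1
}

#' @rdname env_polarity
#' @export
outcome_polarity <- function(variable) {
  if (!variable %in% outcome_variables()) {
    rosmod_abort("rosmod_missing_polarity",
                 paste0("no outcome polarity declared for ", variable))
  }
  if (variable == "pe") 1 else -1
}

#' Plant an interaction regime into a synthetic spec
#'
#' Sets `(b0, b_env, b_mod, b_int)` on centered raw-unit predictors so that
#' the implied crossover `x_c = -b_mod / b_int` (in environment-SD units)
#' sits where the named theoretical model requires over the `[-2, +2]` SD
#' evaluation range:
#' * differential susceptibility: `x_c = 0` (group difference reverses at
#'   the mean — "for better and for worse");
#' * diathesis stress: `x_c` at the supportive edge, so the group
#'   difference is exactly zero in the most supportive environment and
#'   grows toward adversity;
#' * vantage sensitivity: `x_c` at the adverse edge — difference only under
#'   support;
#' * null: `b_int = 0`.
#'
#' Effect sizes are declared in residual-SD units: `es_env` (default 0.30)
#' scales the environment main effect per environment SD, `es_int` (default
#' 0.15) the slope change per moderator SD.  Signs follow the declared
#' polarities so the high-moderator group is the more responsive
#' ("susceptible") one by default.
#'
#' @param spec a [synthetic_spec()].
#' @param pattern overrides `spec$pattern` when given.
#' @param es_env,es_int standardized main and interaction effect sizes.
#' @param susceptible `"high_moderator"` (default) or `"low_moderator"`.
#' @return The spec with `coefficients` set.
#' @export
plant_interaction <- function(spec, pattern = NULL, es_env = 0.30,
                              es_int = 0.15,
                              susceptible = c("high_moderator",
                                              "low_moderator")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  susceptible <- match.arg(susceptible)
  if (!is.null(pattern)) spec$pattern <- pattern
  patterns <- c("null", "differential_susceptibility", "vantage_sensitivity",
                "diathesis_stress")
  if (!spec$pattern %in% patterns) {
    rosmod_abort("rosmod_invalid_spec",
                 paste0("unknown pattern '", spec$pattern, "'"))
  }
  sd_e <- spec$scale_sds[[spec$env_variable]]
  sd_m <- spec$hcc_logsd
  s0 <- spec$noise_sd
  dir <- env_polarity(spec$env_variable) *
    outcome_polarity(spec$outcome_variable)
  b_env <- es_env * s0 / sd_e * dir
  b_int <- es_int * s0 / (sd_e * sd_m) * dir *
    (if (susceptible == "high_moderator") 1 else -1)
  x_c <- switch(spec$pattern,
    null = NA_real_,
    differential_susceptibility = 0,
    diathesis_stress = 2 * env_polarity(spec$env_variable),
    vantage_sensitivity = -2 * env_polarity(spec$env_variable)
  )
  if (spec$pattern == "null") {
    b_int <- 0
    b_mod <- 0
  } else {
    b_mod <- -b_int * x_c * sd_e
  }
  spec$coefficients <- c(b0 = spec$scale_means[[spec$outcome_variable]],
                         b_env = b_env, b_mod = b_mod, b_int = b_int)
  spec
}

#' Generate a synthetic cohort
#'
#' Draws the continuous block from a multivariate normal matched to the
#' spec moments through the symmetric square root of the correlation
#' matrix; the moderator is generated on the log10 scale inside that block
#' and exponentiated to `hcc_raw`.  Demographics are drawn categorically;
#' tenure is drawn from the published three-band mix (48.99% under 5
#' years, 32.26% 5-15, 18.77% over 15), uniform within band.  When the
#' spec carries planted `coefficients`, the target outcome is regenerated
#' from the moderated linear predictor plus Gaussian noise (the target
#' correlations for that outcome are overridden — an arbitrary marginal
#' correlation and a fixed interaction cannot be imposed simultaneously).
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n
  vars <- continuous_block()

  # symmetric square root of the target correlation
  e <- eigen(spec$correlation, symmetric = TRUE)
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  z <- matrix(stats::rnorm(n * 8), n, 8) %*% root
  colnames(z) <- vars

  means <- c(spec$scale_means[scale_variables()],
             log_hcc = spec$hcc_logmean,
             spec$scale_means[outcome_variables()])
  sds <- c(spec$scale_sds[scale_variables()],
           log_hcc = spec$hcc_logsd,
           spec$scale_sds[outcome_variables()])
  x <- sweep(sweep(z, 2, sds[vars], "*"), 2, means[vars], "+")

  department <- sample(names(spec$department_probs), n, replace = TRUE,
                       prob = spec$department_probs)
  shift <- sample(names(spec$shift_probs), n, replace = TRUE,
                  prob = spec$shift_probs)
  band <- sample(1:3, n, replace = TRUE, prob = c(0.4899, 0.3226, 0.1877))
  tenure <- stats::runif(n,
                         min = c(0.5, 5, 15)[band],
                         max = c(5, 15, 30)[band])

  df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    department = department,
    shift_pattern = shift,
    tenure_years = tenure,
    job_control = x[, "job_control"],
    psych_demands = x[, "psych_demands"],
    supervisor_support = x[, "supervisor_support"],
    coworker_support = x[, "coworker_support"],
    ee = x[, "ee"], dp = x[, "dp"], pe = x[, "pe"],
    hcc_raw = 10^x[, "log_hcc"],
    stringsAsFactors = FALSE
  )

  if (!is.null(spec$coefficients)) {
    b <- spec$coefficients
    env_c <- df[[spec$env_variable]] - spec$scale_means[[spec$env_variable]]
    mod_c <- x[, "log_hcc"] - spec$hcc_logmean
    df[[spec$outcome_variable]] <-
      b[["b0"]] + b[["b_env"]] * env_c + b[["b_mod"]] * mod_c +
      b[["b_int"]] * env_c * mod_c + stats::rnorm(n, 0, spec$noise_sd)
  }

  tab <- cohort_table(df, provenance = sprintf("synthetic(seed=%d, pattern=%s)",
                                               spec$seed, spec$pattern))
  if (spec$missing_rate > 0) {
    tab <- inject_missing(tab, spec$missing_rate, seed = spec$seed + 1L)
  }
  tab
}

#' Inject missing-completely-at-random holes
#'
#' Each eligible cell is masked independently with probability `rate`.  The
#' moderator (`hcc_raw`) and demographics are never eligible.
#'
#' @param table a [cohort_table()].
#' @param rate MCAR fraction in `[0, 0.5)`.
#' @param seed RNG seed.
#' @param variables columns to mask; defaults to the seven scale/outcome
#'   scores.
#' @return The table with `NA` holes.
#' @export
inject_missing <- function(table, rate, seed = 1L,
                           variables = c(scale_variables(),
                                         outcome_variables())) {
  if (rate < 0 || rate >= 0.5) {
    rosmod_abort("rosmod_invalid_spec", "rate must lie in [0, 0.5)")
  }
  if (any(variables %in% c("hcc_raw", "log_hcc"))) {
    rosmod_abort("rosmod_missing_moderator",
                 "the moderator must not be masked")
  }
  if (rate == 0) return(table)
  df <- as.data.frame(table)
  variables <- intersect(variables, names(df))
  set.seed(seed)
  for (v in variables) {
    df[[v]][stats::runif(nrow(df)) < rate] <- NA
  }
  out <- df
  class(out) <- class(table)
  attr(out, "provenance") <- attr(table, "provenance")
  out
}
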