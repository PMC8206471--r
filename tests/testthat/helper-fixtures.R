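# Fixtures are built in code: a tiny hand-written cohort, an
# exact-correlation data constructor, and a direct moderation_fit builder
# for probing oracles.

make_cohort_df <- function(n = 6) {
  deps <- rep(rosmod_departments(), length.out = n)
  data.frame(
    subject_id = sprintf("N%03d", seq_len(n)),
    department = deps,
    shift_pattern = rep(rosmod_shifts(), length.out = n),
    tenure_years = seq(1, by = 2.5, length.out = n),
    job_control = seq(40, by = 3, length.out = n),
    psych_demands = seq(20, by = 2, length.out = n),
    supervisor_support = rep(c(8, 12, 15), length.out = n),
    coworker_support = rep(c(9, 11, 14), length.out = n),
    ee = seq(2, 6, length.out = n),
    dp = seq(1.5, 5, length.out = n),
    pe = seq(5.5, 2, length.out = n),
    hcc_raw = seq(1.5, by = 1.1, length.out = n),
    stringsAsFactors = FALSE
  )
}

# n x k data whose sample correlation matrix is EXACTLY `target`
# (empirically whiten, then re-color with the target's Cholesky factor)
exact_corr_data <- function(n, target, seed = 1) {
  set.seed(seed)
  k <- ncol(target)
  x <- matrix(rnorm(n * k), n, k)
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))      # exact identity covariance
  x %*% chol(target)
}

# moderation_fit built directly from coefficients and a covariance block;
# enough structure for simple_slopes / jn_region / crossover / poi / pa
make_fake_fit <- function(b_env, b_mod, b_int, v,
                          env_sd = 1, mod_sd = 1, env_mean = 0,
                          df_resid = 1000, outcome = "pe",
                          env = "job_control") {
  terms <- c(env, "log_hcc", paste0(env, ":log_hcc"))
  dimnames(v) <- list(terms, terms)
  coefs <- data.frame(
    term = c("(Intercept)", terms),
    B = c(0, b_env, b_mod, b_int),
    SE = c(NA, sqrt(diag(v))),
    beta = NA, t = NA, p = NA, stringsAsFactors = FALSE
  )
  structure(list(
    outcome = outcome, env = env, moderator = "log_hcc",
    coefficients = coefs, vcov = v,
    n = df_resid + 4, df_resid = df_resid,
    env_mean = env_mean, env_sd = env_sd,
    mod_mean = 0, mod_sd = mod_sd, sd_y = 1,
    int_name = paste0(env, ":log_hcc")
  ), class = "moderation_fit")
}

# independent PoI oracle: trapezoidal integration of the absolute
# between-line gap on each side of the (clamped) crossover
poi_trapz_oracle <- function(fit, eval_range = c(-2, 2), outcome_pol = 1) {
  co <- fit$coefficients
  b_env <- co$B[co$term == fit$env]
  b_mod <- co$B[co$term == fit$moderator]
  b_int <- co$B[co$term == fit$int_name]
  gap <- function(xsd) 2 * fit$mod_sd * (b_mod + b_int * xsd * fit$env_sd)
  slope_high <- b_env + b_int * fit$mod_sd
  slope_low <- b_env - b_int * fit$mod_sd
  s <- if (abs(slope_high) >= abs(slope_low)) 1 else -1
  xc <- -b_mod / b_int / fit$env_sd
  xc_cl <- min(max(xc, eval_range[1]), eval_range[2])
  trapz <- function(a, b) {
    if (b <= a) return(0)
    xs <- seq(a, b, length.out = 2001)
    g <- abs(gap(xs))
    sum((g[-1] + g[-length(g)]) / 2) * (b - a) / 2000
  }
  area_right <- trapz(xc_cl, eval_range[2])
  area_left <- trapz(eval_range[1], xc_cl)
  vantage_right <- s * b_int * outcome_pol > 0
  if (vantage_right) area_right / (area_right + area_left)
  else area_left / (area_right + area_left)
}

random_psd3 <- function(scale = 0.1) {
  a <- matrix(rnorm(9, sd = scale), 3, 3)
  crossprod(a) + diag(1e-6, 3)
}

# generate -> derive columns -> fit one moderated regression
fit_planted <- function(spec, env_col = NULL) {
  coh <- as.data.frame(generate_cohort(spec))
  coh$log_hcc <- transform_hcc(coh$hcc_raw)
  env <- spec$env_variable
  if (env %in% c("job_control", "psych_demands") && !is.null(env_col) &&
      env_col == "std") {
    coh[[paste0(env, "_std")]] <- jcq_standard_score(coh[[env]], env)
    env <- paste0(env, "_std")
  }
  fit_hierarchical(coh, spec$outcome_variable, env, "log_hcc")
}
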