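test_that("simple slopes follow the linear evaluation and SE form", {
  v <- diag(c(0.04, 0.02, 0.01))
  fit <- make_fake_fit(b_env = 2, b_mod = 0.3, b_int = 1, v = v,
                       mod_sd = 0.5)
  ss <- simple_slopes(fit)
  expect_equal(ss$slope[ss$group == "high"], 2.5)
  expect_equal(ss$slope[ss$group == "low"], 1.5)
  # SE at z = 1 with var(b_env)=0.04, var(b_int)=0.01, cov=0: sqrt(0.05)
  fit1 <- make_fake_fit(2, 0, 1, diag(c(0.04, 0.02, 0.01)), mod_sd = 1)
  ss1 <- simple_slopes(fit1)
  expect_equal(ss1$se[ss1$group == "high"], sqrt(0.05), tolerance = 1e-10)
  expect_equal(round(ss1$se[ss1$group == "high"], 4), 0.2236)
})

test_that("slope midpoint identity holds on random fits", {
  set.seed(60)
  for (i in 1:50) {
    fit <- make_fake_fit(rnorm(1), rnorm(1), rnorm(1), random_psd3(),
                         mod_sd = runif(1, 0.1, 2))
    ss <- simple_slopes(fit)
    b_env <- fit$coefficients$B[fit$coefficients$term == fit$env]
    expect_equal(mean(ss$slope), b_env, tolerance = 1e-12)
  }
})

test_that("Johnson-Neyman bounds solve the hand-derived quadratic", {
  # t_crit exactly 2 via alpha = 2 P(T_1000 > 2)
  alpha2 <- 2 * (1 - pt(2, 1000))
  v <- diag(c(0.01, 0.04, 0.04))
  fit <- make_fake_fit(b_env = 1, b_mod = 0.5, b_int = 1, v = v,
                       df_resid = 1000)
  ros <- jn_region(fit, alpha = alpha2)
  # 0.84 x^2 + x + 0.09 = 0 -> x = -1.092395, -0.098081
  expect_equal(ros$bounds_sd, c(-1.092395, -0.098081), tolerance = 1e-5)
  expect_equal(ros$ros_lower, -1.092395, tolerance = 1e-5)
  expect_equal(ros$ros_upper, -0.098081, tolerance = 1e-5)
  expect_true(ros$sig_at_lower)  # significant outside the window
  expect_true(ros$sig_at_upper)
  # |t| at each bound equals t_crit to 1e-8 (definition check)
  t_at <- function(x) {
    (0.5 + x) / sqrt(0.04 + x^2 * 0.04)
  }
  for (b in ros$bounds_sd) expect_equal(abs(t_at(b)), 2, tolerance = 1e-8)

  # b_int -> 0 with a large main moderator effect: the difference is
  # significant throughout the evaluation window (any real roots sit far
  # outside it, where the interaction variance finally dominates)
  fit2 <- make_fake_fit(1, 5, 1e-9, diag(c(0.01, 0.04, 0.04)),
                        df_resid = 1000)
  ros2 <- jn_region(fit2, alpha = alpha2)
  expect_true(all(ros2$intervals$significant))
  expect_true(all(abs(ros2$bounds_sd) > 6))
  expect_true(is.na(ros2$ros_lower))  # nonsig region is not one interval

  fit3 <- make_fake_fit(1, 0.5, 1, diag(c(0.01, 0.04, 0)))
  expect_error(jn_region(fit3), class = "rosmod_degenerate")
})

test_that("jn_region agrees with a dense grid scan of the t-ratio", {
  set.seed(61)
  checked <- 0
  for (i in 1:30) {
    v <- random_psd3(0.2)
    fit <- make_fake_fit(rnorm(1), rnorm(1, sd = 0.5), rnorm(1, sd = 0.5),
                         v, env_sd = runif(1, 0.5, 2), df_resid = 300)
    ros <- jn_region(fit, alpha = 0.05, eval_range = c(-6, 6))
    blk <- rosmod:::interaction_block(fit)
    xs <- seq(-6, 6, length.out = 100001) * fit$env_sd
    tt <- (blk$b[["mod"]] + blk$b[["int"]] * xs) /
      sqrt(blk$v["mod", "mod"] + 2 * xs * blk$v["mod", "int"] +
             xs^2 * blk$v["int", "int"])
    f <- abs(tt) - ros$t_crit
    cross <- which(f[-1] * f[-length(f)] < 0)
    grid_roots <- (xs[cross] - f[cross] * (xs[cross + 1] - xs[cross]) /
                     (f[cross + 1] - f[cross])) / fit$env_sd
    in_range <- ros$bounds_sd[ros$bounds_sd > -6 & ros$bounds_sd < 6]
    expect_equal(length(grid_roots), length(in_range))
    if (length(in_range)) {
      expect_equal(sort(grid_roots), sort(in_range), tolerance = 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)  # the draw produced real root cases
})

test_that("crossover point matches -b_mod / b_int in SD units", {
  fit <- make_fake_fit(1, 0, 2, diag(c(0.01, 0.01, 0.01)))
  expect_equal(crossover_point(fit), 0)
  # published job-control model coefficients: B_mod 0.037, B_int 3.055,
  # env SD on the standard-score scale 8.38/72
  fit2 <- make_fake_fit(2.462, 0.037, 3.055, diag(c(0.01, 0.01, 0.01)),
                        env_sd = 8.38 / 72)
  expect_equal(crossover_point(fit2), -0.104, tolerance = 1e-3)
  fit3 <- make_fake_fit(2.462, 0.037, -3.055, diag(c(0.01, 0.01, 0.01)),
                        env_sd = 8.38 / 72)
  expect_equal(crossover_point(fit3), -crossover_point(fit2))
  fit0 <- make_fake_fit(1, 0.5, 0, diag(c(0.01, 0.01, 0.01)))
  expect_error(crossover_point(fit0), class = "rosmod_degenerate")
})

test_that("PoI closed form matches its geometry and the integration oracle", {
  v <- diag(c(0.01, 0.01, 0.01))
  # crossover at the range midpoint (0 of [-2,2]) -> 0.5
  expect_equal(poi_index(make_fake_fit(1, 0, 1, v)), 0.5)
  # crossover at the adverse edge (-2 for a supportive env) -> 1
  expect_equal(poi_index(make_fake_fit(1, 2, 1, v)), 1.0)
  # crossover at +1 with vantage side right -> 1/(1+9) = 0.1
  expect_equal(poi_index(make_fake_fit(1, -1, 1, v)), 0.1)
  # numeric integration oracle on random fits
  set.seed(62)
  for (i in 1:50) {
    b_int <- rnorm(1)
    if (abs(b_int) < 0.05) b_int <- 0.5
    fit <- make_fake_fit(rnorm(1), rnorm(1), b_int, v,
                         env_sd = runif(1, 0.5, 2),
                         mod_sd = runif(1, 0.2, 1))
    poi <- poi_index(fit)
    expect_equal(poi, poi_trapz_oracle(fit), tolerance = 1e-6)
    expect_gte(poi, 0); expect_lte(poi, 1)
  }
})

test_that("PA is the empirical fraction on the vantage side", {
  v <- diag(c(0.01, 0.01, 0.01))
  # b_mod = -0.5, b_int = 1 -> crossover +0.5; diff high-low > 0 to the
  # right; susceptible = high (slopes 1.5 vs 0.5); pe higher-better ->
  # vantage side right
  fit <- make_fake_fit(1, -0.5, 1, v)
  expect_equal(pa_index(fit, c(-1, 0, 1, 2)), 0.5)
  expect_equal(pa_index(fit, c(5, 6, 7)), 1.0)  # crossover below sample min
  x <- rnorm(101)
  xc <- crossover_point(fit)
  expect_equal(pa_index(fit, x), mean(x > xc))
  expect_error(pa_index(fit, numeric(0)), class = "rosmod_invalid_input")
})

test_that("classification follows region-of-significance sidedness", {
  # planted regimes at large n give unambiguous geometry
  specs <- list(
    differential_susceptibility = plant_interaction(synthetic_spec(
      n = 5000L, pattern = "differential_susceptibility", seed = 70)),
    vantage_sensitivity = plant_interaction(synthetic_spec(
      n = 5000L, pattern = "vantage_sensitivity", seed = 71)),
    diathesis_stress = plant_interaction(synthetic_spec(
      n = 5000L, pattern = "diathesis_stress", seed = 72))
  )
  for (lab in names(specs)) {
    fit <- fit_planted(specs[[lab]])
    probe <- probe_interaction(fit)
    ip <- fit$coefficients$p[fit$coefficients$term == fit$int_name]
    cls <- classify_pattern(probe, ip, env_pol = 1)
    expect_equal(cls$label, lab)
    expect_equal(cls$susceptible_group, "high_moderator")
  }
  # adverse-coded environment: vantage regime probes at the low-demands end
  vs_pd <- plant_interaction(synthetic_spec(
    n = 5000L, pattern = "vantage_sensitivity", env_variable = "psych_demands",
    outcome_variable = "ee", seed = 73))
  fit <- fit_planted(vs_pd)
  probe <- probe_interaction(fit)
  ip <- fit$coefficients$p[fit$coefficients$term == fit$int_name]
  cls <- classify_pattern(probe, ip, env_pol = -1)
  expect_equal(cls$label, "vantage_sensitivity")
  expect_true(cls$sig_supportive_end)
  expect_false(cls$sig_adverse_end)

  # a non-significant interaction is never classified
  cls_none <- classify_pattern(probe, interaction_p = 0.5, env_pol = -1)
  expect_equal(cls_none$label, "none")
  # optional PoI gate narrows differential susceptibility
  fitds <- fit_planted(specs$differential_susceptibility)
  pds <- probe_interaction(fitds)
  ipds <- fitds$coefficients$p[fitds$coefficients$term == fitds$int_name]
  expect_equal(classify_pattern(pds, ipds, env_pol = 1)$label,
               "differential_susceptibility")
  expect_error(classify_pattern(pds, ipds, env_pol = 0),
               class = "rosmod_missing_polarity")
})

test_that("classification is invariant to positive affine rescaling", {
  spec <- plant_interaction(synthetic_spec(
    n = 5000L, pattern = "differential_susceptibility", seed = 74))
  coh <- as.data.frame(generate_cohort(spec))
  coh$log_hcc <- transform_hcc(coh$hcc_raw)
  run <- function(df) {
    fit <- fit_hierarchical(df, "pe", "job_control", "log_hcc")
    probe <- probe_interaction(fit)
    ip <- fit$coefficients$p[fit$coefficients$term == fit$int_name]
    classify_pattern(probe, ip, env_pol = 1)$label
  }
  base <- run(coh)
  coh2 <- coh
  coh2$job_control <- 3.7 * coh2$job_control + 12
  coh2$log_hcc <- 0.4 * coh2$log_hcc - 1
  coh2$pe <- 2.5 * coh2$pe + 3
  expect_equal(run(coh2), base)
})

test_that("probe grid flags match the analytic region", {
  spec <- plant_interaction(synthetic_spec(
    n = 5000L, pattern = "differential_susceptibility", seed = 75))
  fit <- fit_planted(spec)
  g <- probe_grid(fit)
  ros <- jn_region(fit)
  inside <- g$env_sd > ros$ros_lower & g$env_sd < ros$ros_upper
  expect_true(all(g$significant[!inside][abs(g$diff_t[!inside]) > ros$t_crit + 1e-9]))
  expect_true(all(!g$significant[inside]))
  expect_equal(nrow(g), 201)
})
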