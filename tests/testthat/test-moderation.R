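make_fit_cohort <- function(n = 341, seed = 31, pattern = "null",
                            planted = FALSE) {
  spec <- synthetic_spec(n = as.integer(n), pattern = pattern, seed = seed)
  if (planted) spec <- plant_interaction(spec)
  coh <- as.data.frame(generate_cohort(spec))
  coh$log_hcc <- transform_hcc(coh$hcc_raw)
  coh$job_control_std <- jcq_standard_score(coh$job_control, "job_control")
  coh
}

test_that("dummy coding produces g-1 reference-zero indicators", {
  df <- make_cohort_df(7)
  d <- dummy_code(df, "department", "other")
  expect_equal(ncol(d), 6)
  expect_true(all(d[df$department == "other", ] == 0))
  expect_true(all(colSums(d[df$department != "other", , drop = FALSE]) >= 1))

  s <- dummy_code(df, "shift_pattern", "three_shift_8h")
  expect_equal(ncol(s), 1)
  expect_equal(unname(s[, 1]),
               as.numeric(df$shift_pattern == "two_shift_12h"))

  expect_error(dummy_code(df, "department", "surgery"),
               class = "rosmod_invalid_category")
  df$department[1] <- "ward9"
  expect_error(dummy_code(df, "department", "other",
                          levels = rosmod_departments()),
               class = "rosmod_invalid_category")
})

test_that("hierarchical fit agrees with the lm / anova oracles", {
  coh <- make_fit_cohort(n = 341, seed = 31)
  fit <- fit_hierarchical(coh, "ee", "job_control_std", "log_hcc")

  # oracle: the same final model through stats::lm on centered columns
  coh$env_c <- coh$job_control_std - mean(coh$job_control_std)
  coh$mod_c <- coh$log_hcc - mean(coh$log_hcc)
  ref <- lm(ee ~ department + shift_pattern + tenure_years + env_c + mod_c +
              env_c:mod_c, data = coh)
  ref_s <- summary(ref)
  ours <- fit$coefficients
  expect_equal(ours$B[ours$term == fit$int_name],
               unname(coef(ref)["env_c:mod_c"]), tolerance = 1e-10)
  expect_equal(ours$SE[ours$term == fit$int_name],
               unname(ref_s$coefficients["env_c:mod_c", "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(fit$steps$r2_cumulative[4], ref_s$r.squared,
               tolerance = 1e-12)

  # F-change oracle: pairwise stats::anova comparisons (the F-change
  # denominator is each step's own residual mean square)
  m1 <- lm(ee ~ department + shift_pattern + tenure_years, coh)
  m2 <- update(m1, . ~ . + env_c)
  m3 <- update(m2, . ~ . + mod_c)
  m4 <- update(m3, . ~ . + env_c:mod_c)
  cmps <- list(anova(m1, m2), anova(m2, m3), anova(m3, m4))
  expect_equal(fit$steps$f_change[2:4],
               vapply(cmps, function(a) a$F[2], numeric(1)),
               tolerance = 1e-10)
  expect_equal(fit$steps$p[2:4],
               vapply(cmps, function(a) a$`Pr(>F)`[2], numeric(1)),
               tolerance = 1e-10)
  # df2 is each step's own residual df: n - predictors_at_step - 1
  expect_equal(fit$steps$df2, c(332L, 331L, 330L, 329L))
  expect_true(all(diff(fit$steps$r2_cumulative) >= -1e-15))
})

test_that("interaction B and SE are invariant to main-effect centering", {
  coh <- make_fit_cohort(n = 341, seed = 32)
  fit <- fit_hierarchical(coh, "pe", "job_control_std", "log_hcc")
  # uncentered product regression; the product term's distance from its own
  # conditional expectation is unchanged, so B and SE match
  ref <- lm(pe ~ department + shift_pattern + tenure_years +
              job_control_std * log_hcc, data = coh)
  ref_s <- summary(ref)$coefficients
  ours <- fit$coefficients
  expect_equal(ours$B[ours$term == fit$int_name],
               unname(coef(ref)["job_control_std:log_hcc"]),
               tolerance = 1e-8)
  expect_equal(ours$SE[ours$term == fit$int_name],
               unname(ref_s["job_control_std:log_hcc", "Std. Error"]),
               tolerance = 1e-8)
})

test_that("standardized beta equals B * sd(x) / sd(y)", {
  coh <- make_fit_cohort(n = 341, seed = 33)
  fit <- fit_hierarchical(coh, "dp", "coworker_support", "log_hcc")
  co <- fit$coefficients
  i <- co$term == "tenure_years"
  expect_equal(co$beta[i],
               co$B[i] * sd(coh$tenure_years) / sd(coh$dp),
               tolerance = 1e-12)
  # cross-check: regressing the z-scored outcome on the z-scored final
  # design columns (the product column standardized as a column of its
  # own) reproduces every beta exactly
  Xz <- scale(fit$design_final[, -1])
  yz <- scale(coh$dp)
  bz <- coef(lm(yz ~ Xz))[-1]
  expect_equal(co$beta[match(colnames(Xz), co$term)], unname(bz),
               tolerance = 1e-10)
})

test_that("degenerate designs raise named errors", {
  coh <- make_fit_cohort(n = 341, seed = 34)
  coh$ee_copy <- coh$ee
  # outcome exactly linear in env: step 2 saturates, later increments 0
  coh2 <- coh
  coh2$pe <- 1 + 2 * coh2$job_control_std
  fit <- fit_hierarchical(coh2, "pe", "job_control_std", "log_hcc")
  expect_equal(fit$steps$r2_cumulative[2], 1, tolerance = 1e-12)
  expect_equal(fit$steps$delta_r2[3], 0, tolerance = 1e-10)
  expect_equal(fit$steps$delta_r2[4], 0, tolerance = 1e-10)

  coh3 <- coh
  coh3$dup <- coh3$job_control_std
  expect_error(
    fit_hierarchical(coh3, "ee", "job_control_std", "log_hcc",
                     covariates = list(
                       categorical = c(department = "other"),
                       continuous = c("tenure_years", "dup"))),
    class = "rosmod_rank_deficient")
  expect_error(fit_hierarchical(coh[1:15, ], "ee", "job_control_std",
                                "log_hcc"),
               class = "rosmod_invalid_input")
  coh4 <- coh
  coh4$ee[3] <- NA
  expect_error(fit_hierarchical(coh4, "ee", "job_control_std", "log_hcc"),
               class = "rosmod_missing_items")
})

test_that("collinearity diagnostics match closed forms", {
  # exactly orthogonal predictors -> all VIF 1
  x <- exact_corr_data(100, diag(3), seed = 40)
  y <- rnorm(100)
  df <- data.frame(y = y, a = x[, 1], b = x[, 2], cc = x[, 3],
                   m = rnorm(100))
  fit <- fit_hierarchical(df, "y", "a", "m",
                          covariates = list(categorical = NULL,
                                            continuous = c("b", "cc")))
  cr <- collinearity_report(fit)
  # b, cc are exactly orthogonal to a and each other; the product column
  # adds only chance correlation at n = 100
  main <- cr[cr$term %in% c("b", "cc"), ]
  expect_true(all(main$vif >= 1))
  expect_equal(main$vif, c(1, 1), tolerance = 0.1)
  expect_equal(cr$vif, 1 / cr$tolerance, tolerance = 1e-12)

  # exact r = 0.6 pair -> VIF = 1/(1-0.36) = 1.5625
  r <- matrix(c(1, 0.6, 0.6, 1), 2)
  xy <- exact_corr_data(100, r, seed = 41)
  df2 <- data.frame(y = rnorm(100), a = xy[, 1], m = xy[, 2])
  fit2 <- fit_hierarchical(df2, "y", "a", "m",
                           covariates = list(categorical = NULL,
                                             continuous = character(0)))
  cr2 <- collinearity_report(fit2)
  # the product term adds a little chance correlation at n = 100
  expect_equal(cr2$vif[cr2$term == "a"], 1.5625, tolerance = 0.05)
  # exact closed form on the pair alone: tolerance 0.64, VIF 1.5625
  f_pair <- rosmod:::ols_fit(cbind(m = xy[, 2]), xy[, 1])
  expect_equal(1 / (1 - f_pair$r2), 1.5625, tolerance = 1e-10)

  # near-duplicated predictor flagged
  df3 <- df
  df3$b2 <- df3$b + rnorm(100, sd = 1e-6)
  fit3 <- fit_hierarchical(df3, "y", "a", "m",
                           covariates = list(categorical = NULL,
                                             continuous = c("b", "b2")))
  cr3 <- collinearity_report(fit3)
  expect_true(all(cr3$flagged[cr3$term %in% c("b", "b2")]))
})

test_that("OLS core matches brute-force normal equations", {
  set.seed(50)
  for (i in 1:10) {
    n <- sample(30:60, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    ours <- rosmod:::ols_fit(X, y)
    Xi <- cbind(1, X)
    ref <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(unname(ours$coef), unname(drop(ref)), tolerance = 1e-8)
  }
})
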