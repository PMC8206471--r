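# Scale scoring and data preparation.
#
# JCQ scales are weighted item sums.  The user's-guide weights are not
# printed anywhere in the source tables, but the standardization footnotes
# fix the attainable ranges (24-96 for job control, 12-48 for psychological
# demands) and, for 4-point items, those ranges are reproduced uniquely by
# doubling the six skill-discretion items / quadrupling the three
# decision-authority items, and tripling the first two demand items /
# doubling the remaining three.  The weighting is a config block so an
# alternative user's-guide convention can be declared without code change.

#' Default JCQ scoring weights
#'
#' @return A list with components `skill`, `authority` (job-control item
#'   weights) and `demands_first`, `demands_rest` (psychological-demands
#'   weights for the first two and remaining three items).
#' @export
jcq_weights <- function() {
  list(skill = 2, authority = 4, demands_first = 3, demands_rest = 2)
}

#' Score the Job Content Questionnaire
#'
#' Items (columns) are ordered: 1-6 skill discretion, 7-9 decision
#' authority, 10-14 psychological demands, 15-18 supervisor support, 19-22
#' coworker support.  Job control = `skill * sum(items 1-6) + authority *
#' sum(items 7-9)` (range 24-96 at default weights); psychological demands
#' = `demands_first * sum(items 10-11) + demands_rest * sum(items 12-14)`
#' (range 12-48); supports are plain 4-item sums (range 4-16).
#'
#' @param items numeric vector of 22 responses in 1..4, or an n x 22 matrix.
#' @param weights see [jcq_weights()].
#' @return A data.frame with columns `job_control`, `psych_demands`,
#'   `supervisor_support`, `coworker_support`.
#' @export
#' @examples
#' score_jcq(rep(4, 22))  # job_control 96, psych_demands 48
score_jcq <- function(items, weights = jcq_weights()) {
  m <- to_item_matrix(items, 22L, "JCQ")
  check_items(as.data.frame(m), 1L, 4L, "JCQ")
  if (anyNA(m)) {
    rosmod_abort("rosmod_missing_items",
                 "JCQ items contain missing responses; impute before scoring")
  }
  data.frame(
    job_control = weights$skill * rowSums(m[, 1:6, drop = FALSE]) +
      weights$authority * rowSums(m[, 7:9, drop = FALSE]),
    psych_demands = weights$demands_first * rowSums(m[, 10:11, drop = FALSE]) +
      weights$demands_rest * rowSums(m[, 12:14, drop = FALSE]),
    supervisor_support = rowSums(m[, 15:18, drop = FALSE]),
    coworker_support = rowSums(m[, 19:22, drop = FALSE])
  )
}

#' Score the Maslach Burnout Inventory (general survey)
#'
#' Subscale scores are item means: emotional exhaustion items 1-5,
#' depersonalization items 6-10, professional efficiency items 11-16.
#'
#' @param items numeric vector of 16 responses in 1..7, or an n x 16 matrix.
#' @return A data.frame with columns `ee`, `dp`, `pe` (each in \[1, 7\]).
#' @export
score_mbi <- function(items) {
  m <- to_item_matrix(items, 16L, "MBI")
  check_items(as.data.frame(m), 1L, 7L, "MBI")
  if (anyNA(m)) {
    rosmod_abort("rosmod_missing_items",
                 "MBI items contain missing responses; impute before scoring")
  }
  data.frame(
    ee = rowMeans(m[, 1:5, drop = FALSE]),
    dp = rowMeans(m[, 6:10, drop = FALSE]),
    pe = rowMeans(m[, 11:16, drop = FALSE])
  )
}

to_item_matrix <- function(items, k, what) {
  if (is.vector(items) && is.numeric(items)) items <- matrix(items, nrow = 1)
  m <- as.matrix(items)
  if (ncol(m) != k) {
    rosmod_abort("rosmod_invalid_input",
                 sprintf("%s scoring needs exactly %d items, got %d",
                         what, k, ncol(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' JCQ standard scores and their inverse
#'
#' The regression layer enters job control as `(score - 24) / 72` and
#' psychological demands as `(score - 12) / 36`, mapping the attainable
#' ranges onto the unit interval.
#'
#' @param x raw (or standard, for the inverse) scale scores.
#' @param scale `"job_control"` or `"psych_demands"`.
#' @return Numeric vector.
#' @export
jcq_standard_score <- function(x, scale = c("job_control", "psych_demands")) {
  scale <- match.arg(scale)
  if (scale == "job_control") (x - 24) / 72 else (x - 12) / 36
}

#' @rdname jcq_standard_score
#' @export
jcq_raw_score <- function(x, scale = c("job_control", "psych_demands")) {
  scale <- match.arg(scale)
  if (scale == "job_control") x * 72 + 24 else x * 36 + 12
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`, sample
#' variances with the n-1 denominator.
#'
#' @param item_matrix subjects x items numeric matrix, k >= 2 items, no
#'   missing entries.
#' @param scale optional scale name carried into the report.
#' @return A list (`reliability_report`) with `scale`, `cronbach_alpha`,
#'   `k_items`, `n`.
#' @export
cronbach_alpha <- function(item_matrix, scale = "scale") {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) {
    rosmod_abort("rosmod_invalid_input", "alpha requires k >= 2 items")
  }
  if (anyNA(m)) {
    rosmod_abort("rosmod_missing_items", "alpha requires complete items")
  }
  total_var <- var1(rowSums(m))
  if (total_var <= 0) {
    rosmod_abort("rosmod_degenerate", "zero variance of the item sum")
  }
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var1)) / total_var)
  structure(list(scale = scale, cronbach_alpha = alpha, k_items = k,
                 n = nrow(m)),
            class = "reliability_report")
}

#' Log-transform the hair-cortisol moderator
#'
#' Base-10 logarithm.  The base is irrelevant to correlations and pattern
#' classification (affine invariance) but is fixed for reproducibility.
#'
#' @param hcc_raw cortisol concentrations in pg/mg, strictly positive.
#' @return `log10(hcc_raw)`.
#' @export
transform_hcc <- function(hcc_raw) {
  if (anyNA(hcc_raw) || any(hcc_raw <= 0)) {
    rosmod_abort("rosmod_out_of_range",
                 "hcc_raw must be positive and non-missing")
  }
  log10(hcc_raw)
}

# Adjusted Fisher-Pearson (small-sample) skewness and excess kurtosis,
# the estimators behind the conventional "statistic +/- SE" reporting.
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 + 6)
}

#' Standard errors of skewness and kurtosis
#'
#' Closed forms depending on n only:
#' `se_skew = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))`,
#' `se_kurt = 2 * se_skew * sqrt((n^2-1) / ((n-3)(n+5)))`.
#'
#' @param n sample size.
#' @return Numeric value.
#' @export
se_skewness <- function(n) sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))

#' @rdname se_skewness
#' @export
se_kurtosis <- function(n) {
  2 * se_skewness(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

ks_statistic_normal <- function(x, mean, sd) {
  x <- sort(x)
  n <- length(x)
  f <- stats::pnorm(x, mean, sd)
  max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
}

#' Distributional audit of a numeric variable
#'
#' Reports adjusted Fisher-Pearson skewness and excess kurtosis with their
#' closed-form standard errors, and a one-sample Kolmogorov-Smirnov test
#' against a normal with mean and SD estimated from the data.  Because the
#' parameters are estimated, the p-value is obtained by seeded Monte Carlo
#' (Lilliefors-style): each replicate draws n standard normals and computes
#' the KS statistic against its own fitted normal.
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @param n_mc Monte-Carlo replicates for the p-value (default 10000).
#' @param seed RNG seed for the Monte Carlo.
#' @param cap_display if `TRUE`, the `ks_p_display` element is capped at
#'   0.200, mirroring the conventional ">= .200" reporting of legacy
#'   statistical software.
#' @return A `normality_report` list: `n`, `skewness`, `se_skewness`,
#'   `kurtosis` (excess), `se_kurtosis`, `ks_statistic`, `ks_p`,
#'   `ks_p_display`.
#' @export
normality_report <- function(values, n_mc = 10000L, seed = 20170901L,
                             cap_display = TRUE) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) rosmod_abort("rosmod_invalid_input", "need n >= 8")
  if (stats::sd(x) == 0) {
    rosmod_abort("rosmod_degenerate", "constant vector")
  }
  d_obs <- ks_statistic_normal(x, mean(x), stats::sd(x))
  d_null <- local({
    set.seed(seed)
    vapply(seq_len(n_mc), function(i) {
      z <- stats::rnorm(n)
      ks_statistic_normal(z, mean(z), stats::sd(z))
    }, numeric(1))
  })
  p <- (sum(d_null >= d_obs) + 1) / (n_mc + 1)
  structure(list(
    n = n,
    skewness = sample_skewness(x),
    se_skewness = se_skewness(n),
    kurtosis = sample_excess_kurtosis(x),
    se_kurtosis = se_kurtosis(n),
    ks_statistic = d_obs,
    ks_p = p,
    ks_p_display = if (cap_display) min(p, 0.200) else p
  ), class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf(
    "n = %d; skewness %.3f +/- %.3f; excess kurtosis %.3f +/- %.3f; KS D = %.4f, p = %.3f\n",
    x$n, x$skewness, x$se_skewness, x$kurtosis, x$se_kurtosis,
    x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Expectation-maximization imputation under a multivariate normal model
#'
#' Fits a multivariate normal to the continuous analysis variables by EM
#' (E-step: conditional moments of the missing block given the observed;
#' M-step: updated mean and covariance), iterating until the largest
#' absolute change in any mean or covariance entry is below `tol`, then
#' imputes conditional means.  Deterministic given its input; observed
#' cells are never touched.  Missingness in the moderator is an error.
#'
#' @param table a [cohort_table()] (or plain data.frame).
#' @param variables columns included in the normal model; defaults to the
#'   four job-characteristic scales and three burnout subscales.
#' @param max_missing per-variable missing-fraction cap (default 0.25).
#' @param tol,max_iter convergence controls (1e-6, 500).
#' @return The completed table, with attributes `em_iterations` and
#'   `em_converged`.
#' @export
em_impute <- function(table, variables = c(scale_variables(),
                                           outcome_variables()),
                      max_missing = 0.25, tol = 1e-6, max_iter = 500L) {
  df <- as.data.frame(table)
  if ("hcc_raw" %in% names(df) && anyNA(df$hcc_raw)) {
    rosmod_abort("rosmod_missing_moderator",
                 "moderator (hcc_raw) must have no missing data")
  }
  if ("hcc_raw" %in% variables || "log_hcc" %in% variables) {
    rosmod_abort("rosmod_missing_moderator",
                 "the moderator is excluded from the imputation model")
  }
  variables <- intersect(variables, names(df))
  y <- as.matrix(df[variables])
  storage.mode(y) <- "double"
  miss_frac <- colMeans(is.na(y))
  if (any(miss_frac > max_missing)) {
    rosmod_abort(
      "rosmod_missing_cap",
      sprintf("missing fraction %.2f on '%s' exceeds cap %.2f",
              max(miss_frac), variables[which.max(miss_frac)], max_missing))
  }
  if (!anyNA(y)) return(table)

  n <- nrow(y); p <- ncol(y)
  mu <- colMeans(y, na.rm = TRUE)
  sigma <- stats::cov(y, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  diag(sigma) <- pmax(diag(sigma), 1e-8)
  # group rows by missingness pattern so each pattern is solved once
  pat <- apply(is.na(y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)

  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    for (rows in groups) {
      mis <- is.na(y[rows[1], ])
      yr <- y[rows, , drop = FALSE]
      if (!any(mis)) {
        t1 <- t1 + colSums(yr)
        t2 <- t2 + crossprod(yr)
        next
      }
      obs <- !mis
      s_oo <- sigma[obs, obs, drop = FALSE]
      s_mo <- sigma[mis, obs, drop = FALSE]
      a <- s_mo %*% solve(s_oo)
      cond_cov <- sigma[mis, mis, drop = FALSE] - a %*% t(s_mo)
      e <- yr
      dev <- sweep(yr[, obs, drop = FALSE], 2, mu[obs])
      e[, mis] <- matrix(mu[mis], nrow(yr), sum(mis), byrow = TRUE) +
        dev %*% t(a)
      t1 <- t1 + colSums(e)
      t2 <- t2 + crossprod(e)
      t2[mis, mis] <- t2[mis, mis] + length(rows) * cond_cov
    }
    mu_new <- t1 / n
    sigma_new <- t2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    trace <- c(trace, delta)
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    rosmod_abort("rosmod_em_nonconvergence",
                 sprintf("EM did not converge in %d iterations (last delta %.2e)",
                         iter, trace[length(trace)]),
                 trace = trace)
  }
  # final imputation: conditional means under the converged parameters
  for (rows in groups) {
    mis <- is.na(y[rows[1], ])
    if (!any(mis)) next
    obs <- !mis
    a <- sigma[mis, obs, drop = FALSE] %*% solve(sigma[obs, obs, drop = FALSE])
    dev <- sweep(y[rows, obs, drop = FALSE], 2, mu[obs])
    y[rows, mis] <- matrix(mu[mis], length(rows), sum(mis), byrow = TRUE) +
      dev %*% t(a)
  }
  df[variables] <- as.data.frame(y)
  out <- if (inherits(table, "cohort_table")) {
    cohort_table(df, provenance = attr(table, "provenance"))
  } else df
  attr(out, "em_iterations") <- iter
  attr(out, "em_converged") <- TRUE
  out
}

#' Center or z-score continuous variables
#'
#' Records per-variable mean and SD (n-1 denominator) in the `"scaling"`
#' attribute so the transformation is exactly invertible.
#'
#' @param table data.frame.
#' @param variables columns to transform.
#' @param mode `"center"` (subtract the mean) or `"zscore"`.
#' @return The transformed table with a `"scaling"` attribute
#'   (`data.frame(variable, mean, sd)`).
#' @export
center_and_standardize <- function(table, variables,
                                   mode = c("center", "zscore")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  info <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(variables)) {
    v <- variables[i]
    x <- df[[v]]
    if (!is.numeric(x)) {
      rosmod_abort("rosmod_invalid_input", paste0(v, " is not continuous"))
    }
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      rosmod_abort("rosmod_degenerate", paste0("zero variance in ", v))
    }
    info$mean[i] <- mean(x)
    info$sd[i] <- s
    df[[v]] <- if (mode == "center") x - mean(x) else (x - mean(x)) / s
  }
  attr(df, "scaling") <- info
  df
}
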