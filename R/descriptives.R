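# Descriptive layer: correlation matrix with significance, one-way group
# ANOVAs, common-method-bias screens, and dependent-correlation comparison.

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations with two-sided t-based p-values.
#'
#' @param table data.frame.
#' @param variables numeric columns to correlate.
#' @return A data.frame of entries `var_a`, `var_b`, `r`, `p`, `n` for all
#'   unordered pairs, plus a `"matrix"` attribute with the full symmetric
#'   matrix.
#' @export
correlation_matrix <- function(table, variables) {
  df <- as.data.frame(table)[variables]
  for (v in variables) {
    x <- df[[v]][!is.na(df[[v]])]
    if (length(unique(x)) < 2) {
      rosmod_abort("rosmod_degenerate", paste0("constant variable: ", v))
    }
  }
  k <- length(variables)
  pairs <- utils::combn(k, 2)
  out <- data.frame(var_a = variables[pairs[1, ]],
                    var_b = variables[pairs[2, ]],
                    r = NA_real_, p = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x <- df[[pairs[1, i]]]
    y <- df[[pairs[2, i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) {
      rosmod_abort("rosmod_invalid_input", "fewer than 3 complete pairs")
    }
    r <- stats::cor(x[ok], y[ok])
    out$r[i] <- r
    out$n[i] <- n
    if (abs(r) >= 1) {
      out$p[i] <- 0
    } else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      out$p[i] <- 2 * stats::pt(-abs(t), n - 2)
    }
  }
  m <- diag(k)
  dimnames(m) <- list(variables, variables)
  for (i in seq_len(ncol(pairs))) {
    m[pairs[1, i], pairs[2, i]] <- m[pairs[2, i], pairs[1, i]] <- out$r[i]
  }
  attr(out, "matrix") <- m
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `df_between = g - 1`,
#' `df_within = n - g`.
#'
#' @param table data.frame.
#' @param outcome numeric column name.
#' @param group categorical column name; every group needs >= 2
#'   observations.
#' @return A list `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(table, outcome, group) {
  df <- as.data.frame(table)
  y <- df[[outcome]]
  g <- factor(df[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    rosmod_abort("rosmod_invalid_input",
                 "need >= 2 groups with >= 2 observations each")
  }
  n <- length(y)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ssb <- sum(sizes * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df_between = k - 1L, df_within = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Harman single-factor common-method-bias screen
#'
#' Fraction of total item variance carried by the first unrotated principal
#' component of the item correlation matrix (largest eigenvalue divided by
#' the number of items), conventionally compared against 40%.
#'
#' @param item_matrix subjects x items numeric matrix (>= 3 items, more
#'   subjects than items).
#' @return A list `fraction`, `eigenvalues`, `exceeds_40pct`, `singular`.
#' @export
harman_efa <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 3) rosmod_abort("rosmod_invalid_input", "need >= 3 items")
  if (nrow(m) <= ncol(m)) {
    rosmod_abort("rosmod_invalid_input", "need more subjects than items")
  }
  r <- stats::cor(m)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  singular <- min(ev) < 1e-10
  fraction <- max(ev) / ncol(m)
  list(fraction = fraction, eigenvalues = ev,
       exceeds_40pct = fraction > 0.40, singular = singular)
}

# ML discrepancy of a candidate covariance against the sample covariance
ml_discrepancy <- function(sigma, s, log_det_s) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  log_det <- 2 * sum(log(diag(ch)))
  log_det + sum(diag(chol2inv(ch) %*% s)) - log_det_s - nrow(s)
}

#' One-factor confirmatory factor analysis with fit indices
#'
#' Fits the single-common-factor model `Sigma = lambda lambda' + Psi` by
#' maximum likelihood on the sample covariance (quasi-Newton over loadings
#' and log-uniquenesses, uniquenesses bounded above 1e-6), and reports the
#' conventional fit battery: `chi2 = (n-1) F_ML`, chi2/df, GFI
#' (`1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`), CFI and TLI against
#' the independence baseline, and
#' `RMSEA = sqrt(max(0, chi2 - df) / (df (n-1)))`.
#'
#' @param item_matrix subjects x items numeric matrix (>= 4 items so that
#'   df > 0, more subjects than items); alternatively pass a covariance
#'   matrix via `S` together with `n`.
#' @param S optional sample covariance matrix (used instead of
#'   `item_matrix`).
#' @param n sample size (required with `S`).
#' @return A `fit_indices` list: `chi2`, `df`, `chi2_over_df`, `gfi`,
#'   `cfi`, `tli`, `rmsea`, `p`, `loadings`, `uniquenesses`, `converged`,
#'   `gradient_norm`, `heywood`.
#' @export
single_factor_cfa <- function(item_matrix = NULL, S = NULL, n = NULL) {
  if (is.null(S)) {
    m <- as.matrix(item_matrix)
    if (nrow(m) <= ncol(m)) {
      rosmod_abort("rosmod_invalid_input", "need more subjects than items")
    }
    S <- stats::cov(m)
    n <- nrow(m)
  }
  S <- as.matrix(S)
  p <- ncol(S)
  if (p < 4) rosmod_abort("rosmod_invalid_input", "need >= 4 items (df > 0)")
  if (is.null(n) || n <= p) {
    rosmod_abort("rosmod_invalid_input", "need sample size n > items")
  }
  log_det_s <- determinant(S, logarithm = TRUE)$modulus[1]

  # start: loadings from the first principal component, half-split variance
  e1 <- eigen(S, symmetric = TRUE)
  lambda0 <- e1$vectors[, 1] * sqrt(max(e1$values[1], 1e-6))
  psi0 <- pmax(diag(S) - lambda0^2, 0.1 * diag(S))

  obj <- function(theta) {
    lambda <- theta[1:p]
    psi <- pmax(exp(theta[(p + 1):(2 * p)]), 1e-6)
    ml_discrepancy(tcrossprod(lambda) + diag(psi, p), S, log_det_s)
  }
  grad <- function(theta) {
    lambda <- theta[1:p]
    psi <- pmax(exp(theta[(p + 1):(2 * p)]), 1e-6)
    sigma <- tcrossprod(lambda) + diag(psi, p)
    si <- solve(sigma)
    d <- si %*% (sigma - S) %*% si   # dF/dSigma
    c(2 * d %*% lambda, diag(d) * psi)
  }
  fit <- stats::optim(c(lambda0, log(psi0)), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  lambda <- fit$par[1:p]
  psi <- pmax(exp(fit$par[(p + 1):(2 * p)]), 1e-6)
  gnorm <- sqrt(sum(grad(fit$par)^2))
  converged <- fit$convergence == 0
  if (!converged && gnorm > 1e-3) {
    rosmod_abort("rosmod_cfa_nonconvergence",
                 sprintf("CFA optimizer did not converge (gradient norm %.3g)",
                         gnorm))
  }
  f_ml <- max(fit$value, 0)
  df <- p * (p + 1) / 2 - 2 * p
  chi2 <- (n - 1) * f_ml
  # independence baseline: free variances, zero covariances
  f_base <- sum(log(diag(S))) - log_det_s
  chi2_base <- (n - 1) * f_base
  df_base <- p * (p - 1) / 2
  d_model <- max(chi2 - df, 0)
  d_base <- max(chi2_base - df_base, 0)
  cfi <- if (max(d_model, d_base) == 0) 1 else 1 - d_model / max(d_base, d_model)
  tli <- if (chi2_base > df_base) {
    (chi2_base / df_base - chi2 / df) / (chi2_base / df_base - 1)
  } else 1
  sigma_hat <- tcrossprod(lambda) + diag(psi, p)
  w <- solve(sigma_hat) %*% S
  gfi <- 1 - sum(diag((w - diag(p)) %*% (w - diag(p)))) / sum(diag(w %*% w))
  structure(list(
    chi2 = chi2, df = df, chi2_over_df = chi2 / df, gfi = gfi,
    cfi = cfi, tli = tli,
    rmsea = sqrt(max(0, chi2 - df) / (df * (n - 1))),
    p = stats::pchisq(chi2, df, lower.tail = FALSE),
    loadings = lambda, uniquenesses = psi,
    converged = TRUE, gradient_norm = gnorm,
    heywood = any(psi <= 1.01e-6)
  ), class = "fit_indices")
}

#' Compare two dependent correlations sharing a variable
#'
#' Tests `H0: rho12 = rho13` for correlations measured on the same n
#' subjects, where variable 1 is shared.  `variant = "meng"` implements the
#' Meng-Rosenthal-Rubin Z (Fisher-z difference scaled by
#' `sqrt((n-3) / (2 (1-r23) h))` with `h = (1 - f rbar2)/(1 - rbar2)`,
#' `f = min(1, (1-r23)/(2(1-rbar2)))`, `rbar2 = (r12^2 + r13^2)/2`);
#' `variant = "steiger"` implements Steiger's Z* with the pooled-correlation
#' covariance term.
#'
#' @param r12,r13 the two correlations being compared (share variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (> 10).
#' @param variant `"meng"` or `"steiger"`.
#' @return A list `r12`, `r13`, `r23`, `n`, `z`, `p`, `variant`.
#' @export
compare_dependent_r <- function(r12, r13, r23, n,
                                variant = c("meng", "steiger")) {
  variant <- match.arg(variant)
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    rosmod_abort("rosmod_invalid_input", "correlations must satisfy |r| < 1")
  }
  if (n <= 10) rosmod_abort("rosmod_invalid_input", "need n > 10")
  rm3 <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  if (min(eigen(rm3, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    rosmod_abort("rosmod_not_psd",
                 "the three correlations do not form a PSD matrix")
  }
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  if (variant == "meng") {
    rbar2 <- (r12^2 + r13^2) / 2
    f <- min(1, (1 - r23) / (2 * (1 - rbar2)))
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - r23) * h))
  } else {
    rb <- (r12 + r13) / 2
    psi <- r23 * (1 - rb^2 - rb^2) - 0.5 * rb * rb *
      (1 - rb^2 - rb^2 - r23^2)
    sbar <- psi / (1 - rb^2)^2
    z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * sbar))
  }
  list(r12 = r12, r13 = r13, r23 = r23, n = n, z = z,
       p = 2 * stats::pnorm(-abs(z)), variant = variant)
}
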