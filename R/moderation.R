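# Four-step moderated hierarchical regression.
#
# Step 1: demographics (department dummies, shift indicator, tenure);
# step 2: the centered environment scale; step 3: the centered log
# moderator; step 4: their product.  Each step is an OLS fit of the
# cumulative design; the R-squared increment is tested with the F-change
# statistic.  The final-step coefficient covariance is retained because
# interaction probing needs it.

#' Dummy-code a categorical variable
#'
#' Produces g-1 indicator columns named `<variable>_<level>`; rows at the
#' reference level are all-zero.
#'
#' @param table data.frame.
#' @param variable categorical column name.
#' @param reference reference level (no indicator).
#' @param levels optional fixed level set; values outside it (or outside
#'   the observed levels) raise an error rather than being coerced.
#' @return A numeric matrix with one row per record.
#' @export
dummy_code <- function(table, variable, reference, levels = NULL) {
  x <- as.data.frame(table)[[variable]]
  lev <- levels %||% (if (is.factor(x)) base::levels(x) else sort(unique(as.character(x))))
  x <- as.character(x)
  if (!reference %in% lev) {
    rosmod_abort("rosmod_invalid_category",
                 paste0("reference level '", reference, "' not among levels"))
  }
  unseen <- setdiff(unique(x), lev)
  if (length(unseen)) {
    rosmod_abort("rosmod_invalid_category",
                 paste0("unseen level(s): ", paste(unseen, collapse = ", ")))
  }
  keep <- setdiff(lev, reference)
  m <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, paste(variable, keep, sep = "_")))
  m
}

default_covariates <- function() {
  list(categorical = c(department = "other", shift_pattern = "three_shift_8h"),
       continuous = "tenure_years")
}

# core OLS on a design matrix with intercept prepended; qr-based
ols_fit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    rosmod_abort("rosmod_rank_deficient",
                 paste0("rank-deficient design; aliased term(s): ",
                        paste(aliased, collapse = ", ")),
                 aliased = aliased)
  }
  coef <- qr.coef(qr_x, y)
  fitted <- drop(Xi %*% coef)
  resid <- y - fitted
  df_resid <- length(y) - ncol(Xi)
  sigma2 <- sum(resid^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qr_x))
  dimnames(xtx_inv) <- list(colnames(Xi), colnames(Xi))
  tss <- sum((y - mean(y))^2)
  list(coef = coef, vcov = sigma2 * xtx_inv, sigma2 = sigma2,
       df_resid = df_resid, r2 = 1 - sum(resid^2) / tss, X = Xi)
}

coef_table <- function(fit, y, terms = NULL) {
  b <- fit$coef
  se <- sqrt(diag(fit$vcov))
  t <- b / se
  p <- 2 * stats::pt(-abs(t), fit$df_resid)
  sds <- apply(fit$X, 2, stats::sd)
  beta <- b * sds / stats::sd(y)
  beta["(Intercept)"] <- NA
  out <- data.frame(term = names(b), B = unname(b), SE = unname(se),
                    beta = unname(beta), t = unname(t), p = unname(p),
                    stringsAsFactors = FALSE)
  if (!is.null(terms)) out <- out[out$term %in% terms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a four-step moderated hierarchical regression
#'
#' The environment and moderator columns are centered internally (their
#' means and SDs are recorded on the fit); the step-4 interaction is the
#' product of the centered columns, so its coefficient and SE are invariant
#' to the centering of the main effects.  The F-change at each step is
#' `(delta_R2 / df1) / ((1 - R2_step) / df2)` with `df2 = n - p_step - 1`.
#'
#' @param table a completed [cohort_table()] (or data.frame) with no
#'   missing values among the modelled columns.
#' @param outcome outcome column name.
#' @param env environment (exposure) column name — enter JCQ scales as
#'   their unit-interval standard scores to reproduce the published
#'   coefficient scale.
#' @param moderator moderator column name (the log moderator).
#' @param covariates list with `categorical` (named character vector,
#'   `c(column = reference_level)`) and `continuous` (column names);
#'   defaults to department (reference `"other"`), shift pattern
#'   (reference `"three_shift_8h"`) and tenure.
#' @return A `moderation_fit` with `steps` (step summaries), `coefficients`
#'   at entry and from the final model, the final coefficient covariance,
#'   and the scaling constants probing needs.
#' @export
fit_hierarchical <- function(table, outcome, env, moderator,
                             covariates = default_covariates()) {
  df <- as.data.frame(table)
  used <- c(outcome, env, moderator, names(covariates$categorical),
            covariates$continuous)
  if (anyNA(df[used])) {
    rosmod_abort("rosmod_missing_items",
                 "modelled columns contain missing values; impute first")
  }
  y <- df[[outcome]]
  n <- length(y)

  dummies <- do.call(cbind, lapply(names(covariates$categorical), function(v) {
    dummy_code(df, v, covariates$categorical[[v]])
  }))
  cont <- as.matrix(df[covariates$continuous])
  X1 <- cbind(dummies, cont)

  env_mean <- mean(df[[env]]); env_sd <- stats::sd(df[[env]])
  mod_mean <- mean(df[[moderator]]); mod_sd <- stats::sd(df[[moderator]])
  if (env_sd == 0 || mod_sd == 0) {
    rosmod_abort("rosmod_degenerate", "constant env or moderator")
  }
  env_c <- df[[env]] - env_mean
  mod_c <- df[[moderator]] - mod_mean
  int_name <- paste0(env, ":", moderator)

  designs <- list(X1,
                  cbind(X1, structure(cbind(env_c), dimnames = list(NULL, env))),
                  NULL, NULL)
  designs[[3]] <- cbind(designs[[2]],
                        structure(cbind(mod_c), dimnames = list(NULL, moderator)))
  designs[[4]] <- cbind(designs[[3]],
                        structure(cbind(env_c * mod_c),
                                  dimnames = list(NULL, int_name)))

  if (n <= ncol(designs[[4]]) + 11) {
    rosmod_abort("rosmod_invalid_input",
                 "n must exceed the parameter count by more than 10")
  }

  fits <- lapply(designs, ols_fit, y = y)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  p_step <- vapply(designs, ncol, integer(1))
  entered <- list(colnames(X1), env, moderator, int_name)
  steps <- data.frame(
    step = 1:4,
    terms_entered = vapply(entered, paste, character(1), collapse = ", "),
    delta_r2 = c(r2[1], diff(r2)),
    df1 = c(ncol(X1), 1L, 1L, 1L),
    df2 = n - p_step - 1L,
    r2_cumulative = r2,
    stringsAsFactors = FALSE
  )
  steps$f_change <- (steps$delta_r2 / steps$df1) /
    ((1 - steps$r2_cumulative) / steps$df2)
  steps$p <- stats::pf(steps$f_change, steps$df1, steps$df2,
                       lower.tail = FALSE)

  at_entry <- lapply(1:4, function(s) {
    coef_table(fits[[s]], y, terms = entered[[s]])
  })
  final <- coef_table(fits[[4]], y)

  structure(list(
    outcome = outcome, env = env, moderator = moderator,
    steps = steps, coefficients_at_entry = at_entry,
    coefficients = final, vcov = fits[[4]]$vcov,
    n = n, df_resid = fits[[4]]$df_resid,
    env_mean = env_mean, env_sd = env_sd,
    mod_mean = mod_mean, mod_sd = mod_sd,
    sd_y = stats::sd(y),
    int_name = int_name,
    design_final = fits[[4]]$X
  ), class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("<moderation_fit> %s ~ %s * %s (n = %d)\n",
              x$outcome, x$env, x$moderator, x$n))
  print(x$steps[c("step", "delta_r2", "f_change", "df1", "df2", "p")],
        digits = 4)
  invisible(x)
}

# pull a final-model coefficient and the 3x3 covariance block probing needs
interaction_block <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  terms <- c(fit$env, fit$moderator, fit$int_name)
  if (!all(terms %in% rownames(fit$vcov))) {
    rosmod_abort("rosmod_invalid_input", "coefficient covariance block missing")
  }
  b <- fit$coefficients$B[match(terms, fit$coefficients$term)]
  names(b) <- c("env", "mod", "int")
  v <- fit$vcov[terms, terms]
  dimnames(v) <- list(c("env", "mod", "int"), c("env", "mod", "int"))
  list(b = b, v = v)
}

#' Tolerance and variance-inflation diagnostics
#'
#' For each final-step predictor, the tolerance is `1 - R2` of regressing
#' that predictor on all the others; `VIF = 1 / tolerance`.  Terms with
#' tolerance <= 0.2 or VIF >= 5 are flagged.
#'
#' @param fit a [fit_hierarchical()] result.
#' @return A data.frame `term`, `tolerance`, `vif`, `flagged`.
#' @export
collinearity_report <- function(fit) {
  X <- fit$design_final[, -1, drop = FALSE]  # drop intercept
  out <- data.frame(term = colnames(X), tolerance = NA_real_,
                    vif = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    f <- ols_fit(X[, -j, drop = FALSE], X[, j])
    out$tolerance[j] <- 1 - f$r2
    out$vif[j] <- 1 / out$tolerance[j]
  }
  out$flagged <- out$tolerance <= 0.2 | out$vif >= 5
  out
}
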