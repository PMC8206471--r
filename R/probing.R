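# Interaction probing: simple slopes at moderator M +/- 1 SD, the
# Johnson-Neyman region of significance on the environment axis, the
# crossover point, and the PoI / PA indices; then classification against
# the diathesis-stress / differential-susceptibility / vantage-sensitivity
# taxonomy.
#
# With final-model coefficients (b_env, b_mod, b_int) on centered
# predictors, the high-vs-low moderator group difference at a centered
# environment value x is 2 * SD_mod * (b_mod + b_int * x); its t-ratio is
# invariant to the 2 * SD_mod factor, so significance is driven by
# t(x) = (b_mod + b_int x) / sqrt(v_mm + 2 x c_mi + x^2 v_ii).

#' Simple slopes at moderator M +/- 1 SD
#'
#' The slope of outcome on environment at moderator offset `z` is
#' `b_env + b_int * z`, with `SE = sqrt(v_ee + z^2 v_ii + 2 z c_ei)`;
#' `z = +/- 1` moderator SD.  The mean of the two slopes equals `b_env`
#' exactly.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param moderator_sd moderator SD defining "high"/"low"; defaults to the
#'   fitted cohort's SD of the (log) moderator.
#' @return A data.frame with rows `high`/`low`: `slope`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(fit, moderator_sd = fit$mod_sd) {
  blk <- interaction_block(fit)
  z <- c(high = moderator_sd, low = -moderator_sd)
  slope <- blk$b[["env"]] + blk$b[["int"]] * z
  se <- sqrt(blk$v["env", "env"] + z^2 * blk$v["int", "int"] +
               2 * z * blk$v["env", "int"])
  t <- slope / se
  data.frame(group = names(z), moderator_offset = unname(z),
             slope = unname(slope), se = unname(se), t = unname(t),
             p = unname(2 * stats::pt(-abs(t), fit$df_resid)),
             stringsAsFactors = FALSE)
}

#' Johnson-Neyman region of significance on the environment axis
#'
#' Solves `(b_mod + b_int x)^2 = t_crit^2 (v_mm + 2 x c_mi + x^2 v_ii)` for
#' the centered environment values where the high-vs-low moderator group
#' difference is exactly significant at `alpha`, converts the roots to
#' environment-SD units, and classifies each sub-interval of `eval_range`
#' by the t-ratio at its midpoint.  No real roots means the difference is
#' significant everywhere or nowhere.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param alpha two-sided significance level (default 0.05).
#' @param eval_range evaluation window in environment-SD units (default
#'   `c(-2, 2)`).
#' @return A list: `bounds_sd` (real roots, SD units), `ros_lower`,
#'   `ros_upper` (the non-significance window, possibly infinite),
#'   `intervals` (sub-intervals of `eval_range` with significance flags),
#'   `sig_at_lower`, `sig_at_upper` (at the `eval_range` ends; a bound
#'   exactly on an end counts as significant), `t_crit`, `alpha`,
#'   `eval_range`.
#' @export
jn_region <- function(fit, alpha = 0.05, eval_range = c(-2, 2)) {
  blk <- interaction_block(fit)
  if (blk$v["int", "int"] <= 0) {
    rosmod_abort("rosmod_degenerate", "zero interaction variance")
  }
  t_crit <- stats::qt(1 - alpha / 2, fit$df_resid)
  b_mod <- blk$b[["mod"]]; b_int <- blk$b[["int"]]
  v_mm <- blk$v["mod", "mod"]; v_ii <- blk$v["int", "int"]
  c_mi <- blk$v["mod", "int"]

  a <- b_int^2 - t_crit^2 * v_ii
  b <- 2 * (b_mod * b_int - t_crit^2 * c_mi)
  cc <- b_mod^2 - t_crit^2 * v_mm
  disc <- b^2 - 4 * a * cc

  t_ratio <- function(x) {
    (b_mod + b_int * x) / sqrt(v_mm + 2 * x * c_mi + x^2 * v_ii)
  }

  roots <- numeric(0)
  if (abs(a) > 0 && disc > 0) {
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  } else if (abs(a) <= .Machine$double.eps && abs(b) > 0) {
    roots <- -cc / b
  }
  bounds_sd <- roots / fit$env_sd

  cuts <- sort(unique(c(eval_range, bounds_sd[bounds_sd > eval_range[1] &
                                                bounds_sd < eval_range[2]])))
  mids <- (cuts[-length(cuts)] + cuts[-1]) / 2
  sig <- abs(t_ratio(mids * fit$env_sd)) > t_crit
  intervals <- data.frame(lower = cuts[-length(cuts)], upper = cuts[-1],
                          significant = sig)

  # the non-significance window (SD units): the usual geometry is nonsig
  # between two roots and significant outside; when significance is instead
  # confined between the roots the window is not a single interval and both
  # bounds are NA (the `intervals` table still carries the full story)
  if (length(roots) == 2) {
    if (abs(t_ratio(mean(roots))) <= t_crit) {
      ros_lower <- bounds_sd[1]; ros_upper <- bounds_sd[2]
    } else {
      ros_lower <- NA_real_; ros_upper <- NA_real_
    }
  } else if (length(roots) == 1) {
    if (abs(t_ratio(roots[1] + fit$env_sd)) <= t_crit) {
      ros_lower <- bounds_sd[1]; ros_upper <- Inf
    } else {
      ros_lower <- -Inf; ros_upper <- bounds_sd[1]
    }
  } else {
    everywhere <- abs(t_ratio(mean(eval_range) * fit$env_sd)) > t_crit
    ros_lower <- if (everywhere) NA_real_ else -Inf
    ros_upper <- if (everywhere) NA_real_ else Inf
  }

  # end-point significance: a bound exactly at an edge counts as inside
  sig_at <- function(edge) {
    if (any(abs(bounds_sd - edge) < 1e-12)) return(TRUE)
    abs(t_ratio(edge * fit$env_sd)) > t_crit
  }
  list(bounds_sd = bounds_sd, ros_lower = ros_lower, ros_upper = ros_upper,
       intervals = intervals,
       sig_at_lower = sig_at(eval_range[1]),
       sig_at_upper = sig_at(eval_range[2]),
       diff_sign_lower = sign(b_mod + b_int * eval_range[1] * fit$env_sd),
       diff_sign_upper = sign(b_mod + b_int * eval_range[2] * fit$env_sd),
       t_crit = t_crit, alpha = alpha, eval_range = eval_range)
}

#' Crossover point of the high/low moderator lines
#'
#' The environment value where the two simple-slope lines intersect:
#' `-b_mod / b_int` on centered predictors, reported in environment-SD
#' units from the mean.
#'
#' @param fit a [fit_hierarchical()] result with a nonzero interaction.
#' @return Crossover location in SD units.
#' @export
crossover_point <- function(fit) {
  blk <- interaction_block(fit)
  if (blk$b[["int"]] == 0) {
    rosmod_abort("rosmod_degenerate", "crossover undefined when b_int = 0")
  }
  unname(-blk$b[["mod"]] / blk$b[["int"]] / fit$env_sd)
}

# which side of the crossover is the "vantage" side (where the susceptible
# group is better off)?  +1 = right (higher env), -1 = left.  The group
# difference is linear in env and crosses zero at the crossover, so for
# x > crossover its sign is sign(b_int); relative to the susceptible group
# and the outcome polarity that settles the side globally.
vantage_side <- function(fit, susceptible, outcome_pol) {
  blk <- interaction_block(fit)
  s <- if (susceptible == "high_moderator") 1 else -1
  if (s * blk$b[["int"]] * outcome_pol > 0) 1 else -1
}

#' Proportion-of-interaction (PoI) index
#'
#' Share of the area between the high- and low-moderator regression lines,
#' over `eval_range`, that lies on the side of the crossover where the
#' susceptible group has the better outcome.  For straight lines this is
#' `d_v^2 / (d_v^2 + d_r^2)`, with `d_v`, `d_r` the distances from the
#' crossover to the vantage-side and risk-side edges; a crossover outside
#' the range clamps the index to 0 or 1.  Values near 0.5 indicate a
#' symmetric "for better and for worse" interaction.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param eval_range window in environment-SD units (default `c(-2, 2)`).
#' @param outcome_pol outcome polarity (+1 higher = better); defaults from
#'   the fitted outcome name via [outcome_polarity()].
#' @param susceptible which moderator group is the more responsive one;
#'   defaults to the group with the larger absolute simple slope.
#' @return PoI in `[0, 1]`.
#' @export
poi_index <- function(fit, eval_range = c(-2, 2),
                      outcome_pol = outcome_polarity(fit$outcome),
                      susceptible = NULL) {
  ss <- simple_slopes(fit)
  susceptible <- susceptible %||%
    (if (abs(ss$slope[ss$group == "high"]) >=
         abs(ss$slope[ss$group == "low"])) "high_moderator" else "low_moderator")
  xc <- crossover_point(fit)
  xc_cl <- min(max(xc, eval_range[1]), eval_range[2])
  side <- vantage_side(fit, susceptible, outcome_pol)
  d_right <- eval_range[2] - xc_cl
  d_left <- xc_cl - eval_range[1]
  d_v <- if (side > 0) d_right else d_left
  d_r <- if (side > 0) d_left else d_right
  d_v^2 / (d_v^2 + d_r^2)
}

#' Proportion-affected (PA) index
#'
#' Empirical fraction of the analyzed subjects whose environment score lies
#' on the vantage side of the crossover.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param env_values environment scores of the analyzed sample, on the
#'   scale the model was fitted on (uncentered is fine — the fit's recorded
#'   mean is subtracted).
#' @param outcome_pol,susceptible as in [poi_index()].
#' @return PA in `[0, 1]`.
#' @export
pa_index <- function(fit, env_values,
                     outcome_pol = outcome_polarity(fit$outcome),
                     susceptible = NULL) {
  if (!length(env_values)) {
    rosmod_abort("rosmod_invalid_input", "empty sample")
  }
  ss <- simple_slopes(fit)
  susceptible <- susceptible %||%
    (if (abs(ss$slope[ss$group == "high"]) >=
         abs(ss$slope[ss$group == "low"])) "high_moderator" else "low_moderator")
  xc <- crossover_point(fit)
  side <- vantage_side(fit, susceptible, outcome_pol)
  x_sd <- (env_values - fit$env_mean) / fit$env_sd
  if (side > 0) mean(x_sd > xc) else mean(x_sd < xc)
}

#' Probe one fitted interaction
#'
#' Bundles [simple_slopes()], [jn_region()], [crossover_point()],
#' [poi_index()] and [pa_index()] into a single `probe_result`.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param env_values sample environment scores for the PA index; defaults
#'   to the fitted design's environment column plus the recorded mean.
#' @param alpha significance level (default 0.05).
#' @param eval_range window in environment-SD units (default `c(-2, 2)`).
#' @param outcome_pol outcome polarity; defaulted from the outcome name.
#' @return A `probe_result` list.
#' @export
probe_interaction <- function(fit, env_values = NULL, alpha = 0.05,
                              eval_range = c(-2, 2),
                              outcome_pol = outcome_polarity(fit$outcome)) {
  if (is.null(env_values)) {
    env_values <- fit$design_final[, fit$env] + fit$env_mean
  }
  ss <- simple_slopes(fit)
  susceptible <- if (abs(ss$slope[ss$group == "high"]) >=
                     abs(ss$slope[ss$group == "low"]))
    "high_moderator" else "low_moderator"
  ros <- jn_region(fit, alpha = alpha, eval_range = eval_range)
  structure(list(
    outcome = fit$outcome, env = fit$env,
    slopes = ss,
    crossover_x = crossover_point(fit),
    ros = ros,
    ros_lower = ros$ros_lower, ros_upper = ros$ros_upper,
    eval_range = eval_range,
    poi = poi_index(fit, eval_range, outcome_pol, susceptible),
    pa = pa_index(fit, env_values, outcome_pol, susceptible),
    susceptible_group = susceptible,
    alpha = alpha
  ), class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf(
    "<probe_result> %s ~ %s: slopes %.3f (high) / %.3f (low); crossover %.3f SD;\n  RoS nonsig (%.3f, %.3f) SD; PoI %.2f; PA %.2f; susceptible: %s\n",
    x$outcome, x$env, x$slopes$slope[x$slopes$group == "high"],
    x$slopes$slope[x$slopes$group == "low"], x$crossover_x,
    x$ros_lower, x$ros_upper, x$poi, x$pa, x$susceptible_group))
  invisible(x)
}

#' Classify an interaction against the three theoretical models
#'
#' Default rules: a non-significant interaction (p >= `alpha`) is `"none"`.
#' Otherwise the verdict follows the region-of-significance sidedness over
#' `eval_range`: a group difference significant at both the supportive and
#' adverse ends *with the group ordering reversing across the crossover*
#' ("for better and for worse") is `"differential_susceptibility"`;
#' significant only toward the supportive end, `"vantage_sensitivity"`;
#' only toward the adverse end, `"diathesis_stress"`; at neither end — or
#' at both ends with one group uniformly ahead — `"none"`.  Supportive/adverse ends
#' are resolved from the environment polarity (for an adverse-coded scale
#' such as psychological demands the supportive end is -2 SD).  PoI and PA
#' ride along as descriptive diagnostics; an optional gate restricting
#' differential susceptibility to PoI within `[0.40, 0.60]` can be enabled
#' with `rules$poi_gate = TRUE`.
#'
#' @param probe a [probe_interaction()] result.
#' @param interaction_p final-step p-value of the interaction term.
#' @param env_pol environment polarity (+1 higher = supportive); defaulted
#'   from the probe's environment name.
#' @param alpha significance level (default the probe's).
#' @param rules list of rule switches; currently `poi_gate` (default off).
#' @return A `pattern_classification` list: `label`, `susceptible_group`,
#'   `sig_supportive_end`, `sig_adverse_end`, `probe`, `interaction_p`.
#' @export
classify_pattern <- function(probe, interaction_p,
                             env_pol = env_polarity(probe$env),
                             alpha = probe$alpha,
                             rules = list(poi_gate = FALSE)) {
  stopifnot(inherits(probe, "probe_result"))
  if (!env_pol %in% c(-1, 1)) {
    rosmod_abort("rosmod_missing_polarity", "env_pol must be +1 or -1")
  }
  sig_upper <- probe$ros$sig_at_upper
  sig_lower <- probe$ros$sig_at_lower
  sig_supportive <- if (env_pol > 0) sig_upper else sig_lower
  sig_adverse <- if (env_pol > 0) sig_lower else sig_upper
  # "for better and for worse" requires the group ordering to reverse
  # across the crossover, not merely significance at both ends
  reverses <- probe$ros$diff_sign_lower * probe$ros$diff_sign_upper < 0

  label <- if (interaction_p >= alpha) {
    "none"
  } else if (sig_supportive && sig_adverse && reverses) {
    "differential_susceptibility"
  } else if (sig_supportive && sig_adverse) {
    "none"   # both ends significant with one group uniformly ahead
  } else if (sig_supportive) {
    "vantage_sensitivity"
  } else if (sig_adverse) {
    "diathesis_stress"
  } else {
    "none"
  }
  if (label == "differential_susceptibility" && isTRUE(rules$poi_gate) &&
      (probe$poi < 0.40 || probe$poi > 0.60)) {
    label <- "none"
  }
  structure(list(
    label = label,
    susceptible_group = probe$susceptible_group,
    sig_supportive_end = sig_supportive,
    sig_adverse_end = sig_adverse,
    env_polarity = env_pol,
    interaction_p = interaction_p,
    alpha = alpha,
    probe = probe
  ), class = "pattern_classification")
}

#' @export
print.pattern_classification <- function(x, ...) {
  cat(sprintf(
    "<pattern_classification> %s ~ %s: %s (interaction p = %.4f; susceptible: %s)\n",
    x$probe$outcome, x$probe$env, x$label, x$interaction_p,
    x$susceptible_group))
  invisible(x)
}

#' Plot data for a probed interaction
#'
#' Grid of predicted outcomes at moderator M +/- 1 SD over the evaluation
#' range, with the group-difference t-ratio and a significance flag —
#' sufficient to redraw the shaded region-of-significance figures.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param alpha significance level.
#' @param eval_range window in SD units.
#' @param points grid size.
#' @return A data.frame: `env_sd`, `pred_high`, `pred_low`, `diff_t`,
#'   `significant`.
#' @export
probe_grid <- function(fit, alpha = 0.05, eval_range = c(-2, 2),
                       points = 201L) {
  blk <- interaction_block(fit)
  t_crit <- stats::qt(1 - alpha / 2, fit$df_resid)
  b0 <- fit$coefficients$B[fit$coefficients$term == "(Intercept)"]
  xs <- seq(eval_range[1], eval_range[2], length.out = points)
  x_raw <- xs * fit$env_sd
  pred <- function(z) {
    b0 + blk$b[["env"]] * x_raw + blk$b[["mod"]] * z +
      blk$b[["int"]] * x_raw * z
  }
  tt <- (blk$b[["mod"]] + blk$b[["int"]] * x_raw) /
    sqrt(blk$v["mod", "mod"] + 2 * x_raw * blk$v["mod", "int"] +
           x_raw^2 * blk$v["int", "int"])
  data.frame(env_sd = xs,
             pred_high = pred(fit$mod_sd),
             pred_low = pred(-fit$mod_sd),
             diff_t = tt,
             significant = abs(tt) > t_crit)
}
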