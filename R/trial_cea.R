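#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Divides the incremental cost by the incremental effect and classifies
#' the result on the cost-effectiveness plane: the intervention *dominates*
#' when it is less costly and more effective, is *dominated* when it is
#' more costly and less effective, and yields an undefined ratio when the
#' effect difference is exactly zero.
#'
#' @param delta_cost Incremental cost (pounds), intervention minus
#'   comparator.
#' @param delta_qaly Incremental effect (QALYs).
#' @return An object of class `icer_estimate`: list with `icer` (pounds
#'   per QALY, `NA` when undefined), `classification`, `delta_cost`,
#'   `delta_qaly`.
#' @examples
#' icer(11, 0.010) # £1100 per QALY gained
#' icer(-96, 0.003) # intervention dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (delta_qaly == 0) {
    cls <- "undefined (no difference in effect)"
    ratio <- NA_real_
  } else {
    ratio <- delta_cost / delta_qaly
    cls <- if (delta_cost < 0 && delta_qaly > 0) {
      "dominant (less costly, more effective)"
    } else if (delta_cost > 0 && delta_qaly < 0) {
      "dominated (more costly, less effective)"
    } else if (delta_qaly > 0) {
      "cost per QALY gained"
    } else {
      "cost saved per QALY forgone"
    }
  }
  structure(
    list(
      icer = ratio, classification = cls,
      delta_cost = delta_cost, delta_qaly = delta_qaly
    ),
    class = "icer_estimate"
  )
}

#' @export
print.icer_estimate <- function(x, ...) {
  cat(sprintf(
    "Incremental cost £%.2f, incremental QALYs %.4f\n",
    x$delta_cost, x$delta_qaly
  ))
  if (is.na(x$icer)) {
    cat(sprintf("ICER: %s\n", x$classification))
  } else {
    cat(sprintf("ICER: £%.2f per QALY (%s)\n", x$icer, x$classification))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of replicates with
#' positive net monetary benefit, `lambda * delta_qaly - delta_cost > 0`.
#' Replicates may come from a non-parametric bootstrap of a trial
#' ([bootstrap_cea()]) or from a probabilistic sensitivity analysis
#' ([run_psa()]).
#'
#' @param replicates Data frame with columns `delta_cost` and
#'   `delta_qaly` (one row per replicate).
#' @param thresholds Numeric vector of willingness-to-pay thresholds
#'   (pounds per QALY).
#' @return Data frame with columns `threshold` and `probability`.
#' @examples
#' reps <- data.frame(delta_cost = c(10, -10), delta_qaly = c(0.001, 0.001))
#' ceac(reps, thresholds = c(0, 20000))
#' @export
ceac <- function(replicates, thresholds = c(20000, 30000)) {
  stopifnot(
    is.data.frame(replicates), nrow(replicates) > 0,
    all(c("delta_cost", "delta_qaly") %in% names(replicates)),
    all(is.finite(thresholds)), all(thresholds >= 0)
  )
  prob <- vapply(thresholds, function(lambda) {
    mean(lambda * replicates$delta_qaly - replicates$delta_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Covariate adjustment specification for the within-trial analysis
#'
#' Defines the outcome and adjustment covariates of the generalized linear
#' regressions used for the incremental analysis. The cost model adjusts
#' for baseline (pre-trial) costs to the health service; the QALY model
#' adjusts for baseline utility; both additionally adjust for age, gender,
#' study site, entitlement to free prescriptions and baseline cigarette
#' dependence (FTCD). The treatment-arm indicator is always included; its
#' coefficient is the adjusted incremental estimate.
#'
#' @param outcome `"total_cost"` or `"qaly"`.
#' @param covariates Character vector of adjustment covariates; defaults
#'   depend on the outcome.
#' @return An object of class `adjustment_spec`.
#' @export
adjustment_spec <- function(outcome = c("total_cost", "qaly"),
                            covariates = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(covariates)) {
    baseline <- if (outcome == "total_cost") "baseline_cost" else "utility_0"
    covariates <- c(baseline, "age", "male", "site", "free_rx", "ftcd")
  }
  structure(list(outcome = outcome, covariates = covariates),
    class = "adjustment_spec"
  )
}

spec_formula <- function(spec) {
  stats::reformulate(c("arm", spec$covariates), response = spec$outcome)
}

#' Derive analysis variables for the within-trial CEA
#'
#' Adds to a participant table the variables the incremental analysis
#' models: per-participant treatment cost (from the session/product log),
#' total 12-month cost to the health service (treatment + smoking
#' cessation help + healthcare use), baseline 6-month cost, and QALYs by
#' area under the utility curve. QALYs are `NA` until the utilities are
#' complete, so imputation (see [mice_pmm()]) normally runs first.
#'
#' @param data A `trial_dataset`, or a participant data frame.
#' @param unit_costs A [unit_cost_table()].
#' @param training_cost_pp Named vector of per-participant training cost
#'   by arm.
#' @return The participant data frame with columns `treatment_cost`,
#'   `total_cost`, `baseline_cost` and `qaly` appended.
#' @export
prepare_cea_data <- function(data, unit_costs = unit_cost_table(),
                             training_cost_pp = c(NRT = 0, EC = 4.40)) {
  df <- participant_frame(data)
  df$treatment_cost <- treatment_cost(df, unit_costs, training_cost_pp)
  df$baseline_cost <- df$cost_cessation_baseline + df$cost_healthcare_baseline
  df$total_cost <- df$treatment_cost +
    df$cost_cessation_0_6 + df$cost_cessation_6_12 +
    df$cost_healthcare_0_6 + df$cost_healthcare_6_12
  df$qaly <- qaly_auc(df$utility_0, df$utility_6, df$utility_12,
    .allow_na = TRUE
  )
  df
}

# fit one adjusted model and pull out the arm effect
fit_adjusted <- function(df, spec, family) {
  if (length(unique(df$arm)) < 2) {
    stop("adjusted_difference() needs both treatment arms in the data")
  }
  f <- spec_formula(spec)
  fit <- stats::glm(f, data = df, family = family)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop(
      "collinear covariates dropped from the adjustment model: ",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    )
  }
  arm_term <- grep("^arm", names(cf), value = TRUE)[1]
  est <- cf[[arm_term]]
  se <- sqrt(diag(stats::vcov(fit))[[arm_term]])
  list(estimate = est, variance = se^2, df = stats::df.residual(fit))
}

#' Regression-adjusted incremental cost or effect
#'
#' Estimates the between-arm difference in the outcome named by `spec` by
#' a generalized linear regression adjusting for the specification's
#' covariates; the treatment-arm coefficient is the adjusted incremental
#' estimate. When `data` is a list of multiply imputed completed datasets
#' (from [mice_pmm()]), the model is fitted on each and the estimates are
#' pooled by Rubin's rules ([pool_rubin()]).
#'
#' @param data A complete participant data frame (after
#'   [prepare_cea_data()]), or a `mice_result` / list of completed data
#'   frames.
#' @param spec An [adjustment_spec()].
#' @param family GLM family; the default identity-link gaussian makes the
#'   arm coefficient an adjusted mean difference on the outcome's own
#'   scale.
#' @param conf_level Confidence level for the interval.
#' @return List with `estimate`, `se`, `ci` (length-2 vector), `df`, and
#'   for imputed input the full `pooled_estimate`.
#' @export
adjusted_difference <- function(data, spec, family = stats::gaussian(),
                                conf_level = 0.95) {
  stopifnot(inherits(spec, "adjustment_spec"))
  if (inherits(data, "mice_result")) data <- data$imputations
  if (is.data.frame(data)) {
    one <- fit_adjusted(data, spec, family)
    alpha <- 1 - conf_level
    half <- stats::qt(1 - alpha / 2, one$df) * sqrt(one$variance)
    return(list(
      estimate = one$estimate, se = sqrt(one$variance),
      ci = c(one$estimate - half, one$estimate + half), df = one$df
    ))
  }
  fits <- lapply(data, fit_adjusted, spec = spec, family = family)
  pooled <- pool_rubin(
    vapply(fits, `[[`, numeric(1), "estimate"),
    vapply(fits, `[[`, numeric(1), "variance"),
    conf_level = conf_level
  )
  list(
    estimate = pooled$estimate, se = sqrt(pooled$total_variance),
    ci = c(pooled$ci_low, pooled$ci_high), df = pooled$df,
    pooled = pooled
  )
}

# one bootstrap replicate: stratified-by-arm resample, refit both models
boot_replicate <- function(df, spec_cost, spec_qaly, family, idx = NULL) {
  if (is.null(idx)) {
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$arm), function(i) {
      sample(i, length(i), replace = TRUE)
    }), use.names = FALSE)
  }
  d <- df[idx, , drop = FALSE]
  c(
    delta_cost = fit_adjusted(d, spec_cost, family)$estimate,
    delta_qaly = fit_adjusted(d, spec_qaly, family)$estimate
  )
}

#' Non-parametric bootstrap of the incremental analysis
#'
#' Resamples participants with replacement within each arm (keeping the
#' original per-arm sample sizes), re-estimates the adjusted incremental
#' cost and QALY models on each replicate sample, and returns the cloud of
#' replicate pairs for the cost-effectiveness plane and acceptability
#' curve. With multiply imputed input, replicate `b` is estimated on the
#' completed dataset `((b - 1) mod m) + 1`, cycling through the
#' imputations so that imputation uncertainty enters the cloud.
#'
#' @param data A complete participant data frame (after
#'   [prepare_cea_data()]), or a `mice_result` / list of completed data
#'   frames whose rows align across imputations.
#' @param spec_cost,spec_qaly [adjustment_spec()]s for the cost and QALY
#'   models.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param family GLM family passed to the adjustment models.
#' @return Data frame with `n_boot` rows and columns `delta_cost`,
#'   `delta_qaly`.
#' @export
bootstrap_cea <- function(data,
                          spec_cost = adjustment_spec("total_cost"),
                          spec_qaly = adjustment_spec("qaly"),
                          n_boot = 5000, seed = NULL,
                          family = stats::gaussian()) {
  if (inherits(data, "mice_result")) data <- data$imputations
  if (is.data.frame(data)) data <- list(data)
  m <- length(data)
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    boot_replicate(data[[(b - 1) %% m + 1]], spec_cost, spec_qaly, family)
  }, numeric(2))
  out <- as.data.frame(t(reps))
  names(out) <- c("delta_cost", "delta_qaly")
  out
}

#' Within-trial cost-effectiveness analysis
#'
#' Convenience orchestrator for the 12-month incremental analysis on a
#' (possibly multiply imputed) participant table: adjusted incremental
#' cost and QALYs, their ICER, a stratified bootstrap replicate cloud and
#' the acceptability curve.
#'
#' @param data Complete participant data frame from [prepare_cea_data()],
#'   or a list of completed datasets (each already prepared).
#' @param n_boot Bootstrap replicates.
#' @param thresholds Willingness-to-pay thresholds for the CEAC.
#' @param seed Optional integer seed for the bootstrap.
#' @param family GLM family for the adjustment models.
#' @return An object of class `cea_result`: list with `delta_cost`,
#'   `delta_qaly` (each with `estimate`/`ci`), `icer`, `replicates`,
#'   `ceac`.
#' @export
run_trial_cea <- function(data, n_boot = 5000,
                          thresholds = c(20000, 30000), seed = NULL,
                          family = stats::gaussian()) {
  spec_cost <- adjustment_spec("total_cost")
  spec_qaly <- adjustment_spec("qaly")
  dcost <- adjusted_difference(data, spec_cost, family)
  dqaly <- adjusted_difference(data, spec_qaly, family)
  reps <- bootstrap_cea(data, spec_cost, spec_qaly,
    n_boot = n_boot,
    seed = seed, family = family
  )
  structure(
    list(
      delta_cost = dcost, delta_qaly = dqaly,
      icer = icer(dcost$estimate, dqaly$estimate),
      replicates = reps, ceac = ceac(reps, thresholds)
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Within-trial incremental cost-effectiveness analysis\n")
  cat(sprintf(
    "  adjusted incremental cost:  £%.2f (95%% CI £%.2f to £%.2f)\n",
    x$delta_cost$estimate, x$delta_cost$ci[1], x$delta_cost$ci[2]
  ))
  cat(sprintf(
    "  adjusted incremental QALYs: %.4f (95%% CI %.4f to %.4f)\n",
    x$delta_qaly$estimate, x$delta_qaly$ci[1], x$delta_qaly$ci[2]
  ))
  if (is.na(x$icer$icer)) {
    cat(sprintf("  ICER: %s\n", x$icer$classification))
  } else {
    cat(sprintf(
      "  ICER: £%.0f per QALY (%s)\n", x$icer$icer, x$icer$classification
    ))
  }
  for (i in seq_len(nrow(x$ceac))) {
    cat(sprintf(
      "  P(cost-effective at £%s/QALY) = %.3f  [%d bootstrap replicates]\n",
      format(x$ceac$threshold[i], big.mark = ","), x$ceac$probability[i],
      nrow(x$replicates)
    ))
  }
  invisible(x)
}

#' Complete-case subset for the sensitivity analysis
#'
#' Rows complete on every variable entering the two adjustment models,
#' mirroring a complete-case re-analysis alongside the imputed primary
#' analysis.
#'
#' @param df Prepared participant data frame (see [prepare_cea_data()]).
#' @return The complete-case subset of `df`.
#' @export
complete_cases_cea <- function(df) {
  vars <- unique(c(
    "arm", adjustment_spec("total_cost")$covariates, "total_cost",
    adjustment_spec("qaly")$covariates, "qaly"
  ))
  df[stats::complete.cases(df[, vars]), , drop = FALSE]
}
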