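#' Moment-matched parameter distribution
#'
#' Maps a (mean, standard error) pair onto the distribution family
#' conventionally assigned to that parameter type in probabilistic
#' sensitivity analysis: beta for probabilities, gamma for costs and
#' QALY weights. Parameters are recovered by the method of moments:
#' for the beta, `alpha = m * k`, `beta = (1 - m) * k` with
#' `k = m (1 - m) / s^2 - 1`; for the gamma, `shape = m^2 / s^2`,
#' `rate = m / s^2`. A zero standard error yields a degenerate
#' distribution fixed at the mean.
#'
#' @param mean Parameter mean. Must lie in (0, 1) for the beta family and
#'   be positive for the gamma family.
#' @param se Standard error (standard deviation of the parameter
#'   distribution); non-negative.
#' @param family `"beta"`, `"gamma"`, or `"degenerate"`.
#' @param name Optional parameter label carried through for reporting.
#' @return An object of class `param_distribution`.
#' @examples
#' moment_match(0.5, 0.1, "beta") # alpha = beta = 12
#' moment_match(4, 2, "gamma") # shape = 4, rate = 1
#' @export
moment_match <- function(mean, se, family = c("beta", "gamma", "degenerate"),
                         name = NULL) {
  family <- match.arg(family)
  stopifnot(is.finite(mean), is.finite(se), se >= 0)
  if (se == 0) family <- "degenerate"
  out <- list(name = name, family = family, mean = mean, se = se)
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) stop("beta family requires mean in (0, 1)")
    v <- se^2
    if (v >= mean * (1 - mean)) {
      stop(sprintf(
        "infeasible beta moments%s: variance %.3g >= mean*(1-mean) = %.3g",
        if (is.null(name)) "" else paste0(" for '", name, "'"),
        v, mean * (1 - mean)
      ))
    }
    k <- mean * (1 - mean) / v - 1
    out$shape1 <- mean * k
    out$shape2 <- (1 - mean) * k
  } else if (family == "gamma") {
    if (mean <= 0) stop("gamma family requires a positive mean")
    out$shape <- mean^2 / se^2
    out$rate <- mean / se^2
  }
  structure(out, class = "param_distribution")
}

#' @export
print.param_distribution <- function(x, ...) {
  lab <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  par <- switch(x$family,
    beta = sprintf("alpha = %.4g, beta = %.4g", x$shape1, x$shape2),
    gamma = sprintf("shape = %.4g, rate = %.4g", x$shape, x$rate),
    degenerate = sprintf("fixed at %.4g", x$mean)
  )
  cat(sprintf(
    "%s distribution%s: mean %.4g, se %.4g (%s)\n",
    x$family, lab, x$mean, x$se, par
  ))
  invisible(x)
}

#' Draw from a moment-matched parameter distribution
#'
#' @param dist A `param_distribution` from [moment_match()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; degenerate distributions return
#'   the mean exactly.
#' @export
draw_param <- function(dist, n) {
  stopifnot(inherits(dist, "param_distribution"))
  switch(dist$family,
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    degenerate = rep(dist$mean, n)
  )
}

# draw all model parameters for a PSA: arm-shared parameters (relapse,
# mortality, annual costs and utilities) are drawn once and reused for both
# arms (common random numbers), arm-specific parameters per arm.
draw_psa_parameters <- function(inputs, n, vary_quit_rates = TRUE) {
  band_draws <- function(tab, family) {
    lapply(stats::setNames(c("male", "female"), c("male", "female")), function(sx) {
      sub <- tab[tab$sex == sx, ]
      sub <- sub[order(sub$age_min), ]
      draw_cols <- function(m, s) {
        vapply(seq_along(m), function(b) {
          draw_param(moment_match(m[b], s[b], family), n)
        }, numeric(n))
      }
      list(
        smoker = draw_cols(sub$smoker, sub$smoker_se),
        ex_smoker = draw_cols(sub$ex_smoker, sub$ex_smoker_se)
      )
    })
  }
  shared <- list(
    relapse = draw_param(
      moment_match(inputs$relapse_prob, inputs$relapse_prob_se, "beta",
        name = "relapse_prob"
      ), n
    ),
    mort = band_draws(inputs$mortality, "beta"),
    cost = band_draws(inputs$annual_cost, "gamma"),
    util = band_draws(inputs$annual_utility, "gamma")
  )
  per_arm <- lapply(stats::setNames(c("NRT", "EC"), c("NRT", "EC")), function(arm) {
    quit <- if (vary_quit_rates) {
      draw_param(moment_match(inputs$quit_rate[[arm]],
        inputs$quit_rate_se[[arm]], "beta",
        name = paste0("quit_rate_", arm)
      ), n)
    } else {
      rep(inputs$quit_rate[[arm]], n)
    }
    c(
      list(
        quit = quit,
        death1 = rep(inputs$first_cycle_death_prob[[arm]], n),
        fc_cost = draw_param(moment_match(inputs$first_cycle_cost[[arm]],
          inputs$first_cycle_cost_se[[arm]], "gamma",
          name = paste0("first_cycle_cost_", arm)
        ), n),
        fc_qaly = draw_param(moment_match(inputs$first_cycle_qaly[[arm]],
          inputs$first_cycle_qaly_se[[arm]], "gamma",
          name = paste0("first_cycle_qaly_", arm)
        ), n)
      ),
      shared
    )
  })
  per_arm
}

#' Probabilistic sensitivity analysis of the lifetime model
#'
#' Propagates parameter uncertainty through the three-state lifetime
#' cohort model by Monte Carlo simulation. Each iteration draws one value
#' per uncertain parameter — beta distributions for probabilities
#' (relapse, annual mortality, and by default the one-year quit rates) and
#' gamma distributions for costs and QALY weights (annual utilities,
#' first-cycle trial costs and QALYs), all moment-matched to their
#' mean/SE — runs both arms with identical draws for the parameters the
#' arms share (common random numbers), and records the incremental
#' discounted lifetime cost and QALYs. Annual cost inputs with a zero
#' standard error stay fixed.
#'
#' @param inputs A [lifetime_inputs()] object.
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Optional integer seed; the full run is reproducible from it.
#' @param thresholds Willingness-to-pay thresholds (pounds per QALY) at
#'   which the acceptability curve is evaluated.
#' @param vary_quit_rates Draw the one-year quit rates from beta
#'   distributions matched to their trial means/SEs (default), or hold
#'   them fixed.
#' @return An object of class `psa_result`: list with `draws` (data frame
#'   of per-iteration arm costs/QALYs and increments), `ceac` (data frame
#'   `threshold`, `probability`), `means`, `icer_of_means`, `n_iterations`
#'   and `seed`.
#' @examples
#' psa <- run_psa(lifetime_inputs(), n_iterations = 200, seed = 1)
#' psa$ceac
#' @export
run_psa <- function(inputs, n_iterations = 10000, seed = NULL,
                    thresholds = c(20000, 30000), vary_quit_rates = TRUE) {
  stopifnot(inherits(inputs, "lifetime_inputs"), n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  par <- draw_psa_parameters(inputs, n_iterations, vary_quit_rates)
  res <- lapply(par, function(p) cohort_engine(inputs, p, n_iterations))
  N <- inputs$cohort_size
  draws <- data.frame(
    cost_NRT = res$NRT$cost / N, qaly_NRT = res$NRT$qaly / N,
    cost_EC = res$EC$cost / N, qaly_EC = res$EC$qaly / N
  )
  draws$delta_cost <- draws$cost_EC - draws$cost_NRT
  draws$delta_qaly <- draws$qaly_EC - draws$qaly_NRT
  means <- colMeans(draws)
  structure(
    list(
      draws = draws,
      ceac = ceac(draws, thresholds),
      means = means,
      icer_of_means = icer(means[["delta_cost"]], means[["delta_qaly"]]),
      n_iterations = n_iterations,
      seed = seed
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d iterations\n", x$n_iterations
  ))
  cat(sprintf(
    "  mean lifetime cost/QALYs: NRT £%.0f / %.2f, EC £%.0f / %.2f\n",
    x$means[["cost_NRT"]], x$means[["qaly_NRT"]],
    x$means[["cost_EC"]], x$means[["qaly_EC"]]
  ))
  cat(sprintf(
    "  mean increments (EC - NRT): £%.1f, %.4f QALYs\n",
    x$means[["delta_cost"]], x$means[["delta_qaly"]]
  ))
  for (i in seq_len(nrow(x$ceac))) {
    cat(sprintf(
      "  P(cost-effective at £%s/QALY) = %.3f\n",
      format(x$ceac$threshold[i], big.mark = ","), x$ceac$probability[i]
    ))
  }
  invisible(x)
}
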