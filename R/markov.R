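#' Lifetime Markov model inputs
#'
#' Bundles every input of the three-state (smoker / ex-smoker / dead)
#' lifetime cohort model: first-cycle allocation and accruals taken from a
#' two-arm cessation trial, and the literature-based annual transition
#' probabilities, smoking-attributable healthcare costs and utility weights
#' by sex, age band and smoking status that drive all later cycles.
#'
#' The default values describe a cohort of 1000 smokers entering at age 41
#' (52% male) after a quit attempt with either nicotine replacement therapy
#' (`NRT`) or an e-cigarette starter kit (`EC`): one-year quit rates of 9.9%
#' and 18.0%, first-cycle per-person costs of £1116/£1174 and QALYs of
#' 0.882/0.886, an annual relapse probability of 10% for the ten years after
#' the quit year (abstinence permanent thereafter), and sex- and
#' age-banded annual mortality, smoking-attributable secondary-care costs
#' and utility weights for continuing smokers and ex-smokers.
#'
#' Costs are discounted at 3.5% per year beyond the first cycle; the default
#' QALY discount rate is 0, which is the convention under which the model
#' reproduces its reference lifetime QALY results (see the methods
#' vignette). Both rates are configurable.
#'
#' @param cohort_size Number of persons entering the model.
#' @param entry_age Age (years) at entry; the first cycle is the trial year.
#' @param horizon_age Age attained in the final modelled cycle.
#' @param male_fraction Proportion of the cohort that is male; male and
#'   female sub-cohorts run with sex-specific inputs and are combined.
#' @param quit_rate Named vector (`NRT`, `EC`) of one-year sustained quit
#'   probabilities used to allocate the cohort at the end of cycle 1.
#' @param quit_rate_se Standard errors of `quit_rate` (used by the PSA).
#' @param first_cycle_death_prob Named vector of first-cycle death
#'   probabilities (trial deaths / randomised per arm).
#' @param first_cycle_cost,first_cycle_cost_se Named vectors: mean (SE)
#'   per-person total cost accrued in cycle 1, in pounds.
#' @param first_cycle_qaly,first_cycle_qaly_se Named vectors: mean (SE)
#'   per-person QALYs accrued in cycle 1.
#' @param relapse_prob,relapse_prob_se Annual probability (SE) that an
#'   ex-smoker relapses to smoking.
#' @param relapse_years Number of cycles after cycle 1 in which relapse
#'   applies; afterwards abstinence is permanent.
#' @param mortality,annual_cost,annual_utility Data frames with columns
#'   `sex` (`"male"`/`"female"`), `age_min` (lower bound of the age band:
#'   35, 45, 55, 65, 75), `smoker`, `smoker_se`, `ex_smoker`,
#'   `ex_smoker_se`: annual death probability, annual smoking-attributable
#'   healthcare cost (pounds) and annual utility weight by status.
#' @param discount_rate_cost,discount_rate_qaly Annual discount rates
#'   applied beyond the first cycle.
#' @return An object of class `lifetime_inputs`.
#' @seealso [run_cohort()], [lifetime_icer()], [run_psa()],
#'   [read_lifetime_inputs()]
#' @examples
#' inp <- lifetime_inputs()
#' tr <- run_cohort(inp, arm = "EC")
#' summary(tr)
#' @export
lifetime_inputs <- function(cohort_size = 1000,
                            entry_age = 41,
                            horizon_age = 90,
                            male_fraction = 0.52,
                            quit_rate = c(NRT = 0.099, EC = 0.180),
                            quit_rate_se = c(NRT = 0.014, EC = 0.017),
                            first_cycle_death_prob = c(NRT = 1 / 447, EC = 1 / 439),
                            first_cycle_cost = c(NRT = 1116, EC = 1174),
                            first_cycle_cost_se = c(NRT = 163, EC = 147),
                            first_cycle_qaly = c(NRT = 0.882, EC = 0.886),
                            first_cycle_qaly_se = c(NRT = 0.009, EC = 0.008),
                            relapse_prob = 0.10,
                            relapse_prob_se = 0.0306,
                            relapse_years = 10,
                            mortality = default_mortality_table(),
                            annual_cost = default_annual_cost_table(),
                            annual_utility = default_annual_utility_table(),
                            discount_rate_cost = 0.035,
                            discount_rate_qaly = 0) {
  x <- structure(
    list(
      cohort_size = cohort_size, entry_age = entry_age,
      horizon_age = horizon_age, male_fraction = male_fraction,
      quit_rate = quit_rate, quit_rate_se = quit_rate_se,
      first_cycle_death_prob = first_cycle_death_prob,
      first_cycle_cost = first_cycle_cost,
      first_cycle_cost_se = first_cycle_cost_se,
      first_cycle_qaly = first_cycle_qaly,
      first_cycle_qaly_se = first_cycle_qaly_se,
      relapse_prob = relapse_prob, relapse_prob_se = relapse_prob_se,
      relapse_years = relapse_years,
      mortality = mortality, annual_cost = annual_cost,
      annual_utility = annual_utility,
      discount_rate_cost = discount_rate_cost,
      discount_rate_qaly = discount_rate_qaly
    ),
    class = "lifetime_inputs"
  )
  validate_lifetime_inputs(x)
}

validate_lifetime_inputs <- function(x) {
  stopifnot(
    is.numeric(x$cohort_size), x$cohort_size > 0,
    x$horizon_age > x$entry_age,
    x$male_fraction >= 0, x$male_fraction <= 1,
    all(x$quit_rate >= 0 & x$quit_rate <= 1),
    all(x$first_cycle_death_prob >= 0 & x$first_cycle_death_prob <= 1),
    x$relapse_prob >= 0, x$relapse_prob <= 1,
    x$relapse_years >= 0,
    x$discount_rate_cost >= 0, x$discount_rate_qaly >= 0
  )
  for (nm in c("mortality", "annual_cost", "annual_utility")) {
    tab <- x[[nm]]
    need <- c("sex", "age_min", "smoker", "smoker_se", "ex_smoker", "ex_smoker_se")
    if (!all(need %in% names(tab))) {
      stop(sprintf("'%s' must have columns: %s", nm, paste(need, collapse = ", ")))
    }
    if (!setequal(unique(tab$sex), c("male", "female"))) {
      stop(sprintf("'%s' must cover both sexes", nm))
    }
  }
  if (any(x$mortality$smoker < 0 | x$mortality$smoker > 1)) {
    stop("mortality probabilities must lie in [0, 1]")
  }
  if (any(x$mortality$ex_smoker > x$mortality$smoker)) {
    stop("ex-smoker mortality must not exceed smoker mortality within a band")
  }
  if (any(x$annual_utility$ex_smoker < x$annual_utility$smoker)) {
    stop("ex-smoker utility must not be below smoker utility within a band")
  }
  if (any(x$annual_cost$smoker < 0 | x$annual_cost$ex_smoker < 0)) {
    stop("annual costs must be non-negative")
  }
  x
}

#' @export
print.lifetime_inputs <- function(x, ...) {
  cat("Lifetime cohort model inputs\n")
  cat(sprintf(
    "  cohort: %d persons entering at age %d (%.0f%% male), horizon age %d\n",
    x$cohort_size, x$entry_age, 100 * x$male_fraction, x$horizon_age
  ))
  cat(sprintf(
    "  quit rates: NRT %.1f%%, EC %.1f%%; relapse %.1f%%/year for %d years\n",
    100 * x$quit_rate[["NRT"]], 100 * x$quit_rate[["EC"]],
    100 * x$relapse_prob, x$relapse_years
  ))
  cat(sprintf(
    "  first cycle: cost £%.0f/£%.0f, QALY %.3f/%.3f (NRT/EC)\n",
    x$first_cycle_cost[["NRT"]], x$first_cycle_cost[["EC"]],
    x$first_cycle_qaly[["NRT"]], x$first_cycle_qaly[["EC"]]
  ))
  cat(sprintf(
    "  discounting: costs %.1f%%, QALYs %.1f%% per year beyond cycle 1\n",
    100 * x$discount_rate_cost, 100 * x$discount_rate_qaly
  ))
  invisible(x)
}

band_table <- function(sex, smoker, smoker_se, ex, ex_se) {
  data.frame(
    sex = sex, age_min = c(35, 45, 55, 65, 75),
    smoker = smoker, smoker_se = smoker_se,
    ex_smoker = ex, ex_smoker_se = ex_se
  )
}

#' @rdname lifetime_inputs
#' @export
default_mortality_table <- function() {
  rbind(
    band_table("male",
      smoker = c(0.0024, 0.0080, 0.0194, 0.0515, 0.2536),
      smoker_se = c(0.0040, 0.0040, 0.0052, 0.0082, 0.0204),
      ex = c(0.0018, 0.0051, 0.0124, 0.0308, 0.1512),
      ex_se = c(0.0035, 0.0073, 0.0058, 0.0059, 0.0114)
    ),
    band_table("female",
      smoker = c(0.0014, 0.0053, 0.0130, 0.0345, 0.2079),
      smoker_se = c(0.0031, 0.0033, 0.0043, 0.0068, 0.0190),
      ex = c(0.0011, 0.0034, 0.0083, 0.0206, 0.1240),
      ex_se = c(0.0027, 0.0059, 0.0048, 0.0049, 0.0105)
    )
  )
}

#' @rdname lifetime_inputs
#' @export
default_annual_cost_table <- function() {
  rbind(
    band_table("male",
      smoker = c(54.48, 54.48, 181.97, 315.75, 535.22),
      smoker_se = c(0, 0, 0, 0, 0),
      ex = c(16.57, 16.57, 64.99, 83.82, 105.36),
      ex_se = c(0, 0, 0, 0, 0)
    ),
    band_table("female",
      smoker = c(41.31, 41.31, 119.83, 249.03, 470.69),
      smoker_se = c(0, 0, 0, 0, 0),
      ex = c(10.72, 10.72, 40.95, 71.25, 103.18),
      ex_se = c(0, 0, 0, 0, 0)
    )
  )
}

#' @rdname lifetime_inputs
#' @export
default_annual_utility_table <- function() {
  rbind(
    band_table("male",
      smoker = c(0.889, 0.841, 0.780, 0.756, 0.710),
      smoker_se = c(0.007, 0.007, 0.008, 0.008, 0.009),
      ex = c(0.908, 0.861, 0.803, 0.781, 0.737),
      ex_se = c(0.005, 0.005, 0.005, 0.006, 0.006)
    ),
    band_table("female",
      smoker = c(0.870, 0.830, 0.763, 0.751, 0.676),
      smoker_se = c(0.007, 0.007, 0.008, 0.008, 0.009),
      ex = c(0.889, 0.850, 0.784, 0.773, 0.700),
      ex_se = c(0.004, 0.005, 0.005, 0.006, 0.007)
    )
  )
}

# age band index for ages >= 35: 1 = 35-44, ..., 5 = 75+
band_index <- function(age) findInterval(age, c(0, 45, 55, 65, 75))

# pull the per-band vector for one sex/status out of a band table
band_vector <- function(tab, sex, col) {
  tab <- tab[tab$sex == sex, ]
  tab[[col]][order(tab$age_min)]
}

#' Smoking-attributable proportion of disease costs
#'
#' Fraction of the cost of smoking-related disease attributable to smoking,
#' given the prevalence of current and ex-smoking and the relative risks of
#' smoking-related disease versus never-smokers:
#' \deqn{\frac{p_{cur}(r_{cur}-1) + p_{ex}(r_{ex}-1)}
#'            {1 + p_{cur}(r_{cur}-1) + p_{ex}(r_{ex}-1)}}
#'
#' @param p_cur,p_ex Prevalence of current smokers and of ex-smokers
#'   (`p_cur + p_ex <= 1`).
#' @param r_cur,r_ex Relative risks of smoking-related disease for current
#'   and ex-smokers versus never-smokers.
#' @return Attributable proportion (vectorised). Relative risks below 1 can
#'   produce negative values; these are returned with a warning rather than
#'   rejected.
#' @examples
#' smoking_attributable_proportion(0.5, 0.2, 3, 1.5) # 1.1 / 2.1
#' @export
smoking_attributable_proportion <- function(p_cur, p_ex, r_cur, r_ex) {
  stopifnot(
    all(p_cur >= 0), all(p_ex >= 0), all(p_cur + p_ex <= 1),
    all(r_cur >= 0), all(r_ex >= 0)
  )
  excess <- p_cur * (r_cur - 1) + p_ex * (r_ex - 1)
  denom <- 1 + excess
  if (any(denom <= 0)) stop("denominator 1 + excess risk must be positive")
  out <- excess / denom
  if (any(out < 0)) {
    warning("attributable proportion below 0 (protective relative risk)")
  }
  out
}

# Core cohort engine, vectorised over parameter draws.
#
# `par` carries one value per draw for every model parameter:
#   quit, death1, fc_cost, fc_qaly          : length-n vectors
#   relapse                                 : length-n vector
#   mort[[sex]]$smoker / $ex_smoker         : n x 5 matrices (age bands)
#   cost[[sex]]$..., util[[sex]]$...        : n x 5 matrices
# Cycle semantics: cycle 1 is the trial year; the cohort is allocated to
# states from the quit rate (deaths removed from the quit denominator) and
# accrues the per-person trial cost/QALY undiscounted. Each later cycle t
# (attained age entry + t - 1): relapse moves ex-smokers back to smoking
# (cycles 2 .. 1 + relapse_years); annual costs are accrued on the
# post-relapse, pre-mortality occupancy (decedents incur their death-year
# costs); mortality is applied; QALYs are accrued on the survivors.
# Discount factor for cycle t is (1 + r)^-(t - 1).
cohort_engine <- function(inputs, par, n_draws, trace = FALSE) {
  entry <- inputs$entry_age
  horizon <- inputs$horizon_age
  n_cycles <- horizon - entry + 1
  dc <- inputs$discount_rate_cost
  dq <- inputs$discount_rate_qaly
  N <- inputs$cohort_size

  tot_cost <- numeric(n_draws)
  tot_qaly <- numeric(n_draws)
  trace_rows <- if (trace) vector("list", n_cycles) else NULL
  occ <- list() # per-sex running state

  for (sex in c("male", "female")) {
    n_sex <- N * if (sex == "male") inputs$male_fraction else 1 - inputs$male_fraction
    dead <- n_sex * par$death1
    ex <- par$quit * (n_sex - dead)
    smk <- n_sex - dead - ex
    occ[[sex]] <- list(smk = smk, ex = ex, dead = dead)
    tot_cost <- tot_cost + n_sex * par$fc_cost
    tot_qaly <- tot_qaly + n_sex * par$fc_qaly
  }
  if (trace) {
    trace_rows[[1]] <- data.frame(
      cycle = 1, age = entry,
      smoker = occ$male$smk + occ$female$smk,
      ex_smoker = occ$male$ex + occ$female$ex,
      dead = occ$male$dead + occ$female$dead,
      cycle_cost = tot_cost, cycle_qaly = tot_qaly,
      discount_cost = 1, discount_qaly = 1
    )
  }

  if (n_cycles >= 2) {
    for (t in 2:n_cycles) {
      age <- entry + t - 1
      b <- band_index(age)
      df_c <- 1 / (1 + dc)^(t - 1)
      df_q <- 1 / (1 + dq)^(t - 1)
      cyc_cost <- numeric(n_draws)
      cyc_qaly <- numeric(n_draws)
      for (sex in c("male", "female")) {
        s <- occ[[sex]]
        if (t <= 1 + inputs$relapse_years) {
          rel <- par$relapse * s$ex
          s$ex <- s$ex - rel
          s$smk <- s$smk + rel
        }
        cyc_cost <- cyc_cost +
          s$smk * par$cost[[sex]]$smoker[, b] +
          s$ex * par$cost[[sex]]$ex_smoker[, b]
        d_smk <- s$smk * par$mort[[sex]]$smoker[, b]
        d_ex <- s$ex * par$mort[[sex]]$ex_smoker[, b]
        s$smk <- s$smk - d_smk
        s$ex <- s$ex - d_ex
        s$dead <- s$dead + d_smk + d_ex
        cyc_qaly <- cyc_qaly +
          s$smk * par$util[[sex]]$smoker[, b] +
          s$ex * par$util[[sex]]$ex_smoker[, b]
        occ[[sex]] <- s
      }
      tot_cost <- tot_cost + df_c * cyc_cost
      tot_qaly <- tot_qaly + df_q * cyc_qaly
      if (trace) {
        trace_rows[[t]] <- data.frame(
          cycle = t, age = age,
          smoker = occ$male$smk + occ$female$smk,
          ex_smoker = occ$male$ex + occ$female$ex,
          dead = occ$male$dead + occ$female$dead,
          cycle_cost = cyc_cost, cycle_qaly = cyc_qaly,
          discount_cost = df_c, discount_qaly = df_q
        )
      }
    }
  }

  out <- list(cost = tot_cost, qaly = tot_qaly)
  if (trace) {
    tr <- do.call(rbind, trace_rows)
    tr$cum_disc_cost <- cumsum(tr$cycle_cost * tr$discount_cost)
    tr$cum_disc_qaly <- cumsum(tr$cycle_qaly * tr$discount_qaly)
    out$trace <- tr
  }
  out
}

# deterministic (point-value) parameter set for one arm, n_draws copies
point_parameters <- function(inputs, arm, n_draws = 1) {
  rep_mat <- function(v) matrix(v, nrow = n_draws, ncol = length(v), byrow = TRUE)
  grab <- function(tab) {
    lapply(stats::setNames(c("male", "female"), c("male", "female")), function(sx) {
      list(
        smoker = rep_mat(band_vector(tab, sx, "smoker")),
        ex_smoker = rep_mat(band_vector(tab, sx, "ex_smoker"))
      )
    })
  }
  list(
    quit = rep(inputs$quit_rate[[arm]], n_draws),
    death1 = rep(inputs$first_cycle_death_prob[[arm]], n_draws),
    fc_cost = rep(inputs$first_cycle_cost[[arm]], n_draws),
    fc_qaly = rep(inputs$first_cycle_qaly[[arm]], n_draws),
    relapse = rep(inputs$relapse_prob, n_draws),
    mort = grab(inputs$mortality),
    cost = grab(inputs$annual_cost),
    util = grab(inputs$annual_utility)
  )
}

#' Run the lifetime cohort model for one arm
#'
#' Deterministic run of the three-state cohort model at the point values in
#' `inputs`. Returns the full cohort trace (one row per annual cycle) with
#' state occupancy, per-cycle cost and QALY accruals, discount factors and
#' cumulative discounted totals.
#'
#' @param inputs A [lifetime_inputs()] object.
#' @param arm `"NRT"` or `"EC"`.
#' @return An object of class `cohort_trace`: a data frame of cycles with
#'   attributes `total_cost` and `total_qaly` (per-person discounted
#'   lifetime totals) and `arm`.
#' @examples
#' tr <- run_cohort(lifetime_inputs(), "NRT")
#' attr(tr, "total_qaly")
#' @export
run_cohort <- function(inputs, arm = c("NRT", "EC")) {
  arm <- match.arg(arm)
  stopifnot(inherits(inputs, "lifetime_inputs"))
  res <- cohort_engine(inputs, point_parameters(inputs, arm), 1, trace = TRUE)
  tr <- res$trace
  structure(tr,
    class = c("cohort_trace", "data.frame"),
    total_cost = res$cost / inputs$cohort_size,
    total_qaly = res$qaly / inputs$cohort_size,
    cohort_size = inputs$cohort_size,
    arm = arm
  )
}

#' @export
summary.cohort_trace <- function(object, ...) {
  cat(sprintf(
    "Cohort trace (%s arm): %d cycles, ages %d-%d\n",
    attr(object, "arm"), nrow(object), min(object$age), max(object$age)
  ))
  cat(sprintf(
    "  per-person discounted lifetime cost: £%.2f\n",
    attr(object, "total_cost")
  ))
  cat(sprintf(
    "  per-person discounted lifetime QALYs: %.3f\n",
    attr(object, "total_qaly")
  ))
  invisible(object)
}

#' Lifetime incremental cost-effectiveness ratio
#'
#' Per-person incremental discounted lifetime cost of the e-cigarette arm
#' over the comparator divided by the incremental discounted lifetime
#' QALYs, with the dominance classification of [icer()].
#'
#' @param trace_ref,trace_int `cohort_trace` objects from [run_cohort()]
#'   for the reference (comparator) and intervention arm, run from
#'   identical inputs apart from the arm.
#' @return An `icer_estimate` (see [icer()]) with the per-person
#'   incremental cost and QALYs attached.
#' @examples
#' inp <- lifetime_inputs()
#' lifetime_icer(run_cohort(inp, "NRT"), run_cohort(inp, "EC"))
#' @export
lifetime_icer <- function(trace_ref, trace_int) {
  stopifnot(inherits(trace_ref, "cohort_trace"), inherits(trace_int, "cohort_trace"))
  dc <- attr(trace_int, "total_cost") - attr(trace_ref, "total_cost")
  dq <- attr(trace_int, "total_qaly") - attr(trace_ref, "total_qaly")
  icer(dc, dq)
}

#' Read or write lifetime model inputs as YAML
#'
#' The packaged fixture `system.file("extdata", "lifetime_inputs.yaml",
#' package = "quitcea")` carries the full default input set (including
#' standard errors) in a flat, human-editable form.
#'
#' @param path Path to a YAML file.
#' @return `read_lifetime_inputs()` returns a [lifetime_inputs()] object;
#'   `write_lifetime_inputs()` invisibly returns `path`.
#' @examples
#' inp <- read_lifetime_inputs(
#'   system.file("extdata", "lifetime_inputs.yaml", package = "quitcea")
#' )
#' @export
read_lifetime_inputs <- function(path) {
  y <- yaml::read_yaml(path)
  as_band <- function(lst) {
    do.call(rbind, lapply(lst, function(row) {
      data.frame(
        sex = row$sex, age_min = row$age_min,
        smoker = row$smoker, smoker_se = row$smoker_se,
        ex_smoker = row$ex_smoker, ex_smoker_se = row$ex_smoker_se
      )
    }))
  }
  arms <- function(v) unlist(v[c("NRT", "EC")])
  lifetime_inputs(
    cohort_size = y$cohort_size, entry_age = y$entry_age,
    horizon_age = y$horizon_age, male_fraction = y$male_fraction,
    quit_rate = arms(y$quit_rate), quit_rate_se = arms(y$quit_rate_se),
    first_cycle_death_prob = arms(y$first_cycle_death_prob),
    first_cycle_cost = arms(y$first_cycle_cost),
    first_cycle_cost_se = arms(y$first_cycle_cost_se),
    first_cycle_qaly = arms(y$first_cycle_qaly),
    first_cycle_qaly_se = arms(y$first_cycle_qaly_se),
    relapse_prob = y$relapse_prob, relapse_prob_se = y$relapse_prob_se,
    relapse_years = y$relapse_years,
    mortality = as_band(y$mortality),
    annual_cost = as_band(y$annual_cost),
    annual_utility = as_band(y$annual_utility),
    discount_rate_cost = y$discount_rate_cost,
    discount_rate_qaly = y$discount_rate_qaly
  )
}

#' @rdname read_lifetime_inputs
#' @param inputs A [lifetime_inputs()] object.
#' @export
write_lifetime_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "lifetime_inputs"))
  as_rows <- function(tab) {
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  }
  arms <- function(v) as.list(v)
  y <- list(
    cohort_size = inputs$cohort_size, entry_age = inputs$entry_age,
    horizon_age = inputs$horizon_age, male_fraction = inputs$male_fraction,
    quit_rate = arms(inputs$quit_rate), quit_rate_se = arms(inputs$quit_rate_se),
    first_cycle_death_prob = arms(inputs$first_cycle_death_prob),
    first_cycle_cost = arms(inputs$first_cycle_cost),
    first_cycle_cost_se = arms(inputs$first_cycle_cost_se),
    first_cycle_qaly = arms(inputs$first_cycle_qaly),
    first_cycle_qaly_se = arms(inputs$first_cycle_qaly_se),
    relapse_prob = inputs$relapse_prob,
    relapse_prob_se = inputs$relapse_prob_se,
    relapse_years = inputs$relapse_years,
    mortality = as_rows(inputs$mortality),
    annual_cost = as_rows(inputs$annual_cost),
    annual_utility = as_rows(inputs$annual_utility),
    discount_rate_cost = inputs$discount_rate_cost,
    discount_rate_qaly = inputs$discount_rate_qaly
  )
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
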