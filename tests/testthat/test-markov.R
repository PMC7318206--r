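# inputs with every stochastic ingredient switched off: no mortality, no
# relapse, flat utility u and annual cost c, no discounting
flat_inputs <- function(u = 0.8, cost = 100, ...) {
  flat <- function(val) {
    tab <- default_mortality_table()
    tab$smoker <- val
    tab$ex_smoker <- val
    tab$smoker_se <- 0
    tab$ex_smoker_se <- 0
    tab
  }
  lifetime_inputs(
    first_cycle_death_prob = c(NRT = 0, EC = 0),
    relapse_prob = 0,
    mortality = flat(0),
    annual_cost = flat(cost),
    annual_utility = flat(u),
    discount_rate_cost = 0, discount_rate_qaly = 0,
    ...
  )
}

test_that("occupancy is conserved every cycle and the dead state is absorbing", {
  inp <- lifetime_inputs()
  for (arm in c("NRT", "EC")) {
    tr <- run_cohort(inp, arm)
    totals <- tr$smoker + tr$ex_smoker + tr$dead
    expect_equal(totals, rep(inp$cohort_size, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(tr$smoker >= 0 & tr$ex_smoker >= 0))
  }
})

test_that("with no mortality, relapse or discounting the annuity closed form holds", {
  inp <- flat_inputs(u = 0.8, cost = 100)
  for (arm in c("NRT", "EC")) {
    tr <- run_cohort(inp, arm)
    years <- inp$horizon_age - inp$entry_age # cycles beyond the first
    expect_equal(
      attr(tr, "total_qaly"),
      inp$first_cycle_qaly[[arm]] + 0.8 * years,
      tolerance = 1e-12
    )
    expect_equal(
      attr(tr, "total_cost"),
      inp$first_cycle_cost[[arm]] + 100 * years,
      tolerance = 1e-12
    )
  }
})

test_that("discounting can only shrink lifetime QALYs, with equality at rate zero", {
  undisc <- lifetime_inputs(discount_rate_qaly = 0)
  disc <- lifetime_inputs(discount_rate_qaly = 0.035)
  q0 <- attr(run_cohort(undisc, "EC"), "total_qaly")
  q35 <- attr(run_cohort(disc, "EC"), "total_qaly")
  expect_lt(q35, q0)
  again <- attr(run_cohort(lifetime_inputs(discount_rate_qaly = 0), "EC"), "total_qaly")
  expect_equal(again, q0)
})

test_that("raising the quit rate never lowers lifetime QALYs", {
  qalys <- vapply(seq(0.05, 0.9, by = 0.05), function(q) {
    inp <- lifetime_inputs(quit_rate = c(NRT = 0.099, EC = q))
    attr(run_cohort(inp, "EC"), "total_qaly")
  }, numeric(1))
  expect_true(all(diff(qalys) >= -1e-12))
})

test_that("the cohort engine matches a per-person microsimulation on a short horizon", {
  inp <- lifetime_inputs(
    entry_age = 41, horizon_age = 43, male_fraction = 1,
    cohort_size = 1000, discount_rate_cost = 0, discount_rate_qaly = 0
  )
  tr <- run_cohort(inp, "EC")

  # independent oracle: simulate individuals one at a time under the same
  # transition and accrual rules
  set.seed(99)
  n_sim <- 20000
  q <- inp$quit_rate[["EC"]]
  d1 <- inp$first_cycle_death_prob[["EC"]]
  mort <- inp$mortality[inp$mortality$sex == "male" & inp$mortality$age_min == 35, ]
  cost_t <- inp$annual_cost[inp$annual_cost$sex == "male" & inp$annual_cost$age_min == 35, ]
  util_t <- inp$annual_utility[inp$annual_utility$sex == "male" & inp$annual_utility$age_min == 35, ]
  cost <- qaly <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    cost[i] <- inp$first_cycle_cost[["EC"]]
    qaly[i] <- inp$first_cycle_qaly[["EC"]]
    state <- if (runif(1) < d1) {
      "dead"
    } else if (runif(1) < q) "ex" else "smoker"
    for (t in 2:3) {
      if (state == "dead") break
      if (state == "ex" && runif(1) < inp$relapse_prob) state <- "smoker"
      cost[i] <- cost[i] +
        if (state == "smoker") cost_t$smoker else cost_t$ex_smoker
      p_die <- if (state == "smoker") mort$smoker else mort$ex_smoker
      if (runif(1) < p_die) {
        state <- "dead"
        break
      }
      qaly[i] <- qaly[i] +
        if (state == "smoker") util_t$smoker else util_t$ex_smoker
    }
  }
  expect_lt(
    abs(mean(qaly) - attr(tr, "total_qaly")), 3 * sd(qaly) / sqrt(n_sim)
  )
  expect_lt(
    abs(mean(cost) - attr(tr, "total_cost")), 3 * sd(cost) / sqrt(n_sim)
  )
})

test_that("the smoking-attributable proportion follows the prevalence/risk formula", {
  expect_equal(smoking_attributable_proportion(0.4, 0.3, 1, 1), 0)
  expect_equal(smoking_attributable_proportion(1, 0, 2, 1), 0.5)
  expect_equal(
    smoking_attributable_proportion(0.5, 0.2, 3, 1.5), 1.1 / 2.1
  )
  # enumerated grid against direct arithmetic
  grid <- expand.grid(
    p_cur = c(0.1, 0.3), p_ex = c(0.1, 0.4), r_cur = c(1.5, 4), r_ex = c(1, 2)
  )
  excess <- with(grid, p_cur * (r_cur - 1) + p_ex * (r_ex - 1))
  expect_equal(
    with(grid, smoking_attributable_proportion(p_cur, p_ex, r_cur, r_ex)),
    excess / (1 + excess)
  )
  # protective risks flagged, not rejected
  expect_warning(
    neg <- smoking_attributable_proportion(0.5, 0, 0.5, 1), "below 0"
  )
  expect_lt(neg, 0)
  expect_error(smoking_attributable_proportion(-0.1, 0, 2, 1))
})

test_that("lifetime ICER handles identical arms and weak dominance", {
  inp <- lifetime_inputs()
  tr <- run_cohort(inp, "NRT")
  same <- lifetime_icer(tr, tr)
  expect_true(is.na(same$icer))
  expect_match(same$classification, "undefined")

  # equal costs, higher effect: ICER 0
  ie <- icer(0, 0.2)
  expect_equal(ie$icer, 0)
})

test_that("invalid lifetime inputs are rejected by validation", {
  bad_mort <- default_mortality_table()
  bad_mort$ex_smoker[1] <- bad_mort$smoker[1] + 0.1
  expect_error(lifetime_inputs(mortality = bad_mort), "ex-smoker mortality")

  bad_util <- default_annual_utility_table()
  bad_util$ex_smoker[3] <- bad_util$smoker[3] - 0.05
  expect_error(lifetime_inputs(annual_utility = bad_util), "ex-smoker utility")

  expect_error(lifetime_inputs(horizon_age = 30))
  expect_error(lifetime_inputs(quit_rate = c(NRT = 1.2, EC = 0.18)))
})

test_that("the packaged lifetime-inputs fixture matches the in-code defaults", {
  fix <- read_lifetime_inputs(
    system.file("extdata", "lifetime_inputs.yaml", package = "quitcea")
  )
  expect_equal(unclass(fix), unclass(lifetime_inputs()), ignore_attr = TRUE)
})

test_that("cohort traces export to CSV", {
  tr <- run_cohort(lifetime_inputs(), "NRT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_trace(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$dead, tr$dead)
})
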