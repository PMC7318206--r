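#' Configuration of the synthetic trial generator
#'
#' Describes the statistical structure of a two-arm smoking cessation
#' trial — arm sizes, quit and death rates, session attendance and product
#' issue, right-skewed service costs, correlated utilities, participant
#' expenses, covariate distributions and a section-wise
#' missing-at-random mechanism — so that individual-level datasets with
#' that structure can be simulated for testing and calibration. The
#' defaults emulate a pragmatic stop-smoking-service trial of an
#' e-cigarette starter kit (`EC`) versus nicotine replacement therapy
#' (`NRT`): 447/439 participants, one-year sustained quit rates of
#' 9.9%/18.0%, median age 41, 52% male, three sites, and roughly a third
#' of follow-up questionnaire sections missing.
#'
#' Costs are drawn from gamma distributions around the configured window
#' means, multiplied by a person-level gamma frailty that induces the
#' strong within-person correlation between baseline and follow-up costs
#' seen in service-use data; `cost_dispersion` is the gamma shape of the
#' window draw (small values give the heavy right skew typical of
#' healthcare costs). Utilities at 0/6/12 months are marginally
#' beta-distributed on `[-0.594, 1]` (moment-matched to the configured
#' mean and `utility_sd`) and correlated within person through a Gaussian
#' copula with a person-effect variance share `utility_person_share`;
#' quitters' means at 6 and 12 months are shifted up by
#' `quit_utility_shift` with non-quitters shifted down so the configured
#' marginal means are preserved. Whole follow-up sections go missing
#' together via a logistic model on observed baseline covariates whose
#' intercept is calibrated so the marginal section missingness equals
#' `missing_rate`.
#'
#' @param n_per_arm Named vector (`NRT`, `EC`) of arm sizes (each >= 2).
#' @param quit_rate Named vector of one-year sustained quit probabilities.
#' @param death_prob Named vector of first-year death probabilities.
#' @param sessions_mean,sessions_sd Mean and SD of support sessions
#'   attended (integer 0-6 after rounding and clipping).
#' @param nrt_items_mean,nrt_items_size Negative-binomial mean and size of
#'   the number of NRT items issued per NRT-arm participant.
#' @param lor_rate Poisson mean of letters of recommendation issued per
#'   NRT-arm participant.
#' @param ec_kit_2016_prob,ec_no_kit_prob,ec_extra_liquid_prob EC-arm
#'   probabilities of receiving the 2016 replacement kit, of declining the
#'   kit, and of requesting an extra e-liquid bottle.
#' @param cost_means Named list (`NRT`, `EC`) of 2 x 3 matrices of mean
#'   window costs in pounds: rows `cessation`, `healthcare`; columns
#'   `baseline` (6-month recall), `m0_6`, `m6_12`.
#' @param cost_dispersion Gamma shape of each window cost draw (> 0).
#' @param cost_frailty_shape Gamma shape of the person-level cost frailty.
#' @param utility_means Named list of length-3 vectors of marginal utility
#'   means at months 0/6/12.
#' @param utility_sd Marginal SD of utilities.
#' @param utility_person_share Share of latent utility variance from the
#'   person effect, in `[0, 1]`.
#' @param quit_utility_shift Additive utility advantage of quitters at 6
#'   and 12 months.
#' @param expense_means Named list of length-3 vectors of mean participant
#'   expenses (pounds) on NRT, e-cigarettes and prescription charges.
#' @param expense_dispersion Gamma shape of expense draws.
#' @param missing_rate Marginal probability that a follow-up section is
#'   entirely missing.
#' @param missing_logit_coefs Named coefficients (on standardised baseline
#'   variables `age`, `male`, `ftcd`, `free_rx`, `utility_0`) of the
#'   missingness logit; the mechanism is missing-at-random because it
#'   depends only on fully observed baseline data.
#' @param covariate_specs List: `age_meanlog`, `age_sdlog`, `age_range`,
#'   `male_fraction`, `site_probs` (length 3), `ftcd_mean`, `ftcd_sd`,
#'   `free_rx_fraction`.
#' @param currency_year Currency year label stored in the metadata.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @seealso [generate_trial()]
#' @export
generator_config <- function(n_per_arm = c(NRT = 447, EC = 439),
                             quit_rate = c(NRT = 0.099, EC = 0.180),
                             death_prob = c(NRT = 1 / 447, EC = 1 / 439),
                             sessions_mean = c(NRT = 5.2, EC = 5.5),
                             sessions_sd = c(NRT = 1.2, EC = 1.0),
                             nrt_items_mean = 10.6,
                             nrt_items_size = 4,
                             lor_rate = 1.64,
                             ec_kit_2016_prob = 42 / 439,
                             ec_no_kit_prob = 1 / 439,
                             ec_extra_liquid_prob = 30 / 439,
                             cost_means = default_cost_means(),
                             cost_dispersion = 0.1,
                             cost_frailty_shape = 1,
                             utility_means = default_utility_means(),
                             utility_sd = 0.19,
                             utility_person_share = 0.5,
                             quit_utility_shift = 0.05,
                             expense_means = default_expense_means(),
                             expense_dispersion = 0.1,
                             missing_rate = 0.35,
                             missing_logit_coefs = c(
                               age = -0.3, male = 0.1, ftcd = 0.2,
                               free_rx = 0.15, utility_0 = -0.2
                             ),
                             covariate_specs = list(
                               age_meanlog = log(41), age_sdlog = 0.35,
                               age_range = c(18, 85),
                               male_fraction = 0.52,
                               site_probs = c(0.40, 0.35, 0.25),
                               ftcd_mean = 5.5, ftcd_sd = 2.3,
                               free_rx_fraction = 0.5
                             ),
                             currency_year = "2015/16",
                             seed = 1L) {
  x <- structure(
    list(
      n_per_arm = n_per_arm, quit_rate = quit_rate,
      death_prob = death_prob,
      sessions_mean = sessions_mean, sessions_sd = sessions_sd,
      nrt_items_mean = nrt_items_mean, nrt_items_size = nrt_items_size,
      lor_rate = lor_rate,
      ec_kit_2016_prob = ec_kit_2016_prob,
      ec_no_kit_prob = ec_no_kit_prob,
      ec_extra_liquid_prob = ec_extra_liquid_prob,
      cost_means = cost_means, cost_dispersion = cost_dispersion,
      cost_frailty_shape = cost_frailty_shape,
      utility_means = utility_means, utility_sd = utility_sd,
      utility_person_share = utility_person_share,
      quit_utility_shift = quit_utility_shift,
      expense_means = expense_means,
      expense_dispersion = expense_dispersion,
      missing_rate = missing_rate,
      missing_logit_coefs = missing_logit_coefs,
      covariate_specs = covariate_specs,
      currency_year = currency_year,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(x)
}

validate_generator_config <- function(x) {
  probs <- c(
    x$quit_rate, x$death_prob, x$missing_rate,
    x$ec_kit_2016_prob, x$ec_no_kit_prob, x$ec_extra_liquid_prob,
    x$utility_person_share, x$covariate_specs$male_fraction,
    x$covariate_specs$site_probs, x$covariate_specs$free_rx_fraction
  )
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probabilities in the generator config must lie in [0, 1]")
  }
  if (any(x$n_per_arm < 2)) stop("n_per_arm must be at least 2 per arm")
  costs <- unlist(x$cost_means)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("cost means must be finite and non-negative")
  }
  if (!is.finite(x$cost_dispersion) || x$cost_dispersion <= 0) {
    stop("cost_dispersion must be a positive shape parameter")
  }
  if (!is.finite(x$utility_sd) || x$utility_sd < 0) {
    stop("utility_sd must be non-negative")
  }
  if (any(!is.finite(unlist(x$utility_means)))) {
    stop("utility means must be finite")
  }
  x
}

#' @rdname generator_config
#' @export
default_cost_means <- function() {
  mk <- function(cess, health) {
    matrix(c(cess, health),
      nrow = 2, byrow = TRUE,
      dimnames = list(
        c("cessation", "healthcare"),
        c("baseline", "m0_6", "m6_12")
      )
    )
  }
  list(
    NRT = mk(c(40, 38.5, 38.5), c(605, 419.5, 419.5)),
    EC = mk(c(30, 24, 24), c(509, 511, 511))
  )
}

#' @rdname generator_config
#' @export
default_utility_means <- function() {
  list(NRT = c(0.878, 0.882, 0.887), EC = c(0.868, 0.888, 0.898))
}

#' @rdname generator_config
#' @export
default_expense_means <- function() {
  list(
    NRT = c(nrt = 89, ec = 49, rx_charge = 20),
    EC = c(nrt = 12, ec = 152, rx_charge = 4)
  )
}

# EQ-5D utilities live on [-0.594, 1]
UTILITY_RANGE <- c(-0.594, 1)

# quantile of a beta moment-matched to (mean, sd) on [lo, hi]
qscaled_beta <- function(p, mean, sd, lo = UTILITY_RANGE[1], hi = UTILITY_RANGE[2]) {
  r <- hi - lo
  m <- (mean - lo) / r
  s <- sd / r
  if (any(m <= 0 | m >= 1)) stop("utility mean outside the feasible range")
  if (any(s^2 >= m * (1 - m))) {
    stop("utility_sd too large for a beta marginal on [-0.594, 1]")
  }
  k <- m * (1 - m) / s^2 - 1
  lo + r * stats::qbeta(p, m * k, (1 - m) * k)
}

# gamma draw with given mean and shape (mean 0 -> exactly 0)
rgamma_mean <- function(n, mean, shape) {
  out <- numeric(n)
  pos <- mean > 0
  if (length(mean) == 1) pos <- rep(pos, n)
  mn <- rep_len(mean, n)
  if (any(pos)) {
    out[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape / mn[pos])
  }
  out
}

# format a product count vector as an "id:qty;id:qty" log string
format_product_log <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return("")
  }
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}

# simulate one arm's participants (complete data, no missingness yet)
simulate_arm <- function(cfg, arm) {
  n <- cfg$n_per_arm[[arm]]
  cs <- cfg$covariate_specs
  age <- round(pmin(
    pmax(stats::rlnorm(n, cs$age_meanlog, cs$age_sdlog), cs$age_range[1]),
    cs$age_range[2]
  ))
  male <- stats::rbinom(n, 1, cs$male_fraction)
  site <- sample.int(3, n, replace = TRUE, prob = cs$site_probs)
  ftcd <- pmin(pmax(round(stats::rnorm(n, cs$ftcd_mean, cs$ftcd_sd)), 0), 10)
  free_rx <- stats::rbinom(n, 1, cs$free_rx_fraction)

  died <- stats::rbinom(n, 1, cfg$death_prob[[arm]])
  death_month <- ifelse(died == 1, sample.int(12, n, replace = TRUE), NA_integer_)
  quit_12m <- stats::rbinom(n, 1, cfg$quit_rate[[arm]])

  sessions <- pmin(pmax(
    round(stats::rnorm(n, cfg$sessions_mean[[arm]], cfg$sessions_sd[[arm]])), 0
  ), 6)

  products <- character(n)
  if (arm == "NRT") {
    forms <- names(unit_cost_table()$nrt_item_costs)
    n_items <- stats::rnbinom(n, mu = cfg$nrt_items_mean, size = cfg$nrt_items_size)
    lor <- stats::rpois(n, cfg$lor_rate)
    for (i in seq_len(n)) {
      mix <- stats::rmultinom(1, n_items[i], rep(1, length(forms)))[, 1]
      names(mix) <- forms
      products[i] <- format_product_log(
        c(mix, lor = lor[i], pharmacy_list = 1)
      )
    }
  } else {
    kit2016 <- stats::rbinom(n, 1, cfg$ec_kit_2016_prob)
    no_kit <- stats::rbinom(n, 1, cfg$ec_no_kit_prob)
    extra <- stats::rbinom(n, 1, cfg$ec_extra_liquid_prob)
    for (i in seq_len(n)) {
      counts <- c(
        ec_kit = (1 - no_kit[i]) * (1 - kit2016[i]),
        ec_kit_2016 = (1 - no_kit[i]) * kit2016[i],
        ec_liquid_extra = extra[i],
        info_sheet = 1
      )
      products[i] <- format_product_log(counts)
    }
  }

  # service costs: window gamma draws scaled by a person frailty
  frailty <- stats::rgamma(n, shape = cfg$cost_frailty_shape, rate = cfg$cost_frailty_shape)
  mu <- cfg$cost_means[[arm]]
  cost_col <- function(category, window) {
    rgamma_mean(n, mu[category, window] * frailty, cfg$cost_dispersion)
  }
  costs <- data.frame(
    cost_cessation_baseline = cost_col("cessation", "baseline"),
    cost_cessation_0_6 = cost_col("cessation", "m0_6"),
    cost_cessation_6_12 = cost_col("cessation", "m6_12"),
    cost_healthcare_baseline = cost_col("healthcare", "baseline"),
    cost_healthcare_0_6 = cost_col("healthcare", "m0_6"),
    cost_healthcare_6_12 = cost_col("healthcare", "m6_12")
  )

  # utilities: Gaussian copula latent, scaled-beta marginals; quitters'
  # means at 6/12 months shifted up, non-quitters down, preserving the
  # configured marginal means
  rho <- cfg$utility_person_share
  b <- stats::rnorm(n)
  mu_u <- cfg$utility_means[[arm]]
  q <- cfg$quit_rate[[arm]]
  util <- matrix(NA_real_, n, 3)
  for (t in 1:3) {
    z <- sqrt(rho) * b + sqrt(1 - rho) * stats::rnorm(n)
    shift <- if (t == 1) 0 else cfg$quit_utility_shift
    m_t <- mu_u[t] + ifelse(quit_12m == 1, (1 - q) * shift, -q * shift)
    util[, t] <- qscaled_beta(stats::pnorm(z), m_t, cfg$utility_sd)
  }
  vas <- sapply(1:3, function(t) {
    pmin(pmax(round(100 * (0.3 + 0.6 * util[, t]) + stats::rnorm(n, 0, 8)), 0), 100)
  })

  ex <- cfg$expense_means[[arm]]
  expenses <- data.frame(
    expenses_nrt = rgamma_mean(n, ex[["nrt"]], cfg$expense_dispersion),
    expenses_ec = rgamma_mean(n, ex[["ec"]], cfg$expense_dispersion),
    expenses_rx_charge = rgamma_mean(n, ex[["rx_charge"]], cfg$expense_dispersion)
  )

  cbind(
    data.frame(
      arm = arm, age = age, male = male, site = site, ftcd = ftcd,
      free_rx = free_rx, sessions_attended = sessions,
      products_issued = products, stringsAsFactors = FALSE
    ),
    costs,
    data.frame(
      utility_0 = util[, 1], utility_6 = util[, 2], utility_12 = util[, 3],
      vas_0 = vas[, 1], vas_6 = vas[, 2], vas_12 = vas[, 3]
    ),
    expenses,
    data.frame(quit_12m = quit_12m, died = died, death_month = death_month)
  )
}

# linear predictor of the missingness logit on standardised baseline vars
missing_linear_predictor <- function(df, coefs) {
  std <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  lp <- rep(0, nrow(df))
  for (nm in names(coefs)) {
    if (!nm %in% names(df)) stop("missing_logit_coefs names a variable not in the data: ", nm)
    lp <- lp + coefs[[nm]] * std(df[[nm]])
  }
  lp
}

# intercept such that mean(plogis(a + lp)) == target
calibrate_intercept <- function(lp, target) {
  if (target <= 0) {
    return(-Inf)
  }
  if (target >= 1) {
    return(Inf)
  }
  stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - target,
    interval = c(-30, 30), tol = 1e-10
  )$root
}

# blank out whole follow-up sections under the MAR mechanism
apply_missingness <- function(df, cfg) {
  if (cfg$missing_rate == 0) {
    return(df)
  }
  sections <- list(
    m6 = c("cost_cessation_0_6", "cost_healthcare_0_6", "utility_6", "vas_6"),
    m12 = c(
      "cost_cessation_6_12", "cost_healthcare_6_12", "utility_12", "vas_12",
      "expenses_nrt", "expenses_ec", "expenses_rx_charge"
    )
  )
  lp <- missing_linear_predictor(df, cfg$missing_logit_coefs)
  a <- calibrate_intercept(lp, cfg$missing_rate)
  p <- stats::plogis(a + lp)
  for (cols in sections) {
    miss <- stats::rbinom(nrow(df), 1, p) == 1
    df[miss, cols] <- NA
  }
  df
}

#' Generate a synthetic two-arm cessation trial
#'
#' Simulates an individual-level trial dataset under `config`: covariates,
#' session attendance and product logs, windowed service costs, utilities
#' at 0/6/12 months, participant expenses, quit status (always complete),
#' deaths, and section-wise missing-at-random follow-up data. Cost and
#' utility entries after a participant's death are zero, not missing.
#' Generation is fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An object of class `trial_dataset`: list with `participants`
#'   (data frame, one row per participant), `config`, and `meta` (arm
#'   labels, currency year, seed).
#' @examples
#' td <- generate_trial(generator_config(
#'   n_per_arm = c(NRT = 50, EC = 50),
#'   seed = 7
#' ))
#' head(td$participants)
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  df <- rbind(simulate_arm(config, "NRT"), simulate_arm(config, "EC"))
  df$arm <- factor(df$arm, levels = c("NRT", "EC"))
  df <- cbind(id = seq_len(nrow(df)), df)
  df <- apply_missingness(df, config)
  out <- structure(
    list(
      participants = df,
      config = config,
      meta = list(
        arms = levels(df$arm),
        currency_year = config$currency_year,
        seed = config$seed
      )
    ),
    class = "trial_dataset"
  )
  apply_death_zeroing(out)
}

#' Zero out costs and utilities after death
#'
#' Cost and utility information for participants who died is replaced
#' with zero — not treated as missing — for every window or time point
#' after the month of death: the 6-12-month cost window when death
#' occurred in the first half-year, and each utility/VAS measurement
#' whose time point falls strictly after the death month. A death in
#' month 12 leaves the dataset unchanged (nothing falls after it).
#'
#' @param data A `trial_dataset` or participant data frame with `died`
#'   and `death_month` columns.
#' @return The input with post-death entries zeroed, same class as given.
#' @export
apply_death_zeroing <- function(data) {
  df <- participant_frame(data)
  stopifnot(all(c("died", "death_month") %in% names(df)))
  dead <- which(df$died == 1)
  for (i in dead) {
    d <- df$death_month[i]
    if (is.na(d)) next
    if (d <= 6) {
      df[i, c("cost_cessation_6_12", "cost_healthcare_6_12")] <- 0
    }
    if (d < 6) df[i, c("utility_6", "vas_6")] <- 0
    if (d < 12) df[i, c("utility_12", "vas_12")] <- 0
  }
  if (inherits(data, "trial_dataset")) {
    data$participants <- df
    data
  } else {
    df
  }
}

# accept either a trial_dataset or a bare participant data frame
participant_frame <- function(x) {
  if (inherits(x, "trial_dataset")) {
    return(x$participants)
  }
  if (is.data.frame(x)) {
    return(x)
  }
  stop("expected a trial_dataset or a participant data frame")
}

#' @export
print.trial_dataset <- function(x, ...) {
  tab <- table(x$participants$arm)
  cat(sprintf(
    "Synthetic trial dataset: %d participants (%s), seed %d\n",
    nrow(x$participants),
    paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
    x$meta$seed
  ))
  nmiss <- sum(is.na(x$participants))
  cat(sprintf(
    "  %d missing cells across %d columns; currency year %s\n",
    nmiss, ncol(x$participants), x$meta$currency_year
  ))
  invisible(x)
}

#' Write a trial dataset to disk
#'
#' Writes the participant table as CSV, the generator configuration as
#' YAML and the run metadata (seed, arms, currency year) as JSON into
#' `dir`.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    config = file.path(dir, "generator_config.yaml"),
    meta = file.path(dir, "meta.json")
  )
  utils::write.csv(dataset$participants, paths[["participants"]], row.names = FALSE)
  cfg <- dataset$config
  cfg$cost_means <- lapply(cfg$cost_means, function(m) {
    apply(m, 1, as.list, simplify = FALSE)
  })
  yaml::write_yaml(lapply(unclass(cfg), function(v) {
    if (is.matrix(v)) apply(v, 1, as.list, simplify = FALSE) else v
  }), paths[["config"]])
  jsonlite::write_json(dataset$meta, paths[["meta"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Read a participant table written by [write_trial_dataset()]
#'
#' @param path Path to a `participants.csv` file.
#' @return A participant data frame with `arm` restored as a factor.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$arm <- factor(df$arm, levels = c("NRT", "EC"))
  df$products_issued[is.na(df$products_issued)] <- ""
  df
}
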