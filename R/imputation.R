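#' Configuration of the chained-equation imputation
#'
#' @param m Number of imputations; the working rule sets it to roughly the
#'   highest percentage of missing data among the modelled variables
#'   (default 35).
#' @param k_neighbours Donor pool size for predictive mean matching: each
#'   missing entry receives an observed value donated by one of the
#'   `k_neighbours` cases closest in model-predicted mean.
#' @param max_iterations Number of chained-equation sweeps over the
#'   incomplete variables.
#' @param variables Character vector of variables entering the imputation
#'   model (targets and predictors). `NULL` uses every cost, utility,
#'   VAS and expense column plus the baseline covariates present in the
#'   data.
#' @param seed Optional integer seed; the imputation is reproducible
#'   from it.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(m = 35, k_neighbours = 10,
                              max_iterations = 10, variables = NULL,
                              seed = NULL) {
  stopifnot(m >= 2, k_neighbours >= 1, max_iterations >= 1)
  structure(
    list(
      m = m, k_neighbours = k_neighbours,
      max_iterations = max_iterations, variables = variables,
      seed = seed
    ),
    class = "imputation_config"
  )
}

default_imputation_variables <- function(df) {
  candidates <- c(
    grep("^cost_", names(df), value = TRUE),
    grep("^utility_", names(df), value = TRUE),
    grep("^vas_", names(df), value = TRUE),
    grep("^expenses_", names(df), value = TRUE),
    intersect(c("age", "male", "site", "ftcd", "free_rx"), names(df))
  )
  unique(candidates)
}

# one PMM update of a single variable within one arm's data
pmm_update <- function(dat, target, predictors, k) {
  obs <- !is.na(dat[[paste0(".orig_", target)]])
  f <- stats::reformulate(predictors, response = target)
  fit <- suppressWarnings(stats::lm(f, data = dat))
  pred <- suppressWarnings(stats::predict(fit, newdata = dat))
  y_obs <- dat[[target]][obs]
  p_obs <- pred[obs]
  for (i in which(!obs)) {
    d <- abs(p_obs - pred[i])
    donors <- order(d)[seq_len(min(k, length(d)))]
    dat[[target]][i] <- y_obs[donors[sample.int(length(donors), 1)]]
  }
  dat[[target]]
}

# chained-equation PMM on one arm's data frame; returns m completed copies
mice_pmm_arm <- function(df, config) {
  vars <- config$variables
  if (is.null(vars)) vars <- default_imputation_variables(df)
  vars <- intersect(vars, names(df))
  targets <- vars[vapply(vars, function(v) anyNA(df[[v]]), logical(1))]
  for (v in targets) {
    if (all(is.na(df[[v]]))) {
      stop("variable '", v, "' has no observed values: no donors available")
    }
    if (!is.numeric(df[[v]])) {
      stop("imputation targets must be numeric; '", v, "' is not")
    }
  }
  # monotone-rate ordering: most-observed first
  targets <- targets[order(vapply(targets, function(v) sum(is.na(df[[v]])), numeric(1)))]
  # remember original missingness, work on a copy with markers
  work0 <- df[, vars, drop = FALSE]
  for (v in targets) work0[[paste0(".orig_", v)]] <- df[[v]]

  lapply(seq_len(config$m), function(imp) {
    work <- work0
    for (v in targets) { # initialise from observed values
      na <- is.na(work[[v]])
      work[[v]][na] <- sample(work[[v]][!na], sum(na), replace = TRUE)
    }
    for (iter in seq_len(config$max_iterations)) {
      for (v in targets) {
        work[[v]] <- pmm_update(work, v, setdiff(vars, v), config$k_neighbours)
      }
    }
    out <- df
    for (v in targets) out[[v]] <- work[[v]]
    out
  })
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills the missing follow-up data of a trial dataset by chained
#' equations run separately within each treatment arm. Each incomplete
#' variable is regressed (least squares) on all other model variables
#' using the currently completed data; every missing entry then receives
#' an *observed* value donated by one of the `k_neighbours` cases whose
#' model-predicted means are closest to its own (predictive mean
#' matching), so imputed values never leave the observed support. The
#' sweep over variables — most-observed first — is repeated
#' `max_iterations` times, and the whole procedure `m` times to produce
#' `m` completed datasets. Quit status is never imputed (participants
#' lost to follow-up are classified as smokers upstream).
#'
#' @param data A `trial_dataset` or participant data frame with an `arm`
#'   column; missingness must be confined to the modelled variables.
#' @param config An [imputation_config()].
#' @return An object of class `mice_result`: list with `imputations` (a
#'   list of `m` completed data frames, rows in the original order),
#'   `config`, and `missing_pattern` (per-variable missing counts).
#' @examples
#' td <- generate_trial(generator_config(
#'   n_per_arm = c(NRT = 60, EC = 60),
#'   seed = 3
#' ))
#' mi <- mice_pmm(td, imputation_config(m = 3, max_iterations = 2, seed = 1))
#' sum(is.na(mi$imputations[[1]][, sapply(mi$imputations[[1]], is.numeric)]))
#' @export
mice_pmm <- function(data, config = imputation_config()) {
  df <- participant_frame(data)
  stopifnot(inherits(config, "imputation_config"), "arm" %in% names(df))
  if (!is.null(config$seed)) set.seed(config$seed)
  vars <- config$variables
  if (is.null(vars)) vars <- default_imputation_variables(df)
  other <- setdiff(names(df), vars)
  bad <- other[vapply(other, function(v) anyNA(df[[v]]) && v != "death_month", logical(1))]
  if (length(bad) > 0) {
    stop(
      "missing values outside the imputation model variables: ",
      paste(bad, collapse = ", ")
    )
  }
  arms <- split(seq_len(nrow(df)), df$arm)
  per_arm <- lapply(arms, function(idx) {
    mice_pmm_arm(df[idx, , drop = FALSE], config)
  })
  # restore the original row order
  ord <- order(unlist(arms, use.names = FALSE))
  imputations <- lapply(seq_len(config$m), function(i) {
    stacked <- do.call(rbind, lapply(per_arm, `[[`, i))
    stacked[ord, , drop = FALSE]
  })
  structure(
    list(
      imputations = imputations,
      config = config,
      missing_pattern = vapply(df[vars], function(x) sum(is.na(x)), numeric(1))
    ),
    class = "mice_result"
  )
}

#' @export
print.mice_result <- function(x, ...) {
  cat(sprintf(
    "Multiply imputed dataset: m = %d, PMM with %d nearest neighbours\n",
    x$config$m, x$config$k_neighbours
  ))
  mp <- x$missing_pattern[x$missing_pattern > 0]
  if (length(mp) > 0) {
    cat("  imputed variables (missing counts):\n")
    for (v in names(mp)) cat(sprintf("    %s: %d\n", v, mp[[v]]))
  } else {
    cat("  no missing values; completed datasets equal the input\n")
  }
  invisible(x)
}

#' Write multiply imputed datasets as one long-format CSV
#'
#' Stacks the `m` completed datasets with an `.imp` imputation index
#' column, the layout conventionally used to exchange multiply imputed
#' data.
#'
#' @param mi A `mice_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_imputations_csv <- function(mi, path) {
  stopifnot(inherits(mi, "mice_result"))
  long <- do.call(rbind, lapply(seq_along(mi$imputations), function(i) {
    cbind(.imp = i, mi$imputations[[i]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; its
#' total variance is `T = W + (1 + 1/m) B`, where `W` is the mean
#' within-imputation variance and `B` the between-imputation variance of
#' the estimates. Confidence intervals use a t reference with the Rubin
#' degrees of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when
#' `B = 0`).
#'
#' @param estimates Numeric vector of per-imputation estimates (length
#'   `m >= 2`).
#' @param variances Numeric vector of their squared standard errors, same
#'   length.
#' @param conf_level Confidence level.
#' @return An object of class `pooled_estimate`: list with `estimate`,
#'   `within_variance`, `between_variance`, `total_variance`, `df`,
#'   `ci_low`, `ci_high`, `m`.
#' @examples
#' pool_rubin(c(1, 3), c(1, 1)) # pooled 2, W = 1, B = 2, T = 4
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (length(variances) != m) {
    stop("'estimates' and 'variances' must have the same length")
  }
  stopifnot(m >= 2, all(is.finite(estimates)), all(variances >= 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  alpha <- 1 - conf_level
  half <- stats::qt(1 - alpha / 2, df) * sqrt(total)
  structure(
    list(
      estimate = qbar, within_variance = W, between_variance = B,
      total_variance = total, df = df,
      ci_low = qbar - half, ci_high = qbar + half, m = m
    ),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate %.4g (95%% CI %.4g to %.4g), m = %d\n",
    x$estimate, x$ci_low, x$ci_high, x$m
  ))
  cat(sprintf(
    "  W = %.4g, B = %.4g, T = %.4g, df = %.4g\n",
    x$within_variance, x$between_variance, x$total_variance, x$df
  ))
  invisible(x)
}
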