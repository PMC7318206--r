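#' Unit costs of treatment delivery
#'
#' Unit costs (2015/16 pounds) used to turn session and product logs into
#' per-participant treatment costs: staff time for behavioural support
#' sessions, e-cigarette starter kits and consumables, printed materials,
#' the prescription charge, and the per-item cost (weighted net ingredient
#' cost plus dispensing fee) of each nicotine replacement product form.
#' Session 1 and 2 last 30 minutes each and later sessions 20 minutes.
#'
#' The product identifiers recognised in participant product logs are the
#' names of `nrt_item_costs` plus `"ec_kit"`, `"ec_kit_2016"`,
#' `"ec_liquid_extra"` and `"lor"` (a letter of recommendation for
#' pharmacy supply; each issue adds its print cost, and the recommended
#' product appears in the log as an ordinary NRT item since all letters
#' are assumed redeemed).
#'
#' @param adviser_rate,trainer_rate Staff cost per hour (salary on-costs,
#'   overheads and capital included).
#' @param demo_kit Demonstration e-cigarette kit cost per trained adviser.
#' @param ec_kit,ec_kit_2016 Starter kit cost (original and the 2016
#'   replacement device), liquid included.
#' @param extra_liquid Additional 10 ml e-liquid bottle.
#' @param info_sheet,pharmacy_list,lor_print Printing costs: e-cigarette
#'   information sheet (per EC participant), pharmacy list (per NRT
#'   participant), letter of recommendation (per issue).
#' @param rx_charge Prescription charge per item, payable by
#'   non-exempt participants.
#' @param session_minutes Scheduled minutes of each weekly support
#'   session, in session order.
#' @param nrt_item_costs Named vector of per-item NRT costs by product
#'   form.
#' @return An object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(adviser_rate = 37,
                            trainer_rate = 42,
                            demo_kit = 19.35,
                            ec_kit = 19.35,
                            ec_kit_2016 = 30.54,
                            extra_liquid = 1.34,
                            info_sheet = 0.09,
                            pharmacy_list = 0.05,
                            lor_print = 0.01,
                            rx_charge = 8.2,
                            session_minutes = c(30, 30, 20, 20, 20, 20),
                            nrt_item_costs = c(
                              patch = 10.50, gum = 8.40, lozenge = 12.10,
                              inhalator = 15.30, spray = 14.20,
                              microtab = 9.80
                            )) {
  x <- structure(
    list(
      adviser_rate = adviser_rate, trainer_rate = trainer_rate,
      demo_kit = demo_kit, ec_kit = ec_kit, ec_kit_2016 = ec_kit_2016,
      extra_liquid = extra_liquid, info_sheet = info_sheet,
      pharmacy_list = pharmacy_list, lor_print = lor_print,
      rx_charge = rx_charge, session_minutes = session_minutes,
      nrt_item_costs = nrt_item_costs
    ),
    class = "unit_cost_table"
  )
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all unit costs must be finite and non-negative")
  }
  x
}

# per-unit cost of every product id the log may contain
product_price_table <- function(uc) {
  c(
    uc$nrt_item_costs,
    ec_kit = uc$ec_kit, ec_kit_2016 = uc$ec_kit_2016,
    ec_liquid_extra = uc$extra_liquid, lor = uc$lor_print,
    info_sheet = uc$info_sheet, pharmacy_list = uc$pharmacy_list
  )
}

# log entries that are printed materials rather than therapy products
PRINTABLE_IDS <- c("info_sheet", "pharmacy_list", "lor")

# "patch:4;gum:6" -> named numeric c(patch = 4, gum = 6)
parse_product_log <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  qty <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  stats::setNames(qty, vapply(parts, `[[`, character(1), 1))
}

# cost of one participant's product log; errors on unknown ids.
# `keep` restricts to a subset of ids (after the unknown-id check).
product_log_cost <- function(s, prices, keep = NULL) {
  q <- parse_product_log(s)
  if (length(q) == 0) {
    return(0)
  }
  unknown <- setdiff(names(q), names(prices))
  if (length(unknown) > 0) {
    stop(
      "unknown product id in product log: ",
      paste(unknown, collapse = ", ")
    )
  }
  if (!is.null(keep)) q <- q[names(q) %in% keep]
  if (length(q) == 0) {
    return(0)
  }
  sum(q * prices[names(q)])
}

session_cost <- function(sessions, uc) {
  cum_min <- cumsum(uc$session_minutes)
  k <- pmin(sessions, length(uc$session_minutes))
  mins <- ifelse(k == 0, 0, cum_min[pmax(k, 1)]) * (k > 0)
  mins / 60 * uc$adviser_rate
}

#' Per-participant treatment cost from session and product logs
#'
#' Treatment cost is the sum of the arm's training share, adviser time for
#' the behavioural support sessions attended, and everything issued on
#' record in the product log: starter kits, e-liquid, NRT items, and
#' printed materials (information sheets, pharmacy lists, letters of
#' recommendation). Only sessions attended and items on record are
#' costed; a participant who attended nothing and received nothing costs
#' exactly the arm's training share.
#'
#' @param data A `trial_dataset` or participant data frame with columns
#'   `arm`, `sessions_attended` and `products_issued` (a
#'   `"id:qty;id:qty"` log string).
#' @param unit_costs A [unit_cost_table()].
#' @param training_cost_pp Named per-participant training cost by arm.
#'   Training applied to the e-cigarette arm only; the comparator uses
#'   staff already trained on the job.
#' @return Numeric vector of per-participant treatment costs (pounds).
#' @examples
#' df <- data.frame(
#'   arm = "NRT", sessions_attended = 2,
#'   products_issued = "", stringsAsFactors = FALSE
#' )
#' treatment_cost(df) # 1 hour of adviser time: £37
#' @export
treatment_cost <- function(data, unit_costs = unit_cost_table(),
                           training_cost_pp = c(NRT = 0, EC = 4.40)) {
  df <- participant_frame(data)
  stopifnot(
    all(c("arm", "sessions_attended", "products_issued") %in% names(df))
  )
  uc <- unit_costs
  prices <- product_price_table(uc)
  arm <- as.character(df$arm)
  training <- unname(training_cost_pp[arm])
  sess <- session_cost(df$sessions_attended, uc)
  prod <- vapply(df$products_issued, product_log_cost,
    numeric(1),
    prices = prices, USE.NAMES = FALSE
  )
  training + sess + prod
}

#' Decomposed per-participant treatment cost
#'
#' Same accounting as [treatment_cost()], returned component by component.
#'
#' @inheritParams treatment_cost
#' @return Data frame with columns `training`, `sessions`, `products`,
#'   `printables` and `total`.
#' @export
treatment_cost_components <- function(data, unit_costs = unit_cost_table(),
                                      training_cost_pp = c(NRT = 0, EC = 4.40)) {
  df <- participant_frame(data)
  uc <- unit_costs
  prices <- product_price_table(uc)
  arm <- as.character(df$arm)
  therapy_ids <- setdiff(names(prices), PRINTABLE_IDS)
  out <- data.frame(
    training = unname(training_cost_pp[arm]),
    sessions = session_cost(df$sessions_attended, uc),
    products = vapply(df$products_issued, product_log_cost,
      numeric(1),
      prices = prices, keep = therapy_ids, USE.NAMES = FALSE
    ),
    printables = vapply(df$products_issued, product_log_cost,
      numeric(1),
      prices = prices, keep = PRINTABLE_IDS, USE.NAMES = FALSE
    )
  )
  out$total <- rowSums(out)
  out
}

#' QALYs by area under the utility curve
#'
#' Quality-adjusted life-years over a 12-month period from utility values
#' measured at 0, 6 and 12 months, by the trapezium rule expressed in
#' years: `0.25 * u0 + 0.5 * u6 + 0.25 * u12`.
#'
#' @param u0,u6,u12 Utility values at baseline, 6 and 12 months
#'   (vectorised). Utilities below 0 (states worse than death) are
#'   allowed.
#' @param .allow_na Return `NA` for incomplete profiles instead of
#'   erroring; the analysis pipeline imputes utilities before QALYs are
#'   modelled.
#' @return QALYs accrued over the year.
#' @examples
#' qaly_auc(0.8, 0.9, 1.0) # 0.9
#' @export
qaly_auc <- function(u0, u6, u12, .allow_na = FALSE) {
  if (!.allow_na && (anyNA(u0) || anyNA(u6) || anyNA(u12))) {
    stop("missing utility value; impute utilities before computing QALYs")
  }
  0.5 * (u0 + u6) / 2 + 0.5 * (u6 + u12) / 2
}

#' Participants' own expenses on smoking cessation, by arm
#'
#' Descriptive per-arm summary (mean and standard error of the mean) of
#' what participants spent themselves over the 12 months: over-the-counter
#' and prescribed NRT, e-cigarette purchases including refills, and
#' prescription charges. No hypothesis test is attached; the comparison is
#' descriptive.
#'
#' @param data A `trial_dataset` or participant data frame with columns
#'   `arm`, `expenses_nrt`, `expenses_ec`, `expenses_rx_charge`.
#' @return Data frame with one row per arm and expense category:
#'   `arm`, `category`, `n`, `mean`, `se` (SE is `NA` when `n < 2`).
#' @export
summarize_expenses <- function(data) {
  df <- participant_frame(data)
  cats <- c(
    nrt = "expenses_nrt", ec = "expenses_ec",
    rx_charge = "expenses_rx_charge"
  )
  stopifnot(all(cats %in% names(df)))
  rows <- lapply(levels(factor(df$arm)), function(a) {
    sub <- df[df$arm == a, , drop = FALSE]
    do.call(rbind, lapply(names(cats), function(cat) {
      x <- sub[[cats[[cat]]]]
      x <- x[!is.na(x)]
      n <- length(x)
      data.frame(
        arm = a, category = cat, n = n,
        mean = if (n > 0) mean(x) else NA_real_,
        se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_
      )
    }))
  })
  tot <- lapply(levels(factor(df$arm)), function(a) {
    sub <- df[df$arm == a, , drop = FALSE]
    x <- rowSums(sub[, cats, drop = FALSE])
    x <- x[!is.na(x)]
    n <- length(x)
    data.frame(
      arm = a, category = "total", n = n,
      mean = if (n > 0) mean(x) else NA_real_,
      se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_
    )
  })
  out <- rbind(do.call(rbind, rows), do.call(rbind, tot))
  out[order(out$arm, out$category), ]
}

#' Read or write a unit cost table as YAML
#'
#' @param path Path to a YAML file; the packaged fixture is
#'   `system.file("extdata", "unit_costs.yaml", package = "quitcea")`.
#' @return `read_unit_costs()` returns a [unit_cost_table()];
#'   `write_unit_costs()` invisibly returns `path`.
#' @export
read_unit_costs <- function(path) {
  y <- yaml::read_yaml(path)
  unit_cost_table(
    adviser_rate = y$adviser_rate, trainer_rate = y$trainer_rate,
    demo_kit = y$demo_kit, ec_kit = y$ec_kit,
    ec_kit_2016 = y$ec_kit_2016, extra_liquid = y$extra_liquid,
    info_sheet = y$info_sheet, pharmacy_list = y$pharmacy_list,
    lor_print = y$lor_print, rx_charge = y$rx_charge,
    session_minutes = as.numeric(y$session_minutes),
    nrt_item_costs = unlist(y$nrt_item_costs)
  )
}

#' @rdname read_unit_costs
#' @param unit_costs A [unit_cost_table()].
#' @export
write_unit_costs <- function(unit_costs, path) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  y <- unclass(unit_costs)
  y$nrt_item_costs <- as.list(y$nrt_item_costs)
  yaml::write_yaml(y, path)
  invisible(path)
}
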