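# small generator configurations used across tests

small_config <- function(seed = 1, ...) {
  generator_config(n_per_arm = c(NRT = 60, EC = 60), seed = seed, ...)
}

# a null configuration: the two arms generated from identical settings
# (same quit rate, same cost/utility/expense means), so every true
# between-arm difference is zero
null_config <- function(n = 500, seed = 1, ...) {
  cm <- default_cost_means()
  cm$EC <- cm$NRT
  um <- default_utility_means()
  um$EC <- um$NRT
  em <- default_expense_means()
  em$EC <- em$NRT
  generator_config(
    n_per_arm = c(NRT = n, EC = n),
    quit_rate = c(NRT = 0.12, EC = 0.12),
    sessions_mean = c(NRT = 5.2, EC = 5.2),
    sessions_sd = c(NRT = 1.2, EC = 1.2),
    cost_means = cm, utility_means = um, expense_means = em,
    seed = seed, ...
  )
}

# a handful of hand-built participants for the costing/zeroing contracts
toy_participants <- function() {
  data.frame(
    id = 1:3,
    arm = factor(c("NRT", "NRT", "EC"), levels = c("NRT", "EC")),
    age = c(40, 55, 33), male = c(1, 0, 1), site = c(1, 2, 3),
    ftcd = c(5, 7, 4), free_rx = c(0, 1, 0),
    sessions_attended = c(2, 0, 6),
    products_issued = c("patch:2;gum:1", "", "ec_kit:1;info_sheet:1"),
    cost_cessation_baseline = c(10, 0, 5),
    cost_cessation_0_6 = c(20, 30, 0),
    cost_cessation_6_12 = c(5, 10, 15),
    cost_healthcare_baseline = c(100, 200, 50),
    cost_healthcare_0_6 = c(300, 10, 40),
    cost_healthcare_6_12 = c(50, 60, 70),
    utility_0 = c(0.8, 0.7, 0.9),
    utility_6 = c(0.85, 0.75, 0.92),
    utility_12 = c(0.9, 0.8, 0.95),
    vas_0 = c(70, 60, 80), vas_6 = c(72, 65, 85), vas_12 = c(75, 70, 90),
    expenses_nrt = c(50, 100, 0),
    expenses_ec = c(0, 10, 150),
    expenses_rx_charge = c(8.2, 0, 0),
    quit_12m = c(0, 0, 1), died = c(0, 0, 0),
    death_month = c(NA_integer_, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE
  )
}
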