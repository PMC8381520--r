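# Shared fixture builders (everything generated in code).

# Minimal record frame for the estimator functions.
records <- function(time, status) {
  data.frame(time_years = time, status = status, stringsAsFactors = FALSE)
}

# Quick single-construct registry.
quick_registry <- function(time, status, brand = "Duracon",
                           fixation = "cemented", bearing = "fixed",
                           constraint = "CR", gender = "unknown") {
  n <- length(time)
  tkr_registry(
    procedure_id = sprintf("%s-%03d", brand, seq_len(n)),
    brand = brand, fixation = fixation, bearing = bearing,
    constraint = constraint, gender = gender,
    time_years = time, status = status
  )
}

# Random small record set for oracle comparisons.
random_records <- function(n) {
  records(
    time = round(stats::runif(n, 0.1, 10), 3),
    status = sample(c("revision", "death", "censored"), n, replace = TRUE,
                    prob = c(0.4, 0.2, 0.4))
  )
}

# Two-construct registry with exponential revision times, all follow-up
# administratively truncated beyond t_eval (so no censoring before t_eval
# unless a death hazard is given).
two_arm_config <- function(lambda_ref, lambda_comp, n_per_arm = 1100,
                           admin_years = 15, death_hazard = 0, seed = 1) {
  registry_config(list(
    construct_scenario("RefBrand", "cemented", "fixed", "CR", n = n_per_arm,
                       revision_hazard = lambda_ref,
                       death_hazard = death_hazard,
                       enrol_window = c(admin_years, admin_years)),
    construct_scenario("CompBrand", "cemented", "fixed", "PS", n = n_per_arm,
                       revision_hazard = lambda_comp,
                       death_hazard = death_hazard,
                       enrol_window = c(admin_years, admin_years))
  ), seed = seed)
}

# Greenwood-based estimate from survival::survfit, used as the
# independent product-limit oracle in tests.
survfit_oracle <- function(rec, t) {
  fit <- survival::survfit(
    survival::Surv(rec$time_years, rec$status == "revision") ~ 1,
    conf.type = "plain"
  )
  s <- summary(fit, times = t, extend = TRUE)
  list(failure = 1 - s$surv, variance = s$std.err^2)
}
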