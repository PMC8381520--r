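est_row <- function(construct, failure, n_at_risk) {
  data.frame(construct = construct, t_years = 3, n_at_risk = n_at_risk,
             failure = failure, se = 0.001, ci_low = failure - 0.002,
             ci_high = failure + 0.002, variance = 1e-6,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

test_that("reference selection takes the lowest failure above the at-risk floor", {
  ests <- rbind(est_row("A", 0.012, 3201), est_row("B", 0.010, 800),
                est_row("C", 0.015, 2000))
  expect_equal(select_reference(ests, 1000), "A")  # B under threshold
  ests2 <- rbind(est_row("A", 0.012, 1500), est_row("B", 0.012, 2500))
  expect_equal(select_reference(ests2, 1000), "B")  # tie broken on n
  ests3 <- rbind(est_row("B", 0.012, 1500), est_row("A", 0.012, 1500))
  expect_equal(select_reference(ests3, 1000), "A")  # then on label
  expect_error(select_reference(rbind(est_row("A", 0.01, 999)), 1000),
               "1000")
})

test_that("comparator eligibility applies the at-risk floor and drops the reference", {
  ests <- rbind(est_row("Ref", 0.01, 3000), est_row("B", 0.02, 500),
                est_row("C", 0.02, 499), est_row("D", 0.03, 5000))
  out <- eligible_comparators(ests, "Ref", 500)
  expect_setequal(out$construct, c("B", "D"))
  only_ref <- eligible_comparators(rbind(est_row("Ref", 0.01, 3000)),
                                   "Ref", 500)
  expect_equal(nrow(only_ref), 0L)
})

test_that("margins are 20% and 100% of the reference failure", {
  m <- margins_from_reference(0.0122)
  expect_equal(m$m20, 0.00244)
  expect_equal(m$m100, 0.0122)
  m2 <- margins_from_reference(0.0258)
  expect_equal(m2$m20, 0.00516)
  expect_equal(m2$m100, 0.0258)
  m0 <- margins_from_reference(0)
  expect_true(m0$degenerate)
  expect_equal(c(m0$m20, m0$m100), c(0, 0))
})

test_that("the Wald difference test matches hand arithmetic", {
  comp <- list(failure = 0.05, variance = 0.01^2)
  ref <- list(failure = 0.02, variance = 0.005^2)
  dt <- difference_test(comp, ref)
  expect_equal(dt$diff, 0.03)
  expect_equal(dt$se_diff, 0.011180, tolerance = 1e-4)
  expect_equal(dt$ci_low, 0.008087, tolerance = 1e-4)
  expect_equal(dt$ci_high, 0.051913, tolerance = 1e-4)
  expect_equal(dt$z, 2.6833, tolerance = 1e-4)
  expect_equal(dt$p, 2 * pnorm(-2.68328), tolerance = 1e-4)
})

test_that("degenerate difference cases are handled explicitly", {
  same <- list(failure = 0.02, variance = 1e-5)
  dt <- difference_test(same, same)
  expect_equal(dt$diff, 0)
  expect_equal(dt$z, 0)
  expect_equal(dt$p, 1)
  zero <- list(failure = 0, variance = 0)
  dt0 <- difference_test(zero, zero)
  expect_equal(c(dt0$diff, dt0$z), c(0, 0))
  expect_equal(dt0$p, 1)
  flagged <- difference_test(list(failure = 0.1, variance = 0), zero)
  expect_true(flagged$degenerate)
})

test_that("the four hand-worked intervals map to their categories", {
  m <- margins_from_reference(0.0122)
  expect_equal(classify(0.015, 0.030, m), "inferior_100")
  expect_equal(classify(-0.001, 0.002, m), "noninferior_20")
  expect_equal(classify(0.003, 0.040, m), "inferior_20")
  expect_equal(classify(0.001, 0.020, m), "inconclusive")
})

test_that("classification is exhaustive, exclusive, and internally consistent", {
  set.seed(99)
  cats <- c("inferior_100", "inferior_20", "inconclusive",
            "noninferior_100", "noninferior_20")
  seen <- character(0)
  for (i in 1:2000) {
    m <- margins_from_reference(runif(1, 0.001, 0.2))
    centre <- runif(1, -0.1, 0.4)
    half <- runif(1, 0, 0.15)
    cat_i <- classify(centre - half, centre + half, m)
    expect_true(cat_i %in% cats)
    # consistency with the margin geometry
    if (cat_i == "inferior_100") expect_gt(centre - half, m$m20)
    if (cat_i == "noninferior_20") expect_lt(centre + half, m$m100)
    seen <- union(seen, cat_i)
  }
  expect_setequal(seen, cats)  # all five bands reachable
})

test_that("a construct compared with itself is noninferior when margins allow", {
  # wide margins relative to the CI half-width: self-comparison lands in
  # the tightest noninferiority band
  m <- margins_from_reference(0.05)
  dt <- difference_test(list(failure = 0.05, variance = 1e-6),
                        list(failure = 0.05, variance = 1e-6))
  expect_equal(classify(dt$ci_low, dt$ci_high, m), "noninferior_20")
})

test_that("the pipeline classifies a truly bad construct inferior and keeps the forced reference", {
  cfg <- two_arm_config(lambda_ref = -log(0.98) / 10,
                        lambda_comp = 3 * -log(0.98) / 10,
                        n_per_arm = 1500, seed = 5)
  # make the comparator ineligible as reference by shrinking its cohort
  cfg$scenarios[[2]]$n <- 900L
  reg <- generate_registry(cfg)
  fit <- tkr_benchmark(reg, timepoints = 10)
  rep10 <- fit$reports[[1]]
  expect_equal(rep10$reference, "RefBrand/Fixed/Cemented/CR")
  expect_equal(nrow(rep10$rows), 1L)
  expect_match(rep10$rows$category, "^inferior")
})

test_that("time points with no qualifying reference are skipped, not fatal", {
  cfg <- two_arm_config(lambda_ref = 0.002, lambda_comp = 0.004,
                        n_per_arm = 1200, admin_years = 8, seed = 3)
  reg <- generate_registry(cfg)
  # at 10 years everyone is administratively censored at 8 -> no reference
  expect_message(fit <- tkr_benchmark(reg, timepoints = c(5, 10)),
                 "skipping")
  expect_equal(length(fit$reports), 1L)
  expect_equal(fit$reports[[1]]$t, 5)
  expect_true(grepl("10y", names(fit$skipped)))
})

test_that("gender stratification recomputes the reference within each stratum", {
  cfg <- two_arm_config(lambda_ref = 0.002, lambda_comp = 0.006,
                        n_per_arm = 3000, seed = 9)
  reg <- generate_registry(cfg)
  fit <- tkr_benchmark(reg, timepoints = 10, stratify_by = "gender")
  strata <- vapply(fit$reports, `[[`, character(1), "stratum")
  expect_setequal(unique(strata), c("all", "F", "M"))
  for (r in fit$reports) {
    expect_equal(r$reference, "RefBrand/Fixed/Cemented/CR")
    expect_match(r$rows$category[1], "^inferior")
  }
})

test_that("the flattened fit matches the export schema and survives a round trip", {
  cfg <- two_arm_config(lambda_ref = 0.002, lambda_comp = 0.004,
                        n_per_arm = 1500, seed = 13)
  reg <- generate_registry(cfg)
  fit <- tkr_benchmark(reg, timepoints = c(5, 10))
  df <- as.data.frame(fit)
  expect_equal(names(df),
               c("t_years", "stratum", "reference", "ref_failure",
                 "ref_ci_low", "ref_ci_high", "construct", "n_at_risk",
                 "failure", "diff", "se_diff", "ci_low", "ci_high", "z",
                 "p", "category"))
  expect_true(all(df$ci_low <= df$diff & df$diff <= df$ci_high))
  path <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_csv(fit, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$category, df$category)
})
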