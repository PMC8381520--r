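test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- nzjr_like_scenario(seed = 4)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # and byte-identical on disk
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(r1, p1); write_registry(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("appending a scenario does not perturb earlier substreams", {
  base <- registry_config(list(
    construct_scenario("A", "cemented", "fixed", "CR", n = 50,
                       revision_hazard = 0.05, death_hazard = 0.01)
  ), seed = 2)
  extended <- registry_config(c(base$scenarios, list(
    construct_scenario("B", "cemented", "fixed", "PS", n = 50,
                       revision_hazard = 0.05)
  )), seed = 2)
  r_base <- generate_registry(base)
  r_ext <- generate_registry(extended)
  a_only <- as.data.frame(r_ext)[r_ext$brand == "A",
                                 c("time_years", "status")]
  rownames(a_only) <- NULL
  expect_equal(a_only, as.data.frame(r_base)[, c("time_years", "status")])
})

test_that("zero hazards give only administrative censoring; huge hazards only revisions", {
  quiet <- registry_config(list(
    construct_scenario("A", "cemented", "fixed", "CR", n = 200,
                       revision_hazard = 0, death_hazard = 0,
                       enrol_window = c(10, 2))
  ), seed = 6)
  reg <- generate_registry(quiet)
  expect_true(all(reg$status == "censored"))
  expect_true(all(reg$time_years >= 2 & reg$time_years <= 10))

  loud <- registry_config(list(
    construct_scenario("A", "cemented", "fixed", "CR", n = 200,
                       revision_hazard = 100, death_hazard = 0,
                       enrol_window = c(10, 1))
  ), seed = 6)
  reg2 <- generate_registry(loud)
  expect_gt(mean(reg2$status == "revision"), 0.99)
})

test_that("the closed-form net failure matches its definition", {
  sc <- construct_scenario("A", "cemented", "fixed", "CR", n = 10,
                           revision_hazard = 0.01)
  expect_equal(true_net_failure(sc, 10), 1 - exp(-0.1))
  expect_equal(true_net_failure(sc, 0), 0)
  sc0 <- construct_scenario("A", "cemented", "fixed", "CR", n = 10,
                            revision_hazard = 0)
  expect_equal(true_net_failure(sc0, 50), 0)
  scw <- construct_scenario("A", "cemented", "fixed", "CR", n = 10,
                            revision_hazard = 0.05, shape = 1.5)
  expect_equal(true_net_failure(scw, 4), 1 - exp(-(0.05 * 4)^1.5))
})

test_that("invalid scenario parameters are rejected", {
  expect_error(construct_scenario("A", "cemented", "fixed", "CR", n = 0,
                                  revision_hazard = 0.01))
  expect_error(construct_scenario("A", "cemented", "fixed", "CR", n = 10,
                                  revision_hazard = -1))
  expect_error(construct_scenario("A", "cemented", "fixed", "CR", n = 10,
                                  revision_hazard = 0.01,
                                  enrol_window = c(2, 5)))
  expect_error(registry_config(list()))
})

test_that("1-KM recovers the true exponential failure across replicates", {
  lambda <- -log(0.95) / 10  # 5% failure at 10 years
  sc <- construct_scenario("A", "cemented", "fixed", "CR", n = 400,
                           revision_hazard = lambda, death_hazard = 0.01,
                           enrol_window = c(15, 11))
  cfg <- registry_config(list(sc), seed = 1)
  ests <- vapply(1:100, function(i) {
    reg <- generate_registry(cfg, seed = 1000 + i)
    km_net_failure(as.data.frame(reg), 10)$failure
  }, numeric(1))
  truth <- true_net_failure(sc, 10)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * mc_se)
})

test_that("the demo scenario has a reference-grade construct near 1.2% at 3 years", {
  cfg <- nzjr_like_scenario(seed = 1)
  expect_equal(length(cfg$scenarios), 25L)
  ref_sc <- cfg$scenarios[[1]]
  expect_equal(ref_sc$label, "Duracon/Fixed/Cemented/CR")
  expect_equal(true_net_failure(ref_sc, 3), 0.012, tolerance = 1e-10)
  others <- vapply(cfg$scenarios[-1], true_net_failure, numeric(1), t = 3)
  expect_true(all(others > true_net_failure(ref_sc, 3)))
  # one construct is built with triple the reference hazard
  mults <- vapply(cfg$scenarios, `[[`, numeric(1), "revision_hazard") /
    ref_sc$revision_hazard
  expect_true(any(abs(mults - 3) < 1e-12))
})
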