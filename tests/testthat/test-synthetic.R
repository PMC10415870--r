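test_that("the generator is deterministic given a seed and yields valid data", {
  s1 <- simulate_network(seed = 61)
  s2 <- simulate_network(seed = 61)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_silent(validate_trials(s1))
  expect_equal(dplyr::n_distinct(s1$study_id), 18L)
  # paper geometry reproduces the example network's edge set
  expect_equal(network_edges(s1)[, c("treat1", "treat2")],
               network_edges(pwv_trials())[, c("treat1", "treat2")])
  s3 <- simulate_network(seed = 62)
  expect_false(identical(s1$change_mean, s3$change_mean))
})

test_that("the noiseless limit returns the true contrasts", {
  syn <- simulate_network(design = "star", n_studies = 6,
                          d_true = c(GLP1RA = -1.2, SGLT2i = -0.5),
                          tau_true = 0, arm_sd_range = c(1e-4, 2e-4),
                          seed = 63)
  ct <- build_contrasts(syn)
  truth <- ifelse(ct$treat == "GLP1RA", -1.2, -0.5)
  expect_equal(ct$md, truth, tolerance = 1e-3)
})

test_that("the spread of simulated contrasts matches sqrt(se^2 + tau^2)", {
  tau <- 0.5
  se2 <- 2^2 / 50 + 2^2 / 50
  set.seed(64)
  mds <- replicate(1000, {
    syn <- simulate_network(design = "star", n_studies = 1,
                            d_true = c(GLP1RA = -1), tau_true = tau,
                            n_per_arm = c(50, 50), arm_sd_range = c(2, 2))
    build_contrasts(syn)$md
  })
  expect_equal(sd(mds), sqrt(se2 + tau^2), tolerance = 0.05 * sqrt(se2 + tau^2))
  expect_equal(mean(mds), -1, tolerance = 3 * sqrt((se2 + tau^2) / 1000))
})

test_that("planted inconsistency shifts exactly the targeted edge", {
  syn <- simulate_network(tau_true = 0, arm_sd_range = c(1e-4, 2e-4),
                          inconsistency_offset = c("SGLT2i|placebo" = 2),
                          seed = 65)
  ct <- build_contrasts(syn)
  on_edge <- ct$treat == "SGLT2i" & ct$comparator == "placebo"
  d <- sim_truth(syn)$d_true
  expect_equal(ct$md[on_edge], rep(d[["SGLT2i"]] + 2, sum(on_edge)),
               tolerance = 1e-3)
  off_edge <- ct$treat == "GLP1RA" & ct$comparator == "placebo"
  expect_equal(ct$md[off_edge], rep(d[["GLP1RA"]], sum(off_edge)),
               tolerance = 1e-3)
})

test_that("random connected designs stay connected", {
  for (seed in 71:75) {
    syn <- simulate_network(design = "random_connected", n_studies = 10,
                            seed = seed)
    expect_silent(validate_trials(syn))
  }
})

test_that("recovery scoring computes bias, rmse and coverage", {
  est <- tibble::tibble(
    treatment = rep(c("GLP1RA", "SGLT2i"), each = 3),
    estimate = c(-1.0, -1.2, -1.1, -0.5, -0.4, -0.6),
    conf.low = c(-2, -2, -2, -1, -1, -0.45),
    conf.high = c(0, 0, -1.15, 0, 0, 0)
  )
  truth <- c(GLP1RA = -1.1, SGLT2i = -0.5)
  sc <- score_recovery(est, truth)
  expect_equal(sc$bias[sc$treatment == "GLP1RA"], 0, tolerance = 1e-12)
  expect_equal(sc$ci_coverage[sc$treatment == "GLP1RA"], 2 / 3)
  expect_equal(sc$ci_coverage[sc$treatment == "SGLT2i"], 2 / 3)
  expect_equal(sc$rmse[sc$treatment == "SGLT2i"],
               sqrt(mean(c(0, 0.1, -0.1)^2)), tolerance = 1e-12)
  expect_error(score_recovery(dplyr::mutate(est, treatment = "TZD"), truth),
               "no truth")
})

test_that("truth defaults mirror the frozen example-network posterior", {
  def <- sim_defaults()
  expect_setequal(names(def$d_true),
                  setdiff(pwv_treatments()$code, "placebo"))
  expect_gt(def$tau_true, 0)
  syn <- simulate_network(seed = 66)
  expect_identical(sim_truth(syn)$d_true, def$d_true)
})
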