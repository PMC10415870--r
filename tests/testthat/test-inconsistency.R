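test_that("the example network contains exactly the six expected loops", {
  loops <- enumerate_loops(pwv_trials())
  expect_equal(nrow(loops), 6L)
  sets <- lapply(loops$treatments, sort)
  expected <- list(
    c("GLP1RA", "SGLT2i", "placebo"),
    c("GLP1RA", "metformin", "placebo"),
    c("DPP4i", "metformin", "placebo"),
    c("TZD", "metformin", "placebo"),
    c("DPP4i", "SU", "TZD", "placebo"),
    c("DPP4i", "SU", "TZD", "metformin")
  )
  for (e in expected) {
    expect_true(any(vapply(sets, identical, logical(1), sort(e))))
  }
  # each loop appears once
  expect_equal(anyDuplicated(loops$loop), 0L)
})

test_that("trees have no loops and a triangle has one", {
  star <- dplyr::bind_rows(
    make_study("a", "GLP1RA", "placebo", 30, 30, -0.5, 0.1, 1.2, 1.2),
    make_study("b", "SGLT2i", "placebo", 30, 30, -0.4, 0.1, 1.2, 1.2),
    make_study("c", "TZD", "placebo", 30, 30, 0.2, 0.1, 1.2, 1.2)
  )
  expect_equal(nrow(enumerate_loops(star)), 0L)
  expect_equal(nrow(enumerate_loops(small_network())), 1L)
})

test_that("an exactly consistent loop has IF 0 and p 1", {
  ct <- tibble::tibble(
    study_id = c("ab", "ac", "bc"),
    treat = c("GLP1RA", "GLP1RA", "SGLT2i"),
    comparator = c("SGLT2i", "placebo", "placebo"),
    md = c(-1.0, -0.6, 0.4),   # indirect AB = AC - BC = -1.0 = direct
    se = c(0.5, 0.4, 0.3),
    agmd = TRUE
  )
  r <- loop_if(c("GLP1RA", "SGLT2i", "placebo"), ct)
  expect_equal(r$if_abs, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_false(r$inconsistent)
})

test_that("a Bucher discrepancy reproduces the hand-computed IF, SE and z", {
  ct <- tibble::tibble(
    study_id = c("ab", "ac", "bc"),
    treat = c("GLP1RA", "GLP1RA", "SGLT2i"),
    comparator = c("SGLT2i", "placebo", "placebo"),
    md = c(-0.2, -0.6, 0.4),
    se = c(0.5, 0.4, 0.3),
    agmd = TRUE
  )
  r <- loop_if(c("GLP1RA", "SGLT2i", "placebo"), ct)
  expect_equal(r$if_abs, 0.8, tolerance = 1e-12)
  expect_equal(r$se_if, sqrt(0.25 + 0.16 + 0.09), tolerance = 1e-12)
  expect_equal(r$z, 0.8 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(r$ci_low, max(0, 0.8 - qnorm(0.975) * sqrt(0.5)))
  # invariant to rotation and reflection of the loop argument
  r2 <- loop_if(c("SGLT2i", "placebo", "GLP1RA"), ct)
  r3 <- loop_if(c("placebo", "SGLT2i", "GLP1RA"), ct)
  expect_equal(r2$if_abs, r$if_abs, tolerance = 1e-12)
  expect_equal(r3$if_abs, r$if_abs, tolerance = 1e-12)
  expect_equal(r2$se_if, r$se_if, tolerance = 1e-12)
  # z is scale-free when MDs and SEs are scaled together
  ct_scaled <- dplyr::mutate(ct, md = 3 * md, se = 3 * se)
  r4 <- loop_if(c("GLP1RA", "SGLT2i", "placebo"), ct_scaled)
  expect_equal(r4$z, r$z, tolerance = 1e-10)
  # an edge without direct evidence is an error
  expect_error(loop_if(c("GLP1RA", "TZD", "placebo"), ct), "no direct")
})

test_that("every example-network loop gets a report row", {
  tr <- pwv_trials()
  rep <- loop_inconsistency(tr)
  expect_equal(nrow(rep), 6L)
  expect_true(all(rep$if_abs >= 0))
  expect_true(all(rep$ci_low >= 0))
  expect_equal(rep$inconsistent, rep$p < 0.05)
})

test_that("the global test is zero on exactly consistent single-design data", {
  ct <- tibble::tibble(
    study_id = c("ab", "ac", "bc"),
    treat = c("GLP1RA", "GLP1RA", "SGLT2i"),
    comparator = c("SGLT2i", "placebo", "placebo"),
    md = c(-1.0, -0.6, 0.4),
    se = c(0.5, 0.4, 0.3),
    agmd = TRUE
  )
  g <- global_inconsistency(ct)
  expect_equal(g$statistic, 0, tolerance = 1e-10)
  expect_equal(g$df, 1L)
  expect_equal(g$p, 1, tolerance = 1e-10)
})

test_that("the global test is undefined on a loop-free network", {
  star <- tibble::tibble(
    study_id = c("a", "b"),
    treat = c("GLP1RA", "SGLT2i"),
    comparator = "placebo",
    md = c(-0.5, -0.4), se = c(0.3, 0.3), agmd = TRUE
  )
  expect_error(global_inconsistency(star), "no loops")
})

test_that("a large planted discrepancy is detected", {
  # consistent triangle plus one edge shifted far beyond its SE
  ct <- tibble::tibble(
    study_id = c("ab1", "ab2", "ac", "bc"),
    treat = c("GLP1RA", "GLP1RA", "GLP1RA", "SGLT2i"),
    comparator = c("SGLT2i", "SGLT2i", "placebo", "placebo"),
    md = c(-1.0 + 2.0, -1.0 + 2.0, -0.6, 0.4),
    se = c(0.3, 0.3, 0.2, 0.2),
    agmd = TRUE
  )
  g <- global_inconsistency(ct)
  expect_lt(g$p, 0.05)
  r <- loop_if(c("GLP1RA", "SGLT2i", "placebo"), ct)
  expect_true(r$inconsistent)
})

test_that("orientation of reported designs does not change the global test", {
  ct <- build_contrasts(pwv_trials())
  g1 <- global_inconsistency(ct)
  flipped <- dplyr::mutate(
    ct,
    tmp = treat,
    treat = ifelse(study_id == "Scalzo", comparator, treat),
    comparator = ifelse(study_id == "Scalzo", tmp, comparator),
    md = ifelse(study_id == "Scalzo", -md, md)
  )
  flipped$tmp <- NULL
  g2 <- global_inconsistency(flipped)
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-10)
  expect_equal(g1$df, g2$df)
})
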