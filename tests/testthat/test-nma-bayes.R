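# The sampler itself is checked three independent ways: against the
# conjugate single-study limit, against a frequentist WLS oracle in the
# common-effect limit, and against an external Gibbs implementation (JAGS)
# on a small network.

test_that("a single study in the common-effect limit recovers its own MD and SE", {
  one <- dplyr::filter(pwv_trials(), study_id == "deBoer")
  f <- fit_nma(one, chains = 2, burn_in = 500, samples = 4000,
               tau_fixed = 0, seed = 31)
  se <- sqrt(0.3^2 / 22 + 0.3^2 / 22)
  expect_lt(abs(mean(f$d[, "DPP4i"]) - (-0.8)), 0.02)
  expect_lt(abs(sd(f$d[, "DPP4i"]) - se), 0.01)
})

test_that("with tau fixed at zero the posterior means match the WLS network oracle", {
  tr <- pwv_trials()
  f <- fit_nma(tr, chains = 2, burn_in = 1000, samples = 5000,
               tau_fixed = 0, seed = 32)
  oracle <- wls_fe_oracle(build_contrasts(tr))
  for (a in names(oracle)) {
    expect_equal(mean(f$d[, a]), oracle[[a]], tolerance = 0.05)
  }
})

test_that("the sampler agrees with an independent JAGS fit on a small network", {
  skip_if_not_installed("rjags")
  net <- small_network()
  f <- fit_nma(net, chains = 2, burn_in = 1000, samples = 8000, seed = 33)

  model <- "
  model {
    for (i in 1:ns) {
      yb[i] ~ dnorm(mu[i], 1 / vb[i])
      yk[i] ~ dnorm(mu[i] + delta[i], 1 / vk[i])
      delta[i] ~ dnorm(d[t[i]] - d[b[i]], 1 / (tau * tau))
      mu[i] ~ dnorm(0, 1.0E-4)
    }
    d[1] <- 0
    for (k in 2:3) { d[k] ~ dnorm(0, 1.0E-4) }
    tau ~ dunif(0, 5)
  }"
  trts <- c("placebo", "GLP1RA", "SGLT2i")
  arms <- split(net, factor(net$study_id, unique(net$study_id)))
  dat <- list(
    ns = length(arms),
    yb = vapply(arms, function(a) a$change_mean[2], numeric(1)),
    yk = vapply(arms, function(a) a$change_mean[1], numeric(1)),
    vb = vapply(arms, function(a) a$change_sd[2]^2 / a$n[2], numeric(1)),
    vk = vapply(arms, function(a) a$change_sd[1]^2 / a$n[1], numeric(1)),
    t = vapply(arms, function(a) match(a$treatment[1], trts), numeric(1)),
    b = vapply(arms, function(a) match(a$treatment[2], trts), numeric(1))
  )
  jm <- rjags::jags.model(textConnection(model), data = dat, n.chains = 2,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 33))
  update(jm, 2000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("d", "tau"), n.iter = 10000,
                           progress.bar = "none")
  sm <- summary(s)$statistics
  expect_equal(mean(f$d[, "GLP1RA"]), sm["d[2]", "Mean"], tolerance = 0.1)
  expect_equal(mean(f$d[, "SGLT2i"]), sm["d[3]", "Mean"], tolerance = 0.1)
  expect_equal(mean(f$tau), sm["tau", "Mean"], tolerance = 0.2)
})

test_that("arm-based and contrast-based likelihoods agree on two-arm data", {
  tr <- pwv_trials()
  fa <- fit_nma(tr, chains = 2, burn_in = 1500, samples = 6000, seed = 34)
  fc <- fit_nma(tr, chains = 2, burn_in = 1500, samples = 6000, seed = 34,
                likelihood = "contrast")
  act <- setdiff(fa$treatments, fa$reference)
  expect_equal(colMeans(fa$d[, act]), colMeans(fc$d[, act]), tolerance = 0.1)
  expect_equal(median(fa$tau), median(fc$tau), tolerance = 0.15)
})

test_that("draws satisfy the structural invariants of the consistency model", {
  f <- fit_nma(small_network(), chains = fast_mcmc$chains,
               burn_in = fast_mcmc$burn_in, samples = fast_mcmc$samples,
               seed = 35)
  # reference column identically zero; tau inside its prior support
  expect_true(all(f$d[, f$reference] == 0))
  expect_true(all(f$tau > 0 & f$tau < 5))
  # consistency identity holds draw by draw
  ab <- f$d[, "GLP1RA"] - f$d[, "SGLT2i"]
  via_ref <- (f$d[, "GLP1RA"] - f$d[, "placebo"]) -
    (f$d[, "SGLT2i"] - f$d[, "placebo"])
  expect_equal(ab, via_ref, tolerance = 1e-12)
})

test_that("the same seed reproduces draws exactly; seeds differ within MC error", {
  args <- list(x = small_network(), chains = 2, burn_in = 500,
               samples = 2000)
  f1 <- do.call(fit_nma, c(args, seed = 36))
  f2 <- do.call(fit_nma, c(args, seed = 36))
  expect_identical(f1$d, f2$d)
  expect_identical(f1$tau, f2$tau)
  f3 <- do.call(fit_nma, c(args, seed = 37))
  expect_false(identical(f1$d, f3$d))
  mcse <- sd(f1$d[, "GLP1RA"]) / sqrt(min(f1$diagnostics$ess))
  expect_lt(abs(mean(f1$d[, "GLP1RA"]) - mean(f3$d[, "GLP1RA"])),
            10 * mcse + 0.05)
})

test_that("refitting with a different reference leaves contrasts unchanged", {
  f1 <- fit_nma(small_network(), chains = 2, burn_in = 800, samples = 4000,
                seed = 38)
  cb_g <- pwv_treatments(reference = "GLP1RA")
  f2 <- fit_nma(small_network(), codebook = cb_g, chains = 2,
                burn_in = 800, samples = 4000, seed = 39)
  c1 <- contrast_effect(f1, "GLP1RA", "SGLT2i")
  c2 <- contrast_effect(f2, "GLP1RA", "SGLT2i")
  expect_equal(c1$estimate, c2$estimate, tolerance = 0.1)
  expect_equal(c1$ci_low, c2$ci_low, tolerance = 0.15)
})

test_that("league table and contrast summaries share one source of truth", {
  f <- fit_nma(small_network(), chains = 2, burn_in = 500, samples = 2000,
               seed = 40)
  lt <- league_table(f)
  expect_equal(nrow(lt), 6L)  # 3 treatments, ordered pairs
  for (i in seq_len(nrow(lt))) {
    ce <- contrast_effect(f, lt$treat[i], lt$comparator[i])
    expect_equal(lt$estimate[i], ce$estimate)
    expect_equal(lt$ci_low[i], ce$ci_low)
  }
  # antisymmetry and the self contrast
  ab <- contrast_effect(f, "GLP1RA", "SGLT2i")
  ba <- contrast_effect(f, "SGLT2i", "GLP1RA")
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$ci_low, -ba$ci_high)
  self <- contrast_effect(f, "placebo", "placebo")
  expect_equal(unlist(self[, c("estimate", "ci_low", "ci_high")]),
               c(estimate = 0, ci_low = 0, ci_high = 0))
  expect_error(contrast_effect(f, "placebo", "aspirin"), "unknown treatment")
  # formatted league matrix puts treatments on the diagonal
  lm <- league_matrix(f)
  expect_identical(unname(diag(lm)), f$treatments)
})

test_that("non-convergence is reported loudly", {
  expect_error(
    fit_nma(small_network(), chains = 3, burn_in = 0, samples = 300,
            seed = 41, rhat_threshold = 1.0000001),
    "converge")
  expect_warning(
    fit_nma(small_network(), chains = 3, burn_in = 0, samples = 300,
            seed = 41, rhat_threshold = 1.0000001,
            on_nonconvergence = "warn"),
    "converge")
})

test_that("multi-arm studies are fitted through the joint-normal conditionals", {
  tri <- tibble::tibble(
    study_id = "tri",
    treatment = c("GLP1RA", "SGLT2i", "placebo"),
    n = c(40, 40, 40),
    change_mean = c(-1.0, -0.7, 0.1),
    change_sd = c(1.5, 1.5, 1.5),
    baseline_mean = NA_real_, baseline_sd = NA_real_,
    final_mean = NA_real_, final_sd = NA_real_,
    population = "T2DM", duration_weeks = 24, agmd = TRUE
  )
  x <- dplyr::bind_rows(tri, small_network())
  f <- fit_nma(x, chains = 2, burn_in = 800, samples = 3000, seed = 42)
  td <- tidy(f)
  expect_equal(nrow(td), 2L)
  expect_true(all(is.finite(td$estimate)))
  expect_true(all(td$rhat < 1.05))
})
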