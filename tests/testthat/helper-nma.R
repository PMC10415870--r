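# Shared fixtures and independent oracles for the test suite.

# Short MCMC schedule for tests; long enough for split-R-hat < 1.05 on the
# small networks used here.
fast_mcmc <- list(chains = 2, burn_in = 500, samples = 2500)

# Build one two-arm study as arm-level rows (experimental arm first).
make_study <- function(study_id, treat, comparator, n1, n2, y1, y2, s1, s2,
                       population = "T2DM", duration_weeks = 24) {
  tibble::tibble(
    study_id = study_id,
    treatment = c(treat, comparator),
    n = c(n1, n2),
    change_mean = c(y1, y2),
    change_sd = c(s1, s2),
    baseline_mean = NA_real_, baseline_sd = NA_real_,
    final_mean = NA_real_, final_sd = NA_real_,
    population = population, duration_weeks = duration_weeks,
    agmd = population %in% agmd_populations
  )
}

# A small three-treatment network with direct evidence on every edge.
small_network <- function() {
  dplyr::bind_rows(
    make_study("s1", "GLP1RA", "placebo", 40, 40, -0.8, 0.1, 1.5, 1.4),
    make_study("s2", "GLP1RA", "placebo", 30, 30, -0.2, 0.3, 1.2, 1.2),
    make_study("s3", "SGLT2i", "placebo", 50, 50, -0.5, 0.2, 1.6, 1.5),
    make_study("s4", "GLP1RA", "SGLT2i", 35, 35, -0.7, -0.2, 1.3, 1.4)
  )
}

# Independent closed-form DerSimonian-Laird oracle for k = 2 studies.
dl2_oracle <- function(md, se) {
  stopifnot(length(md) == 2)
  w <- 1 / se^2
  mfe <- sum(w * md) / sum(w)
  q <- sum(w * (md - mfe)^2)
  tau2 <- max(0, (q - 1) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(md_pooled = sum(wr * md) / sum(wr),
       q = q,
       i2 = max(0, (q - 1) / q) * 100,
       tau2 = tau2,
       se_pooled = sqrt(1 / sum(wr)))
}

# Frequentist fixed-effect network estimate by weighted least squares,
# an independent oracle for the tau -> 0 limit of the Bayesian model.
wls_fe_oracle <- function(contrasts, reference = "placebo") {
  act <- setdiff(unique(c(contrasts$treat, contrasts$comparator)), reference)
  X <- sapply(act, function(a) {
    (contrasts$treat == a) - (contrasts$comparator == a)
  })
  fit <- stats::lm(contrasts$md ~ 0 + X, weights = 1 / contrasts$se^2)
  stats::setNames(unname(stats::coef(fit)), act)
}

# Minimal fit-shaped object so ranking can be tested on hand-built draws.
fake_fit <- function(d) {
  structure(list(d = d, treatments = colnames(d),
                 reference = colnames(d)[1]),
            class = "nma_fit")
}
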