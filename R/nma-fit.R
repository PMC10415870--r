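#' Fit the Bayesian random-effects consistency network meta-analysis
#'
#' Estimates basic treatment effects `d` (mean difference in the change
#' outcome versus the reference, in m/s), trial baselines `mu` and the
#' between-trial SD `tau` from arm-level summaries, using a purpose-built
#' Gibbs sampler.
#'
#' The default (arm-based) likelihood treats each observed arm mean as
#' \deqn{y_{ik} \sim N(\mu_i + \delta_{ik},\; sd_{ik}^2 / n_{ik}),}
#' with \eqn{\delta} fixed at 0 in the study's baseline arm and
#' \eqn{\delta_{ik} \sim N(d_{t(i,k)} - d_{t(i,b)},\, \tau^2)} otherwise
#' (multi-arm studies use the exchangeable joint normal with
#' \eqn{\tau^2/2} covariance).  Priors are vague normals with mean 0 and
#' precision `effect_prior_precision` on all baselines and basic effects,
#' and Uniform(0, `tau_max`) on `tau`.  All conditionals except `tau` are
#' conjugate normals; `tau` is updated by slice sampling.  Chains start
#' from overdispersed states and convergence is checked with split-R-hat;
#' by default the fit fails loudly if any monitored parameter exceeds
#' `rhat_threshold`.
#'
#' A contrast-based likelihood (`likelihood = "contrast"`; study mean
#' differences with their SEs, no explicit baselines) is available as a
#' cross-check and agrees with the arm-based model within Monte-Carlo
#' error for two-arm studies.
#'
#' @inheritParams build_contrasts
#' @param likelihood `"arm"` (default) or `"contrast"`.
#' @param effect_prior_precision Prior precision for baselines and basic
#'   effects (vague default `1e-4`, i.e. variance `1e4`).
#' @param tau_max Upper bound of the uniform prior on `tau` (m/s).
#' @param tau_fixed Optional non-negative value at which to fix `tau`
#'   instead of sampling it; `0` gives the common-effect (fixed-effect)
#'   model.
#' @param chains,burn_in,samples,thin MCMC schedule per chain: number of
#'   parallel chains, discarded burn-in iterations, retained iterations,
#'   and thinning interval.
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @param rhat_threshold Split-R-hat limit for declaring convergence.
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @param keep_mu Retain draws of the trial baselines.
#'
#' @return An object of class `nma_fit`: posterior draw matrices `d`
#'   (one column per treatment, reference column identically 0) and
#'   `tau`, a per-draw `chain` index, a `diagnostics` tibble (split-R-hat
#'   and effective sample size per monitored parameter), the `contrasts`
#'   used, and the configuration.  Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance], [contrast_effect()], [league_table()]
#'   and [sucra()] to summarize it.
#' @examples
#' \donttest{
#' fit <- fit_nma(pwv_trials(), chains = 2, burn_in = 500, samples = 2000)
#' tidy(fit)
#' }
#' @export
fit_nma <- function(x, codebook = pwv_treatments(), corr = 0.5,
                    likelihood = c("arm", "contrast"),
                    effect_prior_precision = 1e-4,
                    tau_max = 5, tau_fixed = NULL,
                    chains = 3, burn_in = 20000, samples = 80000, thin = 1,
                    seed = 1, rhat_threshold = 1.05,
                    on_nonconvergence = c("error", "warn"),
                    keep_mu = FALSE) {
  likelihood <- match.arg(likelihood)
  on_nonconvergence <- match.arg(on_nonconvergence)
  codebook <- check_codebook(codebook)
  stopifnot(chains >= 1, samples > 0, burn_in >= 0, thin >= 1)
  if (nrow(x) == 0) abort("empty dataset")
  validate_trials(x, codebook = codebook)
  x <- impute_change_sd(x, corr = corr)

  ref <- reference_code(codebook)
  trts <- codebook$code[codebook$code %in% unique(x$treatment)]
  if (!ref %in% trts) abort("reference treatment absent from data")
  act <- setdiff(trts, ref)
  p <- length(act)

  studies <- prepare_studies(x, ref, act)
  if (likelihood == "contrast" && any(vapply(studies, function(s) s$K, 1L) > 1)) {
    abort("contrast likelihood supports two-arm studies only")
  }
  contrasts <- build_contrasts(x, codebook = codebook, corr = corr)
  if (likelihood == "contrast") {
    # collapse each two-arm study to its mean difference and SE
    studies <- lapply(studies, function(s) {
      s$yk <- s$yk - s$yb
      s$vk <- s$vk + s$vb
      s
    })
  }

  kept <- floor(samples / thin)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  init_off <- c(0, 1, -1)
  init_tau <- c(1, 0.1, tau_max / 2)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    off <- init_off[(ch - 1L) %% 3L + 1L]
    tau0 <- if (!is.null(tau_fixed)) tau_fixed else
      min(init_tau[(ch - 1L) %% 3L + 1L], tau_max * 0.99)
    res[[ch]] <- run_chain(
      studies, p, likelihood, effect_prior_precision, tau_max, tau_fixed,
      burn_in, samples, thin, kept, d0 = rep(off, p), mu0 = off, tau0 = tau0,
      keep_mu = keep_mu)
  }

  d_all <- do.call(rbind, lapply(res, `[[`, "d"))
  colnames(d_all) <- act
  d_full <- cbind(matrix(0, nrow(d_all), 1, dimnames = list(NULL, ref)), d_all)
  d_full <- d_full[, trts, drop = FALSE]
  tau_all <- unlist(lapply(res, `[[`, "tau"))
  chain_idx <- rep(seq_len(chains), each = kept)

  diag_tbl <- nma_diagnostics(res, act, tau_fixed)
  fit <- structure(list(
    treatments = trts, reference = ref,
    d = d_full, tau = tau_all, chain = chain_idx,
    mu = if (keep_mu && likelihood == "arm") {
      m <- do.call(rbind, lapply(res, `[[`, "mu"))
      colnames(m) <- vapply(studies, `[[`, "", "study_id"); m
    },
    diagnostics = diag_tbl,
    contrasts = contrasts,
    n_studies = length(studies),
    config = list(likelihood = likelihood, corr = corr,
                  effect_prior_precision = effect_prior_precision,
                  tau_max = tau_max, tau_fixed = tau_fixed,
                  chains = chains, burn_in = burn_in, samples = samples,
                  thin = thin, seed = seed,
                  rhat_threshold = rhat_threshold)
  ), class = "nma_fit")

  bad <- diag_tbl$parameter[!is.na(diag_tbl$rhat) &
                              diag_tbl$rhat > rhat_threshold]
  if (length(bad) > 0 && chains >= 2) {
    msg <- paste0("MCMC did not converge (split-R-hat > ", rhat_threshold,
                  " for ", paste(bad, collapse = ", "), ")")
    if (on_nonconvergence == "error") abort(msg) else warn(msg)
  }
  fit
}

# Per-study sampler inputs.  Baseline arm: reference if present, else the
# last arm.  K = number of non-baseline arms.
prepare_studies <- function(x, ref, act) {
  lapply(split(x, factor(x$study_id, unique(x$study_id))), function(d) {
    b <- if (ref %in% d$treatment) which(d$treatment == ref) else nrow(d)
    k <- setdiff(seq_len(nrow(d)), b)
    X <- matrix(0, length(k), length(act),
                dimnames = list(NULL, act))
    for (j in seq_along(k)) {
      tk <- d$treatment[k[j]]
      tb <- d$treatment[b]
      if (tk != ref) X[j, tk] <- 1
      if (tb != ref) X[j, tb] <- X[j, tb] - 1
    }
    list(study_id = d$study_id[1],
         yb = d$change_mean[b], vb = d$change_sd[b]^2 / d$n[b],
         yk = d$change_mean[k], vk = d$change_sd[k]^2 / d$n[k],
         X = X, K = length(k))
  })
}

# Core Gibbs sampler for one chain.  Two-arm studies are updated in
# vectorized blocks; multi-arm studies fall back to per-study draws from
# their joint-normal conditionals.
run_chain <- function(studies, p, likelihood, p0, tau_max, tau_fixed,
                      burn_in, samples, thin, kept, d0, mu0, tau0, keep_mu) {
  ns <- length(studies)
  K <- vapply(studies, `[[`, 1L, "K")
  two <- which(K == 1L)
  multi <- which(K > 1L)

  yb <- vapply(studies, function(s) s$yb, numeric(1))
  vb <- vapply(studies, function(s) s$vb, numeric(1))
  yk2 <- vapply(studies[two], function(s) s$yk[1], numeric(1))
  vk2 <- vapply(studies[two], function(s) s$vk[1], numeric(1))
  X2 <- if (length(two)) {
    do.call(rbind, lapply(studies[two], `[[`, "X"))
  } else {
    matrix(0, 0, p)
  }
  wb <- 1 / vb
  wk2 <- 1 / vk2

  # multi-arm constants
  ml <- lapply(studies[multi], function(s) {
    k <- s$K
    Om <- 2 * (diag(k) - matrix(1, k, k) / (k + 1))  # inverse of (I+J)/2
    list(X = s$X, yk = s$yk, vk = s$vk, K = k, Om = Om,
         Wk = diag(1 / s$vk, k))
  })

  # d-update constants: A = sum X' Omega X; C maps stacked delta to X'Omega delta
  A <- crossprod(X2)
  for (s in ml) A <- A + t(s$X) %*% s$Om %*% s$X
  eA <- eigen(A, symmetric = TRUE)
  V <- eA$vectors
  lam <- pmax(eA$values, 0)
  m_tot <- sum(K)

  mu <- rep(mu0, ns)
  d <- d0
  tau <- tau0
  fixed0 <- !is.null(tau_fixed) && tau_fixed == 0
  if (fixed0 && length(multi) > 0) {
    abort("tau_fixed = 0 currently supports two-arm studies only")
  }
  delta2 <- rep(0, length(two))
  delta_m <- lapply(ml, function(s) rep(0, nrow(s$X)))

  keep_d <- matrix(NA_real_, kept, p)
  keep_tau <- numeric(kept)
  keep_mu_m <- if (keep_mu && likelihood == "arm") matrix(NA_real_, kept, ns)
  # fixed-effect (tau = 0) path couples delta to d exactly, so sample d
  # from its collapsed conditional instead of via delta
  W2 <- if (fixed0) diag(wk2, length(two))

  total <- burn_in + samples
  slot <- 0L
  for (it in seq_len(total)) {
    tau2 <- tau * tau
    if (likelihood == "arm") {
      # mu | .
      if (length(two)) {
        pm <- wb[two] + wk2 + p0
        theta2 <- as.vector(X2 %*% d)
        resid_k <- yk2 - (if (fixed0) theta2 else delta2)
        mm <- (yb[two] * wb[two] + resid_k * wk2) / pm
        mu[two] <- mm + rnorm(length(two)) / sqrt(pm)
      }
      if (length(multi)) {
        for (j in seq_along(multi)) {
          i <- multi[j]; s <- ml[[j]]
          pm <- wb[i] + sum(1 / s$vk) + p0
          mm <- (yb[i] * wb[i] + sum((s$yk - delta_m[[j]]) / s$vk)) / pm
          mu[i] <- mm + rnorm(1) / sqrt(pm)
        }
      }
    }
    # delta | . and d | .
    if (fixed0) {
      # d | mu: precision X'W X + p0 I
      if (likelihood == "arm") {
        z2 <- yk2 - mu[two]
      } else {
        z2 <- yk2
      }
      Ad <- crossprod(X2, W2 %*% X2) + diag(p0, p)
      bd <- crossprod(X2, wk2 * z2)
      ch <- chol(Ad)
      mean_d <- backsolve(ch, forwardsolve(t(ch), bd))
      d <- as.vector(mean_d + backsolve(ch, rnorm(p)))
    } else {
      theta2 <- as.vector(X2 %*% d)
      if (length(two)) {
        zk <- if (likelihood == "arm") yk2 - mu[two] else yk2
        pd <- wk2 + 1 / tau2
        md <- (zk * wk2 + theta2 / tau2) / pd
        delta2 <- md + rnorm(length(two)) / sqrt(pd)
      }
      if (length(multi)) {
        for (j in seq_along(multi)) {
          s <- ml[[j]]
          th <- as.vector(s$X %*% d)
          P <- s$Wk + s$Om / tau2
          zk <- if (likelihood == "arm") s$yk - mu[multi[j]] else s$yk
          bvec <- zk / s$vk + (s$Om %*% th) / tau2
          chp <- chol(P)
          mean_dm <- backsolve(chp, forwardsolve(t(chp), bvec))
          delta_m[[j]] <- as.vector(mean_dm + backsolve(chp, rnorm(s$K)))
        }
      }
      # d | delta, tau: precision A/tau2 + p0 I (eigen-form, no per-iter chol)
      lin <- crossprod(X2, delta2) / tau2
      for (j in seq_along(multi)) {
        s <- ml[[j]]
        lin <- lin + (t(s$X) %*% (s$Om %*% delta_m[[j]])) / tau2
      }
      den <- lam / tau2 + p0
      d <- as.vector(V %*% (crossprod(V, lin) / den) +
                       V %*% (rnorm(p) / sqrt(den)))
      # tau | delta, d  (slice step under the uniform prior)
      if (is.null(tau_fixed)) {
        r2 <- delta2 - as.vector(X2 %*% d)
        Q <- sum(r2 * r2)
        for (j in seq_along(multi)) {
          s <- ml[[j]]
          rm <- delta_m[[j]] - as.vector(s$X %*% d)
          Q <- Q + as.vector(t(rm) %*% s$Om %*% rm)
        }
        logf <- function(t) -m_tot * log(t) - Q / (2 * t * t)
        tau <- slice_update(tau, logf, lower = 1e-12, upper = tau_max)
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      slot <- slot + 1L
      keep_d[slot, ] <- d
      keep_tau[slot] <- tau
      if (!is.null(keep_mu_m)) keep_mu_m[slot, ] <- mu
    }
  }
  list(d = keep_d, tau = keep_tau, mu = keep_mu_m)
}

nma_diagnostics <- function(res, act, tau_fixed) {
  params <- c(paste0("d[", act, "]"), if (is.null(tau_fixed)) "tau")
  per_chain <- lapply(seq_along(act), function(j) {
    lapply(res, function(r) r$d[, j])
  })
  if (is.null(tau_fixed)) per_chain <- c(per_chain, list(lapply(res, `[[`, "tau")))
  rhat <- vapply(per_chain, split_rhat, numeric(1))
  ess <- vapply(per_chain, function(chains_j) {
    sum(vapply(chains_j, function(v) {
      unname(coda::effectiveSize(coda::mcmc(v)))
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(parameter = params, rhat = rhat, ess = ess)
}
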