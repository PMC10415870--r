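#' Default true effects for synthetic networks
#'
#' The generator's default truth mirrors the example network: the basic
#' effects are the posterior means, and the heterogeneity the posterior
#' median, of the default [fit_nma()] run on [pwv_trials()] (full MCMC
#' schedule), frozen here so simulations are reproducible without
#' refitting.
#'
#' @return Named list with `d_true` (m/s versus placebo) and `tau_true`.
#' @export
sim_defaults <- function() {
  list(
    d_true = c(GLP1RA = -1.03, SGLT2i = -0.81, DPP4i = -0.80,
               TZD = -0.67, SU = -0.73, metformin = -1.44),
    tau_true = 1.43
  )
}

#' Simulate an arm-level trial network with known truth
#'
#' Generates two-arm trials under the same hierarchical model the
#' estimator assumes: per study a baseline mean is drawn uniformly, a
#' trial-specific effect \eqn{\delta_i \sim N(d_t - d_b + offset,
#' \tau^2)} perturbs the contrast, and each arm's observed change mean is
#' drawn with sampling variance `sd^2/n`.  Arm SDs and sizes are drawn
#' uniformly within ranges matching the example dataset (SDs 0.3-3.5
#' m/s, 13-97 participants per arm).  The output passes
#' [validate_trials()] unchanged; the generating truth is attached as the
#' `"truth"` attribute (see [sim_truth()]).
#'
#' @param design `"example_geometry"` (the example network's 18 treatment
#'   pairs), `"star"` (every active treatment versus the reference, round
#'   robin) or `"random_connected"` (random spanning tree plus random
#'   extra edges).
#' @param n_studies Number of trials; fixed to 18 for
#'   `"example_geometry"`.
#' @param d_true Named vector of true basic effects versus the reference
#'   (m/s); names must be treatment codes from `codebook`.
#' @param tau_true True between-trial SD (m/s), `>= 0`.
#' @param n_per_arm Integer range (length 2) of per-arm sample sizes.
#' @param arm_sd_range Range of arm change-score SDs (m/s).
#' @param baseline_range Range of true baseline change means (m/s).
#' @param inconsistency_offset Optional named numeric planting a
#'   loop-inconsistent shift on specific edges, e.g.
#'   `c("SGLT2i|placebo" = 1.5)` adds 1.5 m/s to every
#'   SGLT2i-vs-placebo contrast ("treat|comparator").
#' @param seed Optional integer seed.
#' @inheritParams validate_trials
#' @return Arm-level tibble in the [pwv_trials()] layout with attribute
#'   `"truth"`.
#' @examples
#' syn <- simulate_network(seed = 42)
#' sim_truth(syn)$tau_true
#' @export
simulate_network <- function(design = c("example_geometry", "star",
                                        "random_connected"),
                             n_studies = 18,
                             d_true = sim_defaults()$d_true,
                             tau_true = sim_defaults()$tau_true,
                             n_per_arm = c(13, 97),
                             arm_sd_range = c(0.3, 3.5),
                             baseline_range = c(-0.5, 0.5),
                             inconsistency_offset = NULL,
                             seed = NULL,
                             codebook = pwv_treatments()) {
  design <- match.arg(design)
  stopifnot(tau_true >= 0, all(names(d_true) %in% codebook$code))
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  ref <- reference_code(codebook)
  d_full <- c(stats::setNames(0, ref), d_true)

  pairs <- switch(design,
    example_geometry = {
      fx <- pwv_trials()
      sp <- split(fx$treatment, factor(fx$study_id, unique(fx$study_id)))
      lapply(sp, function(tr) c(tr[1], tr[2]))  # (treat, comparator)
    },
    star = {
      act <- names(d_true)
      lapply(seq_len(n_studies), function(i) {
        c(act[(i - 1) %% length(act) + 1], ref)
      })
    },
    random_connected = {
      nodes <- c(ref, names(d_true))
      # spanning tree then random extra edges
      tree <- lapply(seq_along(nodes)[-1], function(i) {
        c(nodes[i], sample(nodes[seq_len(i - 1)], 1))
      })
      extra <- max(0, n_studies - length(tree))
      more <- lapply(seq_len(extra), function(i) sample(nodes, 2))
      c(tree, more)[seq_len(max(n_studies, length(tree)))]
    })

  offset_for <- function(t1, t2) {
    if (is.null(inconsistency_offset)) return(0)
    key1 <- paste(t1, t2, sep = "|")
    key2 <- paste(t2, t1, sep = "|")
    if (key1 %in% names(inconsistency_offset)) {
      unname(inconsistency_offset[key1])
    } else if (key2 %in% names(inconsistency_offset)) {
      -unname(inconsistency_offset[key2])
    } else 0
  }

  pairs <- unname(pairs)
  n_pool <- seq(n_per_arm[1], n_per_arm[2])
  rows <- purrr::imap_dfr(pairs, function(pr, idx) {
    tk <- pr[1]; tb <- pr[2]
    mu_i <- runif(1, baseline_range[1], baseline_range[2])
    theta <- d_full[tk] - d_full[tb] + offset_for(tk, tb)
    delta <- rnorm(1, theta, tau_true)
    n <- n_pool[sample.int(length(n_pool), 2, replace = TRUE)]
    sds <- runif(2, arm_sd_range[1], arm_sd_range[2])
    tibble::tibble(
      study_id = sprintf("sim%02d", as.integer(idx)),
      treatment = c(tk, tb),
      n = n,
      change_mean = c(rnorm(1, mu_i + delta, sds[1] / sqrt(n[1])),
                      rnorm(1, mu_i, sds[2] / sqrt(n[2]))),
      change_sd = sds,
      baseline_mean = NA_real_, baseline_sd = NA_real_,
      final_mean = NA_real_, final_sd = NA_real_,
      population = "T2DM", duration_weeks = 24, agmd = TRUE
    )
  })
  names(rows$change_mean) <- NULL
  attr(rows, "truth") <- list(d_true = d_true, tau_true = tau_true,
                              design = design,
                              inconsistency_offset = inconsistency_offset)
  rows
}

#' @rdname simulate_network
#' @param x A tibble produced by `simulate_network()`.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Score parameter recovery across simulation replicates
#'
#' Compares per-replicate posterior summaries with the generating truth:
#' bias and RMSE of the posterior means and empirical coverage of the
#' 95% credible intervals, per treatment.
#'
#' @param estimates Tibble with one row per replicate x treatment:
#'   columns `treatment`, `estimate`, `conf.low`, `conf.high` (the shape
#'   of [tidy.nma_fit()], optionally with a `replicate` column).
#' @param d_true Named vector of true basic effects.
#' @return A tibble per treatment: `n_replicates`, `bias`, `rmse`,
#'   `ci_coverage`.
#' @export
score_recovery <- function(estimates, d_true) {
  miss <- setdiff(unique(estimates$treatment), names(d_true))
  if (length(miss) > 0) {
    abort(paste0("no truth supplied for treatment(s): ",
                 paste(miss, collapse = ", ")))
  }
  est <- dplyr::mutate(estimates, truth = d_true[.data$treatment])
  dplyr::summarise(
    dplyr::group_by(est, .data$treatment),
    n_replicates = dplyr::n(),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    ci_coverage = mean(.data$conf.low <= .data$truth &
                         .data$truth <= .data$conf.high),
    .groups = "drop"
  )
}
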