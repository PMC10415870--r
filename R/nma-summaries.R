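#' @export
print.nma_fit <- function(x, ...) {
  cfg <- x$config
  cat("Bayesian network meta-analysis (", cfg$likelihood, "-based likelihood)\n",
      sep = "")
  cat(x$n_studies, "studies,", length(x$treatments), "treatments, reference:",
      x$reference, "\n")
  cat(cfg$chains, "chain(s) x", cfg$samples, "iterations after", cfg$burn_in,
      "burn-in\n")
  if (is.null(cfg$tau_fixed)) {
    cat("tau (between-trial SD): median", round(median(x$tau), 3),
        " 95% CrI [", round(quantile(x$tau, 0.025), 3), ",",
        round(quantile(x$tau, 0.975), 3), "]\n")
  } else {
    cat("tau fixed at", cfg$tau_fixed, "\n")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy posterior summaries of the basic treatment effects
#'
#' One row per non-reference treatment: posterior mean difference versus
#' the reference (m/s), equal-tailed 95% credible interval, and the
#' convergence diagnostics of that parameter.
#'
#' @param x An [nma_fit] object.
#' @param ... Unused.
#' @return A tibble with columns `treatment`, `estimate`, `conf.low`,
#'   `conf.high`, `rhat`, `ess`.
#' @exportS3Method generics::tidy
tidy.nma_fit <- function(x, ...) {
  act <- setdiff(x$treatments, x$reference)
  est <- colMeans(x$d[, act, drop = FALSE])
  ci <- apply(x$d[, act, drop = FALSE], 2, quantile, c(0.025, 0.975))
  dg <- x$diagnostics
  idx <- match(paste0("d[", act, "]"), dg$parameter)
  tibble::tibble(
    treatment = act,
    estimate = unname(est),
    conf.low = unname(ci[1, ]),
    conf.high = unname(ci[2, ]),
    rhat = dg$rhat[idx],
    ess = dg$ess[idx]
  )
}

#' One-line model summary
#'
#' @param x An [nma_fit] object.
#' @param ... Unused.
#' @return A one-row tibble: network size, heterogeneity summary and
#'   worst-case convergence diagnostics.
#' @exportS3Method generics::glance
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    n_studies = x$n_studies,
    n_treatments = length(x$treatments),
    tau_median = median(x$tau),
    tau_ci_low = unname(quantile(x$tau, 0.025)),
    tau_ci_high = unname(quantile(x$tau, 0.975)),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    n_draws = length(x$tau)
  )
}

#' Posterior summary of one treatment contrast
#'
#' Summarizes the per-draw difference `d[treat] - d[comparator]` by its
#' posterior mean and equal-tailed 95% credible interval.  Because the
#' model is parameterized in basic effects, every contrast is internally
#' consistent: `contrast_effect(f, a, b)` is the exact negative of
#' `contrast_effect(f, b, a)`.
#'
#' @param fit An [nma_fit] object.
#' @param treat,comparator Treatment codes present in the network.
#' @return A one-row tibble: `treat`, `comparator`, `estimate`, `ci_low`,
#'   `ci_high`, `significant` (credible interval excludes zero).
#' @export
contrast_effect <- function(fit, treat, comparator) {
  for (tr in c(treat, comparator)) {
    if (!tr %in% fit$treatments) {
      abort(paste0("unknown treatment '", tr, "'"))
    }
  }
  diff <- fit$d[, treat] - fit$d[, comparator]
  ci <- quantile(diff, c(0.025, 0.975))
  tibble::tibble(
    treat = treat, comparator = comparator,
    estimate = mean(diff),
    ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    significant = ci[1] > 0 | ci[2] < 0
  )
}

#' League table of all pairwise treatment contrasts
#'
#' Every ordered pair of treatments with its posterior mean difference,
#' 95% credible interval, and a significance flag (interval excludes 0).
#' `league_matrix()` formats the same information as the conventional
#' square league-table display, with treatments on the diagonal and
#' "mean (low, high)" in each off-diagonal cell, reading cell (row, col)
#' as column-treatment minus row-treatment.
#'
#' @param fit An [nma_fit] object.
#' @param digits Decimal places in the formatted matrix.
#' @return `league_table()`: a tibble with one row per ordered pair;
#'   `league_matrix()`: a character matrix.
#' @export
league_table <- function(fit) {
  trts <- fit$treatments
  pairs <- tidyr::expand_grid(treat = trts, comparator = trts)
  pairs <- dplyr::filter(pairs, .data$treat != .data$comparator)
  purrr::pmap_dfr(pairs, function(treat, comparator) {
    contrast_effect(fit, treat, comparator)
  })
}

#' @rdname league_table
#' @export
league_matrix <- function(fit, digits = 2) {
  trts <- fit$treatments
  lt <- league_table(fit)
  m <- matrix("", length(trts), length(trts), dimnames = list(trts, trts))
  diag(m) <- trts
  for (i in seq_len(nrow(lt))) {
    cell <- sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)%s"),
                    lt$estimate[i], lt$ci_low[i], lt$ci_high[i],
                    ifelse(lt$significant[i], "*", ""))
    m[lt$comparator[i], lt$treat[i]] <- cell
  }
  m
}
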