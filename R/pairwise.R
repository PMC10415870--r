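#' Pairwise random-effects meta-analysis of every direct comparison
#'
#' Pools the study-level mean differences on each network edge with an
#' inverse-variance random-effects model using the DerSimonian-Laird
#' between-trial variance (via [metafor::rma()]), and attaches Cochran's
#' Q, its p-value, and the I-squared statistic.  Heterogeneity is flagged
#' `"mild"` when the Q-test p-value is at least 0.1 and I-squared is at
#' most 50%, and `"investigate"` otherwise.
#'
#' Studies reporting the same comparison in opposite orientations are
#' aligned to one canonical orientation (sign-flipping the MD) before
#' pooling, so each unordered treatment pair yields a single row.
#'
#' @param contrasts Contrast tibble from [build_contrasts()]; may cover
#'   one edge or the whole network.
#' @return A tibble with one row per direct comparison:
#'   `treat`, `comparator`, `k`, `md_pooled`, `ci_low`, `ci_high`,
#'   `q`, `df`, `i2`, `p_het`, `tau2_dl`, `heterogeneity_flag`.
#' @examples
#' pool_pairwise(build_contrasts(pwv_trials()))
#' @export
pool_pairwise <- function(contrasts) {
  if (nrow(contrasts) == 0) abort("no contrasts to pool")
  grouped <- dplyr::group_by(canonicalize_edges(contrasts),
                             .data$treat, .data$comparator)
  out <- dplyr::group_modify(grouped, function(d, key) {
    fit <- suppressWarnings(
      metafor::rma(yi = d$md, sei = d$se, method = "DL", test = "z"))
    k <- nrow(d)
    q <- unname(fit$QE)
    df <- k - 1L
    tibble::tibble(
      k = k,
      md_pooled = unname(fit$beta[1, 1]),
      ci_low = unname(fit$ci.lb),
      ci_high = unname(fit$ci.ub),
      q = q,
      df = df,
      i2 = if (df > 0) max(0, (q - df) / q) * 100 else 0,
      p_het = if (df > 0) unname(fit$QEp) else 1,
      tau2_dl = unname(fit$tau2)
    )
  })
  out <- dplyr::ungroup(out)
  dplyr::mutate(out, heterogeneity_flag = ifelse(
    .data$p_het >= 0.1 & .data$i2 <= 50, "mild", "investigate"))
}

#' Comparison-adjusted funnel-plot data
#'
#' Centers each study's mean difference on the fixed-effect pooled
#' estimate of its own comparison, so that studies from different edges
#' share a common zero and can be displayed in one funnel.  Single-study
#' edges center to exactly zero.
#'
#' @inheritParams pool_pairwise
#' @return A tibble sorted by `se`: `study_id`, `edge`, `centered_effect`,
#'   `se`.
#' @export
funnel_data <- function(contrasts) {
  if (nrow(contrasts) == 0) abort("no contrasts")
  out <- dplyr::group_by(canonicalize_edges(contrasts),
                         .data$treat, .data$comparator)
  out <- dplyr::mutate(
    out,
    centered_effect = .data$md -
      sum(.data$md / .data$se^2) / sum(1 / .data$se^2)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::transmute(
    out,
    study_id = .data$study_id,
    edge = paste(.data$treat, "vs", .data$comparator),
    centered_effect = .data$centered_effect,
    se = .data$se
  )
  dplyr::arrange(out, .data$se)
}

# Align both orientations of the same comparison to the orientation of
# its first occurrence in the data, flipping the MD sign where needed.
canonicalize_edges <- function(contrasts) {
  key <- paste(pmin(contrasts$treat, contrasts$comparator),
               pmax(contrasts$treat, contrasts$comparator), sep = "|")
  first <- !duplicated(key)
  lead_treat <- stats::setNames(contrasts$treat[first], key[first])
  flip <- unname(lead_treat[key]) != contrasts$treat
  out <- contrasts
  out$treat <- ifelse(flip, contrasts$comparator, contrasts$treat)
  out$comparator <- ifelse(flip, contrasts$treat, contrasts$comparator)
  out$md <- ifelse(flip, -contrasts$md, contrasts$md)
  out
}
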