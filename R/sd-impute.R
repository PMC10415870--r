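#' Impute a change-score SD from baseline and final SDs
#'
#' When a trial reports the SD of the outcome at baseline and at follow-up
#' but not the SD of the within-arm change, the change-score SD is
#' recovered from the assumed pre/post correlation:
#' \deqn{SD_{change} = \sqrt{SD_{baseline}^2 + SD_{final}^2
#'       - 2\,\rho\, SD_{baseline} SD_{final}}.}
#' The radicand cannot be negative for \eqn{\rho \le 1}; it is exactly zero
#' only in the degenerate case of equal SDs and \eqn{\rho = 1}, which is
#' rejected downstream because contrasts need a positive SE.
#'
#' @param baseline_sd,final_sd Positive SDs of the outcome (m/s).
#' @param corr Assumed pre/post correlation \eqn{\rho}, in \[0, 1\].
#'   0.5 is the conventional conservative default.
#' @return The imputed change-score SD (vectorized).
#' @examples
#' sd_change(3, 4, 0.5)  # sqrt(13)
#' @export
sd_change <- function(baseline_sd, final_sd, corr = 0.5) {
  if (any(corr < 0 | corr > 1)) abort("corr must lie in [0, 1]")
  if (any(baseline_sd <= 0, na.rm = TRUE) || any(final_sd <= 0, na.rm = TRUE)) {
    abort("baseline_sd and final_sd must be positive")
  }
  sqrt(baseline_sd^2 + final_sd^2 - 2 * corr * baseline_sd * final_sd)
}

#' Estimate an SD from a range or an interquartile range
#'
#' Conventional conversions for trials reporting dispersion as a range
#' (SD = width / 6) or an interquartile range (SD = (Q3 - Q1) / 1.35).
#'
#' @param range_width Positive width of the reported range.
#' @param q1,q3 First and third quartiles, `q3 > q1`.
#' @return The estimated SD.
#' @examples
#' sd_from_range(6)       # 1
#' sd_from_iqr(8.2, 11.2) # 3 / 1.35
#' @export
sd_from_range <- function(range_width) {
  if (any(range_width <= 0)) abort("range_width must be positive")
  range_width / 6
}

#' @rdname sd_from_range
#' @export
sd_from_iqr <- function(q1, q3) {
  if (any(q3 <= q1)) abort("q3 must exceed q1")
  (q3 - q1) / 1.35
}

#' Build within-trial treatment contrasts from arm summaries
#'
#' For every study, each non-baseline arm is contrasted against the
#' study's baseline arm: the reference treatment when present, otherwise
#' the last arm (the comparator/control by convention of the data layout).
#' The mean difference is `change_mean[k] - change_mean[baseline]` and its
#' standard error `sqrt(sd_k^2/n_k + sd_b^2/n_b)`.  Missing change-score
#' SDs are first imputed with [sd_change()] at the given correlation.
#'
#' @inheritParams validate_trials
#' @param corr Pre/post correlation used for SD imputation where needed.
#' @param force_impute Logical; ignore reported change-score SDs and
#'   re-impute every arm that has baseline and final SDs (sensitivity use).
#' @return A tibble of contrasts: `study_id`, `treat`, `comparator`,
#'   `md` (m/s), `se` (m/s), `agmd`.
#' @examples
#' contrasts <- build_contrasts(pwv_trials())
#' @export
build_contrasts <- function(x, codebook = pwv_treatments(), corr = 0.5,
                            force_impute = FALSE) {
  validate_trials(x, codebook = codebook)
  ref <- reference_code(codebook)
  x <- impute_change_sd(x, corr = corr, force = force_impute)
  bad <- which(is.na(x$change_sd) | x$change_sd <= 0)
  if (length(bad)) {
    abort(paste0("arm(s) without a positive change SD after imputation (rows ",
                 paste(bad, collapse = ", "), ")"))
  }
  out <- dplyr::group_modify(dplyr::group_by(x, .data$study_id), function(d, key) {
    b <- if (ref %in% d$treatment) which(d$treatment == ref) else nrow(d)
    k <- setdiff(seq_len(nrow(d)), b)
    tibble::tibble(
      treat = d$treatment[k],
      comparator = d$treatment[b],
      md = d$change_mean[k] - d$change_mean[b],
      se = sqrt(d$change_sd[k]^2 / d$n[k] + d$change_sd[b]^2 / d$n[b]),
      agmd = d$agmd[k]
    )
  })
  out <- dplyr::ungroup(out)
  if (any(out$se <= 0)) abort("zero standard error in contrast")
  out
}

# Fill change_sd from baseline/final SDs where missing (or everywhere
# imputable when force = TRUE).
impute_change_sd <- function(x, corr = 0.5, force = FALSE) {
  can <- !is.na(x$baseline_sd) & !is.na(x$final_sd)
  todo <- if (force) can else is.na(x$change_sd) & can
  if (any(todo)) {
    x$change_sd[todo] <- sd_change(x$baseline_sd[todo], x$final_sd[todo], corr)
  }
  x
}

#' Sensitivity of pooled direct comparisons to the imputation correlation
#'
#' Re-imputes every change-score SD that has baseline and final SDs
#' available under each candidate correlation, rebuilds the contrasts, and
#' reports the DerSimonian-Laird pooled mean difference per direct
#' comparison.  On datasets where every change-score SD is reported
#' directly this is a what-if exercise: the `reported` column gives the
#' pooled MD using the SDs as shipped.  Arms lacking a final SD borrow the
#' baseline SD for the sweep (stationary-dispersion assumption), so that
#' datasets reporting only baseline and change SDs can still be probed.
#'
#' @inheritParams build_contrasts
#' @param corr_values Correlations to sweep.
#' @return A tibble with one row per direct comparison and one pooled-MD
#'   column per correlation, plus `reported`.
#' @export
sensitivity_corr <- function(x, codebook = pwv_treatments(),
                             corr_values = c(0.3, 0.5, 0.7)) {
  base <- pool_pairwise(build_contrasts(x, codebook))
  out <- dplyr::select(base, "treat", "comparator", reported = "md_pooled")
  x2 <- dplyr::mutate(x, final_sd = dplyr::coalesce(.data$final_sd, .data$baseline_sd))
  for (r in corr_values) {
    p <- pool_pairwise(build_contrasts(x2, codebook, corr = r, force_impute = TRUE))
    p <- dplyr::select(p, "treat", "comparator", "md_pooled")
    names(p)[3] <- paste0("corr_", r)
    out <- dplyr::left_join(out, p, by = c("treat", "comparator"))
  }
  out
}
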