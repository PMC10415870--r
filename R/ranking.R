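#' SUCRA treatment ranking from posterior draws
#'
#' Ranks all treatments (reference included) within every posterior draw
#' — by default the most negative effect (largest PWV reduction) gets
#' rank 1 — and summarizes the empirical rank distribution by the surface
#' under the cumulative ranking curve:
#' \deqn{SUCRA_k = \frac{1}{a-1} \sum_{j=1}^{a-1} F_k(j),}
#' where \eqn{F_k(j)} is the cumulative probability that treatment
#' \eqn{k} ranks among the best \eqn{j} of \eqn{a} treatments.  SUCRA is
#' 1 for a treatment certain to be best and 0 for one certain to be
#' worst; across all treatments SUCRA always averages exactly 0.5.  Ties
#' within a draw are broken by a uniformly random permutation, which
#' keeps the rank-probability matrix doubly stochastic.
#'
#' @param fit An [nma_fit] object.
#' @param direction `"lower"` (default; smaller effect ranks better,
#'   appropriate for a change outcome where negative means improvement)
#'   or `"higher"`.
#' @return An object of class `nma_rank`: tibbles `sucra` (per
#'   treatment, proportion in `[0, 1]` and `percent`), `rank_probs` and
#'   `cum_probs` (long form, treatment x rank).  `tidy()` returns the
#'   `sucra` table.
#' @examples
#' \donttest{
#' fit <- fit_nma(pwv_trials(), chains = 2, burn_in = 500, samples = 2000)
#' tidy(sucra(fit))
#' }
#' @export
sucra <- function(fit, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  eff <- fit$d
  if (direction == "higher") eff <- -eff
  a <- ncol(eff)
  if (a < 2) abort("ranking needs at least two treatments")
  rk <- rank_draws(eff)
  nd <- nrow(eff)
  probs <- vapply(seq_len(a), function(j) tabulate(rk[, j], a) / nd,
                  numeric(a))             # rank x treatment
  cum <- apply(probs, 2, cumsum)
  suc <- colSums(cum[seq_len(a - 1), , drop = FALSE]) / (a - 1)
  trts <- colnames(eff)
  long <- function(m, value) {
    tibble::tibble(
      treatment = rep(trts, each = a),
      rank = rep(seq_len(a), times = a),
      !!value := as.vector(m)
    )
  }
  structure(list(
    treatments = trts,
    direction = direction,
    sucra = tibble::tibble(treatment = trts, sucra = unname(suc),
                           percent = unname(100 * suc)),
    rank_probs = long(probs, "probability"),
    cum_probs = long(cum, "cumulative_probability")
  ), class = "nma_rank")
}

# Per-draw ranks with uniformly random tie-breaking.
rank_draws <- function(eff) {
  t(apply(eff, 1, rank, ties.method = "random"))
}

#' @export
print.nma_rank <- function(x, ...) {
  cat("SUCRA ranking (", x$direction, " effect ranks better)\n", sep = "")
  print(dplyr::arrange(x$sucra, dplyr::desc(.data$sucra)), ...)
  invisible(x)
}

#' @rdname sucra
#' @param x An `nma_rank` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nma_rank <- function(x, ...) {
  dplyr::arrange(x$sucra, dplyr::desc(.data$sucra))
}

#' @rdname sucra
#' @param object An `nma_rank` object.
#' @exportS3Method ggplot2::autoplot
autoplot.nma_rank <- function(object, ...) {
  ggplot2::ggplot(object$cum_probs,
                  ggplot2::aes(x = .data$rank,
                               y = .data$cumulative_probability)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "Rank", y = "Cumulative probability",
                  title = "Cumulative ranking curves") +
    ggplot2::theme_minimal()
}
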