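# MCMC building blocks: univariate slice sampler and split-R-hat.

# One slice-sampling update (stepping out + shrinkage; Neal 2003) for a
# univariate target on (lower, upper).  logf need not be normalized.
slice_update <- function(x0, logf, lower, upper, w = 0.5, max_steps = 50L) {
  ly <- logf(x0) - rexp(1)
  u <- runif(1)
  L <- max(lower, x0 - w * u)
  R <- min(upper, L + w)
  steps <- max_steps
  while (L > lower && logf(L) > ly && steps > 0L) {
    L <- max(lower, L - w); steps <- steps - 1L
  }
  steps <- max_steps
  while (R < upper && logf(R) > ly && steps > 0L) {
    R <- min(upper, R + w); steps <- steps - 1L
  }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Split-R-hat (Gelman-Rubin with each chain split in half).
# draws: list of numeric vectors, one per chain, equal length.
split_rhat <- function(draws) {
  half <- floor(min(lengths(draws)) / 2)
  if (half < 2) return(NA_real_)
  seqs <- unlist(lapply(draws, function(x) {
    list(x[seq_len(half)], x[seq_len(half) + half])
  }), recursive = FALSE)
  m <- length(seqs)
  n <- half
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
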