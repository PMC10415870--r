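#' Enumerate the evidence loops of a treatment network
#'
#' Finds every chordless cycle of length 3 or 4 in the direct-comparison
#' graph — the loops around which direct and indirect evidence can be
#' confronted.  Each loop is returned once, in canonical orientation
#' (started at its codebook-first treatment, proceeding toward the
#' codebook-smaller neighbour).
#'
#' @inheritParams validate_trials
#' @return A tibble with `loop` (label) and `treatments` (list column of
#'   treatment codes in cycle order); zero rows for a tree network.
#' @examples
#' enumerate_loops(pwv_trials())
#' @export
enumerate_loops <- function(x, codebook = pwv_treatments()) {
  ed <- network_edges(x, codebook)
  nodes <- codebook$code[codebook$code %in% unique(x$treatment)]
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(ed))) {
    adj[ed$treat1[i], ed$treat2[i]] <- TRUE
    adj[ed$treat2[i], ed$treat1[i]] <- TRUE
  }
  loops <- list()
  if (length(nodes) >= 3) {
    tri <- utils::combn(nodes, 3, simplify = FALSE)
    for (s in tri) {
      if (adj[s[1], s[2]] && adj[s[2], s[3]] && adj[s[1], s[3]]) {
        loops <- c(loops, list(s))
      }
    }
  }
  if (length(nodes) >= 4) {
    quads <- utils::combn(nodes, 4, simplify = FALSE)
    for (s in quads) {
      # three distinct 4-cycles on a vertex set; chordless means the two
      # non-cycle pairs are non-edges
      orders <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4))
      for (o in orders) {
        v <- s[o]
        cyc <- adj[v[1], v[2]] && adj[v[2], v[3]] &&
          adj[v[3], v[4]] && adj[v[4], v[1]]
        chords <- adj[v[1], v[3]] || adj[v[2], v[4]]
        if (cyc && !chords) loops <- c(loops, list(canonical_cycle(v, codebook)))
      }
    }
  }
  loops <- unique(loops)
  tibble::tibble(
    loop = vapply(loops, paste, "", collapse = "-"),
    treatments = loops
  )
}

# Rotate/reflect a cycle to a canonical orientation.
canonical_cycle <- function(v, codebook) {
  ord <- match(v, codebook$code)
  k <- length(v)
  start <- which.min(ord)
  idx <- c(seq(start, k), seq_len(start - 1))
  v <- v[idx]; ord <- ord[idx]
  if (ord[2] > ord[k]) v <- c(v[1], rev(v[-1]))
  v
}

#' Bucher loop-inconsistency factor
#'
#' Confronts direct and indirect evidence around one loop: each edge's
#' direct studies are pooled by inverse variance with a loop-common
#' between-trial variance (method of moments over the loop's edges), the
#' pooled estimates are summed around the oriented cycle, and the
#' absolute discrepancy is the inconsistency factor IF.  Its standard
#' error adds the edge variances; `z = IF / se` gives a two-sided normal
#' p-value, with p < 0.05 flagged as inconsistent.  The 95% CI of IF is
#' truncated at zero by convention.
#'
#' @param loop Character vector of treatment codes in cycle order
#'   (length 3 or 4).
#' @param contrasts Contrast tibble from [build_contrasts()].
#' @return A one-row tibble: `loop`, `if_abs`, `se_if`, `ci_low`,
#'   `ci_high`, `z`, `p`, `tau2_loop`, `inconsistent`.
#' @export
loop_if <- function(loop, contrasts) {
  k <- length(loop)
  stopifnot(k >= 3)
  edges <- lapply(seq_len(k), function(j) c(loop[j], loop[j %% k + 1]))
  per_edge <- lapply(edges, function(e) {
    sub <- dplyr::filter(contrasts,
                         (.data$treat == e[1] & .data$comparator == e[2]) |
                           (.data$treat == e[2] & .data$comparator == e[1]))
    if (nrow(sub) == 0) {
      abort(paste0("loop edge ", e[1], "-", e[2], " has no direct evidence"))
    }
    sign <- ifelse(sub$treat == e[1], 1, -1)
    list(md = sign * sub$md, v = sub$se^2)
  })
  # loop-common tau^2 by method of moments across the loop's edges
  num <- 0; den <- 0
  for (pe in per_edge) {
    w <- 1 / pe$v
    if (length(w) > 1) {
      mfe <- sum(w * pe$md) / sum(w)
      num <- num + sum(w * (pe$md - mfe)^2) - (length(w) - 1)
      den <- den + sum(w) - sum(w^2) / sum(w)
    }
  }
  tau2 <- if (den > 0) max(0, num / den) else 0
  est <- vapply(per_edge, function(pe) {
    w <- 1 / (pe$v + tau2)
    sum(w * pe$md) / sum(w)
  }, numeric(1))
  vs <- vapply(per_edge, function(pe) 1 / sum(1 / (pe$v + tau2)), numeric(1))
  if_signed <- sum(est)
  if_abs <- abs(if_signed)
  se_if <- sqrt(sum(vs))
  z <- if_abs / se_if
  p <- 2 * pnorm(-z)
  tibble::tibble(
    loop = paste(loop, collapse = "-"),
    if_abs = if_abs, se_if = se_if,
    ci_low = max(0, if_abs - qnorm(0.975) * se_if),
    ci_high = if_abs + qnorm(0.975) * se_if,
    z = z, p = p, tau2_loop = tau2,
    inconsistent = p < 0.05
  )
}

#' Loop-inconsistency report for every loop in a network
#'
#' @inheritParams validate_trials
#' @param contrasts Optional precomputed contrasts; built from `x` when
#'   omitted.
#' @return One [loop_if()] row per enumerated loop.
#' @export
loop_inconsistency <- function(x, codebook = pwv_treatments(),
                               contrasts = NULL) {
  if (is.null(contrasts)) contrasts <- build_contrasts(x, codebook)
  loops <- enumerate_loops(x, codebook)
  purrr::map_dfr(loops$treatments, loop_if, contrasts = contrasts)
}

#' Global design-by-treatment inconsistency test
#'
#' Two-stage Wald test of the consistency assumption.  A shared
#' between-trial variance is estimated by the method of moments from the
#' unrelated-design-means (inconsistency) model, so that genuine
#' between-design disagreement is not absorbed into heterogeneity; each
#' design (treatment pair, for two-arm studies) is then pooled and the
#' pooled design means are tested against the best-fitting set of
#' consistent basic effects.  The statistic is
#' chi-squared with degrees of freedom equal to the number of designs
#' minus the number of identifiable basic effects — zero exactly when the
#' network has no loops, in which case the test is undefined and an error
#' is raised.
#'
#' @param contrasts Contrast tibble from [build_contrasts()].
#' @param reference Reference treatment code.
#' @return A one-row tibble: `statistic`, `df`, `p`, `tau2`.
#' @export
global_inconsistency <- function(contrasts, reference = "placebo") {
  trts <- unique(c(contrasts$treat, contrasts$comparator))
  act <- setdiff(trts, reference)
  y <- contrasts$md
  v <- contrasts$se^2
  n <- length(y)

  # A design is the unordered treatment pair: align orientations so the
  # same comparison reported both ways is one design.
  flip <- contrasts$treat > contrasts$comparator
  key <- ifelse(flip,
                paste(contrasts$comparator, contrasts$treat, sep = "|"),
                paste(contrasts$treat, contrasts$comparator, sep = "|"))
  y_al <- ifelse(flip, -y, y)

  # shared tau^2: DerSimonian-Laird moments within designs (the
  # unrelated-design-means model), summed over designs
  w <- 1 / v
  q_within <- 0; mom_denom <- 0; df_within <- 0L
  for (k in unique(key)) {
    i <- key == k
    if (sum(i) > 1) {
      wi <- w[i]
      mfe <- sum(wi * y_al[i]) / sum(wi)
      q_within <- q_within + sum(wi * (y_al[i] - mfe)^2)
      mom_denom <- mom_denom + sum(wi) - sum(wi^2) / sum(wi)
      df_within <- df_within + sum(i) - 1L
    }
  }
  tau2 <- if (mom_denom > 0) {
    max(0, (q_within - df_within) / mom_denom)
  } else 0

  # stage two: pool per design, test pooled means against consistency
  wstar <- 1 / (v + tau2)
  agg <- tibble::tibble(key = key, y = y_al, w = wstar)
  agg <- dplyr::summarise(dplyr::group_by(agg, .data$key),
                          m = sum(.data$w * .data$y) / sum(.data$w),
                          V = 1 / sum(.data$w), .groups = "drop")
  parts <- strsplit(agg$key, "|", fixed = TRUE)
  Xe <- design_rows(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2), act)
  df <- nrow(Xe) - qr(Xe)$rank
  if (df <= 0) {
    abort("global inconsistency test undefined: network has no loops")
  }
  We <- 1 / agg$V
  de <- solve(crossprod(Xe, Xe * We), crossprod(Xe, We * agg$m))
  stat <- sum(We * (agg$m - Xe %*% de)^2)
  tibble::tibble(statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE), tau2 = tau2)
}

design_rows <- function(treat, comparator, act) {
  X <- matrix(0, length(treat), length(act),
              dimnames = list(NULL, act))
  for (i in seq_along(treat)) {
    if (treat[i] %in% act) X[i, treat[i]] <- 1
    if (comparator[i] %in% act) X[i, comparator[i]] <- X[i, comparator[i]] - 1
  }
  X
}
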