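#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow on an arm-level dataset: contrasts,
#' pairwise meta-analysis and funnel data, the Bayesian NMA on all
#' studies and on the abnormal-glucose-metabolism subgroup, SUCRA
#' rankings for both fits, loop and global inconsistency, and
#' plot-ready league/forest tables.  Deterministic given `seed`: two runs
#' with the same seed produce identical numeric output.
#'
#' @inheritParams fit_nma
#' @param subgroup Run the AGMD-subgroup fit as well (default `TRUE`;
#'   skipped automatically when the subgroup equals the full dataset).
#' @return An object of class `pwv_report`, a list with elements
#'   `contrasts`, `pairwise`, `funnel`, `fit_all`, `fit_agmd`,
#'   `league_all`, `league_agmd`, `sucra_all`, `sucra_agmd`, `forest`,
#'   `loops`, `global` and `provenance`.
#' @examples
#' \donttest{
#' rep <- run_full_analysis(pwv_trials(), chains = 2,
#'                          burn_in = 500, samples = 2000)
#' rep$forest
#' }
#' @export
run_full_analysis <- function(x = pwv_trials(), codebook = pwv_treatments(),
                              corr = 0.5, chains = 3, burn_in = 20000,
                              samples = 80000, seed = 1, subgroup = TRUE,
                              ...) {
  validate_trials(x, codebook)
  contrasts <- build_contrasts(x, codebook, corr = corr)
  pairwise <- pool_pairwise(contrasts)
  funnel <- funnel_data(contrasts)

  fit_all <- fit_nma(x, codebook, corr = corr, chains = chains,
                     burn_in = burn_in, samples = samples, seed = seed, ...)
  agmd <- dplyr::filter(x, .data$agmd)
  do_sub <- subgroup && nrow(agmd) > 0 && nrow(agmd) < nrow(x)
  fit_agmd <- if (do_sub) {
    fit_nma(filter_agmd(x, codebook), codebook, corr = corr, chains = chains,
            burn_in = burn_in, samples = samples, seed = seed + 1, ...)
  }

  sucra_all <- sucra(fit_all)
  sucra_agmd <- if (!is.null(fit_agmd)) sucra(fit_agmd)
  forest <- forest_rows(fit_all, "all")
  if (!is.null(fit_agmd)) {
    forest <- dplyr::bind_rows(forest, forest_rows(fit_agmd, "agmd"))
  }

  loops <- loop_inconsistency(x, codebook, contrasts = contrasts)
  global <- global_inconsistency(contrasts, reference = reference_code(codebook))

  structure(list(
    contrasts = contrasts, pairwise = pairwise, funnel = funnel,
    fit_all = fit_all, fit_agmd = fit_agmd,
    league_all = league_table(fit_all),
    league_agmd = if (!is.null(fit_agmd)) league_table(fit_agmd),
    sucra_all = sucra_all, sucra_agmd = sucra_agmd,
    forest = forest, loops = loops, global = global,
    provenance = list(seed = seed, corr = corr, chains = chains,
                      burn_in = burn_in, samples = samples,
                      package_version = as.character(utils::packageVersion("pwvnma")),
                      r_version = R.version.string)
  ), class = "pwv_report")
}

forest_rows <- function(fit, analysis) {
  act <- setdiff(fit$treatments, fit$reference)
  rows <- purrr::map_dfr(act, contrast_effect, fit = fit,
                         comparator = fit$reference)
  dplyr::transmute(rows,
                   analysis = analysis,
                   label = paste(.data$treat, "vs", .data$comparator),
                   treat = .data$treat,
                   md = .data$estimate,
                   ci_low = .data$ci_low, ci_high = .data$ci_high,
                   significant = .data$significant)
}

#' @export
print.pwv_report <- function(x, ...) {
  cat("PWV network meta-analysis report\n")
  cat("--------------------------------\n")
  g <- glance(x$fit_all)
  cat("All studies:", g$n_studies, "trials,", g$n_treatments,
      "treatments; tau median", round(g$tau_median, 2), "\n")
  sig <- dplyr::filter(x$forest, .data$analysis == "all", .data$significant)
  cat("Significant vs", x$fit_all$reference, "comparisons:",
      if (nrow(sig)) paste(sig$treat, collapse = ", ") else "none", "\n")
  if (!is.null(x$fit_agmd)) {
    ga <- glance(x$fit_agmd)
    cat("AGMD subgroup:", ga$n_studies, "trials; tau median",
        round(ga$tau_median, 2), "\n")
  }
  cat("Global inconsistency: chi2 =", round(x$global$statistic, 2),
      "df =", x$global$df, "p =", round(x$global$p, 3), "\n")
  cat("Loops:", nrow(x$loops), "assessed,",
      sum(x$loops$inconsistent), "inconsistent at p < 0.05\n")
  invisible(x)
}

#' Write a report's tables to disk
#'
#' Emits the report's components as CSV files (league tables, SUCRA,
#' forest rows, pairwise results, loop report, funnel data) plus a JSON
#' file with the global test and provenance, into `dir`.
#'
#' @param report A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  emit <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(obj, p)
    paths <<- c(paths, p)
  }
  emit(report$contrasts, "contrasts")
  emit(report$pairwise, "pairwise")
  emit(report$funnel, "funnel")
  emit(report$league_all, "league_all")
  if (!is.null(report$league_agmd)) emit(report$league_agmd, "league_agmd")
  emit(tidy(report$sucra_all), "sucra_all")
  if (!is.null(report$sucra_agmd)) emit(tidy(report$sucra_agmd), "sucra_agmd")
  emit(report$forest, "forest")
  emit(report$loops, "loops")
  pj <- file.path(dir, "global.json")
  jsonlite::write_json(list(global = as.list(report$global),
                            provenance = report$provenance),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}
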