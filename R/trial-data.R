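#' Populations counted as abnormal glucose metabolism disease (AGMD)
#'
#' Pre-type-2-diabetes, type 1 and type 2 diabetes form the AGMD subgroup;
#' trials in coronary artery disease, chronic heart failure or
#' non-alcoholic fatty liver disease populations fall outside it.
#'
#' @export
agmd_populations <- c("pre-T2DM", "T1DM", "T2DM")

pwv_populations <- c("pre-T2DM", "T1DM", "T2DM", "CAD", "CHF", "NAFLD")

#' Example dataset: 18 randomized trials of antidiabetic drugs and PWV change
#'
#' Arm-level summaries (one row per trial arm) of 18 published randomized
#' controlled trials comparing six antidiabetic drug classes with each other
#' or with placebo, with change in pulse wave velocity (m/s) from baseline
#' to end of treatment as the outcome.  Values are stored exactly as printed
#' in the source trial reports' summary table; negative change means
#' improved (lower) arterial stiffness.  Within each study the experimental
#' arm comes first and the control/comparator arm last.
#'
#' One quirk is preserved deliberately: the Kolwelter trial studied
#' empagliflozin (an SGLT-2 inhibitor) but is labelled DPP-4i in the source
#' summary table.  The default keeps the printed class so that analyses
#' track the published network; `reclassify_kolwelter = TRUE` assigns the
#' pharmacologically correct class instead.  The network edge set is the
#' same either way.
#'
#' @param reclassify_kolwelter Logical; reassign the Kolwelter experimental
#'   arm from `DPP4i` (as printed) to `SGLT2i` (pharmacologically correct).
#'
#' @return A tibble with one row per arm and columns `study_id`,
#'   `treatment`, `n`, `change_mean`, `change_sd`, `baseline_mean`,
#'   `baseline_sd`, `final_mean`, `final_sd` (all PWV in m/s),
#'   `population`, `duration_weeks` and the derived logical `agmd`.
#' @examples
#' trials <- pwv_trials()
#' dplyr::count(trials, study_id)
#' @export
pwv_trials <- function(reclassify_kolwelter = FALSE) {
  x <- tibble::tribble(
    ~study_id,      ~treatment,  ~n, ~change_mean, ~change_sd, ~baseline_mean, ~baseline_sd, ~population, ~duration_weeks,
    "Christoph",    "TZD",       27,  0.7,  2.1, 12.9, 3.5, "CAD",      36,
    "Christoph",    "placebo",   27,  0.5,  2.1, 13.9, 3.6, "CAD",      36,
    "Antonio",      "SGLT2i",    42, -0.6,  1.4,  6.2, 1.6, "T2DM",     24,
    "Antonio",      "placebo",   42,  0.6,  1.2,  6.0, 1.0, "T2DM",     24,
    "Ikonomidis",   "GLP1RA",    40, -1.1,  2.4, 11.6, 2.8, "T2DM",     48,
    "Ikonomidis",   "SGLT2i",    40, -1.1,  2.5, 12.0, 2.8, "T2DM",     48,
    "Stakos",       "TZD",       40,  1.1,  0.4,   NA,  NA, "T2DM",     48,
    "Stakos",       "placebo",   97,  0.7,  0.4,   NA,  NA, "T2DM",     48,
    "Lambadiari",   "GLP1RA",    30, -0.6,  2.8, 11.8, 2.5, "T2DM",     24,
    "Lambadiari",   "metformin", 30, -0.2,  3.2, 10.3, 3.3, "T2DM",     24,
    "Tuttolomondo", "GLP1RA",    56, -0.3,  0.8, 11.2, 0.9, "T2DM",     36,
    "Tuttolomondo", "metformin", 56,  0.1,  0.7, 10.9, 0.8, "T2DM",     36,
    "Kato",         "TZD",       25,  0.08, 0.4, 15.4, 0.4, "T2DM",     12,
    "Kato",         "metformin", 25,  0.01, 0.4, 14.7, 0.4, "T2DM",     12,
    "Papadopoulou", "SGLT2i",    43, -0.2,  1.1,  8.8, 1.1, "T2DM",     12,
    "Papadopoulou", "placebo",   42,  0.01, 1.3,  8.7, 1.3, "T2DM",     12,
    "deBoer",       "DPP4i",     22, -0.4,  0.3,  8.7, 0.3, "T2DM",     26,
    "deBoer",       "placebo",   22,  0.4,  0.3,  8.8, 0.3, "T2DM",     26,
    "Kolwelter",    "DPP4i",     48, -0.3,  1.6,  9.6, 1.5, "CHF",      12,
    "Kolwelter",    "placebo",   26,  0.3,  1.7,  9.0, 1.6, "CHF",      12,
    "Zografou",     "DPP4i",     32, -0.3,  1.5,  8.6, 2.1, "T2DM",     24,
    "Zografou",     "metformin", 32,  0.2,  1.8,  8.9, 2.0, "T2DM",     24,
    "Paiman",       "GLP1RA",    22,  0.2,  2.1,  8.8, 2.4, "T2DM",     26,
    "Paiman",       "placebo",   25, -0.2,  1.7,  8.3, 2.4, "T2DM",     26,
    "Kim",          "TZD",       45, -0.9,  2.5, 14.8, 2.6, "pre-T2DM", 12,
    "Kim",          "placebo",   40,  0.02, 2.0, 14.4, 2.3, "pre-T2DM", 12,
    "Bjornstad",    "metformin", 24, -1.1,  1.2,   NA,  NA, "T1DM",     12,
    "Bjornstad",    "placebo",   21,  4.1,  1.6,   NA,  NA, "T1DM",     12,
    "Scalzo",       "SU",        13, -0.3,  0.9, 10.1, 1.0, "T2DM",     12,
    "Scalzo",       "DPP4i",     14,  0.2,  1.1, 11.6, 1.1, "T2DM",     12,
    "Martin",       "DPP4i",     24, -0.1,  1.2,  8.6, 1.2, "T2DM",     24,
    "Martin",       "SU",        24, -0.4,  1.3,  8.5, 1.3, "T2DM",     24,
    "Sofer",        "metformin", 32, -1.0,  0.9,  6.7, 1.1, "NAFLD",    12,
    "Sofer",        "placebo",   31,  0.2,  1.0,  6.3, 1.0, "NAFLD",    12,
    "Watanabe",     "TZD",       13, -1.0,  2.2, 15.2, 2.5, "T2DM",     24,
    "Watanabe",     "SU",        14,  0.1,  1.8, 15.2, 1.7, "T2DM",     24
  )
  if (reclassify_kolwelter) {
    x$treatment[x$study_id == "Kolwelter" & x$treatment == "DPP4i"] <- "SGLT2i"
  }
  x$final_mean <- NA_real_
  x$final_sd <- NA_real_
  x$agmd <- x$population %in% agmd_populations
  x[, c("study_id", "treatment", "n", "change_mean", "change_sd",
        "baseline_mean", "baseline_sd", "final_mean", "final_sd",
        "population", "duration_weeks", "agmd")]
}

#' Read and write arm-level trial data
#'
#' `read_trials()` reads a delimited text file with one row per trial arm
#' (columns `study_id`, `treatment`, `n`, `change_mean`, `change_sd`,
#' optionally `baseline_mean`, `baseline_sd`, `final_mean`, `final_sd`,
#' plus `population` and `duration_weeks`), validates it against the
#' treatment codebook and the network-connectivity requirement, and returns
#' a tibble in the same shape as [pwv_trials()].  `write_trials()` writes
#' that tibble back out; a read/write round trip reproduces all numeric
#' fields exactly.
#'
#' @param path Path to a CSV (or TSV, inferred from the extension) file.
#' @param codebook Treatment codebook, see [pwv_treatments()].
#' @param validate Logical; run [validate_trials()] after reading.
#' @param x Arm-level tibble to write.
#'
#' @return `read_trials()` returns the validated arm-level tibble;
#'   `write_trials()` invisibly returns `path`.
#' @export
read_trials <- function(path, codebook = pwv_treatments(), validate = TRUE) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  for (col in c("baseline_mean", "baseline_sd", "final_mean", "final_sd")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
    x[[col]] <- as.numeric(x[[col]])  # all-NA columns parse as logical
  }
  x <- dplyr::mutate(x, agmd = .data$population %in% agmd_populations)
  if (validate) validate_trials(x, codebook = codebook)
  tibble::as_tibble(x)
}

#' @rdname read_trials
#' @export
write_trials <- function(x, path) {
  out <- dplyr::select(x, !dplyr::any_of("agmd"))
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate an arm-level trial dataset
#'
#' Checks the structural invariants required by the downstream analyses:
#' known treatment codes, at least two arms per study with distinct
#' treatments, analysable sample sizes (`n >= 2`), a positive change-score
#' SD (or baseline and final SDs from which one can be imputed), admissible
#' population labels, treatment durations of at least 12 weeks, and a
#' connected comparison network in which every treatment is reachable from
#' the reference.  All violations are collected and reported together with
#' row numbers.
#'
#' @param x Arm-level tibble as returned by [pwv_trials()] or [read_trials()].
#' @inheritParams read_trials
#'
#' @return Invisibly `x`, or an error listing every violation.
#' @export
validate_trials <- function(x, codebook = pwv_treatments()) {
  codebook <- check_codebook(codebook)
  required <- c("study_id", "treatment", "n", "change_mean", "change_sd",
                "population", "duration_weeks")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  note <- function(rows, what) {
    problems <<- c(problems,
                   paste0(what, " (row", if (length(rows) > 1) "s" else "",
                          " ", paste(rows, collapse = ", "), ")"))
  }

  bad <- which(!x$treatment %in% codebook$code)
  if (length(bad)) note(bad, "unknown treatment code")
  bad <- which(is.na(x$n) | x$n < 2 | x$n != round(x$n))
  if (length(bad)) note(bad, "sample size n must be an integer >= 2")
  bad <- which(!is.na(x$change_sd) & x$change_sd <= 0)
  if (length(bad)) note(bad, "change_sd must be positive")
  has_bf <- if (all(c("baseline_sd", "final_sd") %in% names(x))) {
    !is.na(x$baseline_sd) & !is.na(x$final_sd)
  } else {
    rep(FALSE, nrow(x))
  }
  bad <- which(is.na(x$change_sd) & !has_bf)
  if (length(bad)) note(bad, "change_sd absent and not imputable (needs baseline_sd and final_sd)")
  bad <- which(!x$population %in% pwv_populations)
  if (length(bad)) note(bad, paste0("population must be one of ",
                                    paste(pwv_populations, collapse = ", ")))
  bad <- which(is.na(x$duration_weeks) | x$duration_weeks < 12)
  if (length(bad)) note(bad, "duration_weeks must be >= 12")

  by_study <- split(seq_len(nrow(x)), x$study_id)
  for (sid in names(by_study)) {
    rows <- by_study[[sid]]
    if (length(rows) < 2) note(rows, paste0("study '", sid, "' has a single arm"))
    dup <- rows[duplicated(x$treatment[rows])]
    if (length(dup)) note(dup, paste0("duplicate treatment within study '", sid, "'"))
  }

  if (length(problems) == 0) {
    conn <- network_connected(x, codebook)
    if (!conn$connected) {
      problems <- c(problems, paste0(
        "network disconnected: treatment(s) ",
        paste(conn$unreachable, collapse = ", "),
        " not reachable from reference '", reference_code(codebook), "'"))
    }
  }

  if (length(problems) > 0) {
    abort(paste0("invalid trial dataset:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(x)
}

# Connectivity of the comparison graph, taken from the reference treatment.
# Treatments in the codebook but absent from the data count as unreachable
# only for the reference itself (an absent reference makes everything
# unreachable); absent non-reference treatments are ignored.
network_connected <- function(x, codebook = pwv_treatments()) {
  ref <- reference_code(codebook)
  trts <- unique(x$treatment)
  ed <- network_edges(x, codebook)
  g <- igraph::graph_from_data_frame(
    ed[, c("treat1", "treat2")], directed = FALSE,
    vertices = data.frame(name = union(trts, ref))
  )
  comp <- igraph::components(g)
  ref_comp <- comp$membership[ref]
  unreachable <- names(comp$membership)[comp$membership != ref_comp]
  list(connected = length(unreachable) == 0, unreachable = unreachable)
}

#' Direct-comparison edges of the treatment network
#'
#' One row per unordered treatment pair compared head-to-head in at least
#' one study, with the number of studies providing the comparison.  Pairs
#' are oriented in codebook order.
#'
#' @inheritParams validate_trials
#' @return A tibble with columns `treat1`, `treat2`, `n_studies`.
#' @export
network_edges <- function(x, codebook = pwv_treatments()) {
  ord <- match(x$treatment, codebook$code)
  pairs <- dplyr::group_by(
    tibble::tibble(study_id = x$study_id, treatment = x$treatment, ord = ord),
    .data$study_id)
  pairs <- dplyr::reframe(pairs, {
    o <- order(ord)
    tr <- .data$treatment[o]
    cmb <- utils::combn(tr, 2)
    tibble::tibble(treat1 = cmb[1, ], treat2 = cmb[2, ])
  })
  dplyr::count(pairs, .data$treat1, .data$treat2, name = "n_studies")
}

#' Summarize network geometry
#'
#' @inheritParams validate_trials
#' @return A one-row tibble: number of studies, treatments and direct
#'   edges, whether the network is connected, and how many studies are
#'   placebo-controlled versus head-to-head (relative to the reference).
#' @export
network_geometry <- function(x, codebook = pwv_treatments()) {
  ref <- reference_code(codebook)
  by_study <- split(x$treatment, x$study_id)
  has_ref <- vapply(by_study, function(tr) ref %in% tr, logical(1))
  tibble::tibble(
    n_studies = length(by_study),
    n_treatments = length(unique(x$treatment)),
    n_edges = nrow(network_edges(x, codebook)),
    connected = network_connected(x, codebook)$connected,
    n_reference_controlled = sum(has_ref),
    n_head_to_head = sum(!has_ref)
  )
}

#' Restrict a dataset to the abnormal-glucose-metabolism subgroup
#'
#' Keeps only studies whose population is pre-T2DM, T1DM or T2DM and
#' re-validates the resulting network.  Errors if no AGMD studies remain or
#' if the restricted network is disconnected.
#'
#' @inheritParams validate_trials
#' @return The filtered arm-level tibble.
#' @export
filter_agmd <- function(x, codebook = pwv_treatments()) {
  out <- dplyr::filter(x, .data$population %in% agmd_populations)
  if (nrow(out) == 0) {
    abort("no AGMD studies in dataset (empty subgroup network)")
  }
  validate_trials(out, codebook = codebook)
  out
}
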