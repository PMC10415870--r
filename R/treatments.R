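#' Treatment-class codebook
#'
#' The six antidiabetic drug classes compared in the example network, plus
#' placebo.  Placebo is the reference treatment: all basic effects in the
#' Bayesian model are parameterized as differences from it.
#'
#' @param reference Code of the reference treatment.  Must appear in the
#'   codebook; defaults to `"placebo"`.
#'
#' @return A tibble with columns `code` (short identifier used in data
#'   files), `label` (display name) and `reference` (logical, exactly one
#'   `TRUE`).
#' @examples
#' pwv_treatments()
#' @export
pwv_treatments <- function(reference = "placebo") {
  cb <- tibble::tribble(
    ~code,       ~label,
    "placebo",   "Placebo",
    "GLP1RA",    "GLP-1 RA",
    "SGLT2i",    "SGLT-2 inhibitor",
    "DPP4i",     "DPP-4 inhibitor",
    "TZD",       "Thiazolidinedione",
    "SU",        "Sulfonylurea",
    "metformin", "Metformin"
  )
  if (!reference %in% cb$code) {
    abort(paste0("reference treatment '", reference, "' is not in the codebook"))
  }
  cb$reference <- cb$code == reference
  cb
}

# Validate a user-supplied codebook: unique codes, exactly one reference.
check_codebook <- function(codebook) {
  stopifnot(is.data.frame(codebook), all(c("code", "label") %in% names(codebook)))
  if (anyDuplicated(codebook$code)) {
    abort("treatment codes must be unique")
  }
  if (!"reference" %in% names(codebook)) {
    codebook$reference <- codebook$code == codebook$code[1]
  }
  if (sum(codebook$reference) != 1L) {
    abort("exactly one treatment must be flagged as the reference")
  }
  tibble::as_tibble(codebook)
}

reference_code <- function(codebook) codebook$code[codebook$reference][1]
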