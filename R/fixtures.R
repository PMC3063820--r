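#' Packaged qPCR tables from an Artemisia annua tissue survey
#'
#' Returns the printed values of a published qPCR survey of terpene-metabolism
#' genes in six *Artemisia annua* tissues, shipped with the package as
#' plain-text fixtures:
#'
#' * `"ct_means"` — average measured CT values for 19 amplicon rows
#'   (17 transcripts plus two beta-actin rows) across flower buds, young
#'   leaves, old leaves, stems, roots and hairy roots. ADS in roots was not
#'   detected and is recorded as missing with `detected = FALSE`. The
#'   `actin_b` row is the second beta-actin series (marked with a hash in the
#'   source); `DBR2` is the DBR2-specific primer pair (also hash-marked) and
#'   `DBR2_OPR3` the combined DBR2 + OPR3-like amplicon. Which run each
#'   hash-marked row belongs to is not stated in the source, so both rows are
#'   kept verbatim and pairing is left to the caller.
#' * `"efficiencies"` — calculated primer efficiencies (fold/cycle) for the
#'   18 primer pairs (1.82–1.93).
#' * `"kinetics"` — Michaelis constants, turnover numbers and substrate
#'   stoichiometries for the enzymes scored in the turnover-potential
#'   analysis. The squalene-synthase row carries the assumed
#'   `kcat = 1 s^-1` with `stoichiometry = 2` (two farnesyl-diphosphate
#'   molecules condensed per catalytic event) and is marked
#'   `kcat_assumed = TRUE`.
#'
#' @param name Which fixture to load.
#' @param format For `"ct_means"`: `"long"` (default) returns one row per
#'   gene-tissue cell with columns `gene`, `tissue`, `ct`, `detected`;
#'   `"wide"` returns genes as rows and tissues as columns.
#'
#' @return A tibble.
#' @export
#' @examples
#' artemisia_fixture("ct_means") %>% head()
#' artemisia_fixture("efficiencies")
artemisia_fixture <- function(name = c("ct_means", "efficiencies", "kinetics"),
                              format = c("long", "wide")) {
  name <- match.arg(name)
  format <- match.arg(format)
  file <- switch(name,
    ct_means = "aannua_ct_means.csv",
    efficiencies = "aannua_primer_efficiency.csv",
    kinetics = "aannua_kinetics.csv"
  )
  path <- system.file("extdata", file, package = "qpcrflux", mustWork = TRUE)
  if (name == "efficiencies") {
    return(readr::read_csv(path, col_types = "cd", progress = FALSE))
  }
  if (name == "kinetics") {
    return(readr::read_csv(path, col_types = "cccddil", progress = FALSE))
  }
  wide <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (format == "wide") {
    return(dplyr::mutate(wide, dplyr::across(
      -"gene", ~ suppressWarnings(as.numeric(.x))
    )))
  }
  wide %>%
    tidyr::pivot_longer(-"gene", names_to = "tissue", values_to = "ct_raw") %>%
    dplyr::mutate(
      detected = .data$ct_raw != "n.d.",
      ct = dplyr::if_else(.data$detected,
                          suppressWarnings(as.numeric(.data$ct_raw)),
                          NA_real_)
    ) %>%
    dplyr::select("gene", "tissue", "ct", "detected")
}
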