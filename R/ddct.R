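#' ddCt and normalized transcript amount for one target
#'
#' The Livak 2^-ddCt method with the amplification factor fixed at 2:
#' \deqn{\Delta C_T^{target} = C_T(g, t) - C_T(ref, t),\quad
#'   \Delta C_T^{cal} = C_T(g_{cal}, t_{cal}) - C_T(ref, t_{cal}),}
#' \deqn{\Delta\Delta C_T = \Delta C_T^{target} - \Delta C_T^{cal},\quad
#'   amount = 2^{-\Delta\Delta C_T}.}
#' The reference gene is always taken in the same tissue as the CT it
#' normalizes.
#'
#' @param ct_means Aggregated CT tibble with columns `gene`, `tissue`, `ct`
#'   (missing `ct` = not detected).
#' @param target_gene,target_tissue The quantified cell.
#' @param reference_gene Normalizing (housekeeping) gene.
#' @param calibrator_gene,calibrator_tissue The cell whose amount defines 1.
#'
#' @return A one-row tibble: `gene`, `tissue`, `ddct`, `amount`,
#'   `defined` (`FALSE` with `NA` values when any input CT is missing).
#' @export
#' @examples
#' ct <- artemisia_fixture("ct_means")
#' delta_delta_ct(ct, "ADS", "flower_buds", "actin", "RED1", "flower_buds")
delta_delta_ct <- function(ct_means, target_gene, target_tissue,
                           reference_gene, calibrator_gene,
                           calibrator_tissue) {
  assert_columns(ct_means, c("gene", "tissue", "ct"), "`ct_means`")
  get_ct <- function(g, t) {
    v <- ct_means$ct[ct_means$gene == g & ct_means$tissue == t]
    if (length(v) == 0) {
      abort(sprintf("No CT entry for gene '%s' in tissue '%s'.", g, t),
            class = "qpcrflux_lookup_error")
    }
    if (length(v) > 1) {
      abort(sprintf("Multiple CT entries for gene '%s' in tissue '%s'.",
                    g, t),
            class = "qpcrflux_format_error")
    }
    v
  }
  cts <- c(get_ct(target_gene, target_tissue),
           get_ct(reference_gene, target_tissue),
           get_ct(calibrator_gene, calibrator_tissue),
           get_ct(reference_gene, calibrator_tissue))
  if (anyNA(cts)) {
    return(tibble::tibble(gene = target_gene, tissue = target_tissue,
                          ddct = NA_real_, amount = NA_real_,
                          defined = FALSE))
  }
  ddct <- (cts[1] - cts[2]) - (cts[3] - cts[4])
  tibble::tibble(gene = target_gene, tissue = target_tissue, ddct = ddct,
                 amount = 2^(-ddct), defined = TRUE)
}

#' Normalized transcript amounts for a set of genes and tissues
#'
#' Applies [delta_delta_ct()] cell-wise against a single calibrator cell,
#' with the reference gene always measured in the same tissue as the cell it
#' normalizes. The calibrator cell itself has amount 1 by construction.
#'
#' @inheritParams delta_delta_ct
#' @param genes,tissues Cells to quantify (defaults: all genes except the
#'   reference, all tissues).
#' @param rounding `"exact"` keeps full precision; `"report"` rounds amounts
#'   to integers, the convention used when reporting normalized amounts.
#'
#' @return A tibble: `gene`, `tissue`, `ddct`, `amount`, `defined`.
#' @export
#' @examples
#' ct <- artemisia_fixture("ct_means")
#' amount_matrix(ct, genes = c("ADS", "ECS", "SQS"),
#'               tissues = c("flower_buds", "young_leaves"),
#'               reference_gene = "actin",
#'               calibrator_gene = "GAS", calibrator_tissue = "stems",
#'               rounding = "report")
amount_matrix <- function(ct_means, genes = NULL, tissues = NULL,
                          reference_gene, calibrator_gene,
                          calibrator_tissue,
                          rounding = c("exact", "report")) {
  rounding <- match.arg(rounding)
  genes <- genes %||% setdiff(unique(ct_means$gene), reference_gene)
  tissues <- tissues %||% unique(ct_means$tissue)
  out <- tidyr::expand_grid(gene = genes, tissue = tissues) %>%
    purrr::pmap_dfr(function(gene, tissue) {
      delta_delta_ct(ct_means, gene, tissue, reference_gene,
                     calibrator_gene, calibrator_tissue)
    })
  if (rounding == "report") out$amount <- round(out$amount)
  out
}

## reporting convention for turnover scores: integers from 10 up,
## one decimal below
round_turnover <- function(x) {
  dplyr::if_else(abs(x) >= 10, round(x), round(x, 1))
}

#' Relative turnover potential from transcript amounts and kcat
#'
#' Scores each enzyme's capacity to consume its substrate as
#' `normalized transcript amount x kcat x substrate stoichiometry`, under
#' the assumptions that active-site number is proportional to transcript
#' level and that the enzymes work at substrate saturation (so kcat alone
#' captures conversion; the Michaelis constant is carried along but unused).
#'
#' @param amounts Tibble from [amount_matrix()] (columns `gene`, `tissue`,
#'   `amount`).
#' @param kinetics Kinetics table with columns `enzyme`, `gene`,
#'   `substrate`, `km_uM`, `kcat_per_s`, `stoichiometry` (see
#'   [artemisia_fixture()]`("kinetics")`). Rows without a kcat are excluded
#'   with `excluded = TRUE`.
#' @param rounding `"exact"` or `"report"`; the report mode multiplies the
#'   integer-rounded amount by kcat and rounds scores to integers (one
#'   decimal below 10), the convention used in printed summaries.
#'
#' @return A tibble: `enzyme`, `gene`, `substrate`, `tissue`, `ddct`,
#'   `amount`, `km_uM`, `kcat_per_s`, `stoichiometry`,
#'   `relative_turnover`, `excluded`.
#' @export
turnover_potential <- function(amounts, kinetics,
                               rounding = c("exact", "report")) {
  rounding <- match.arg(rounding)
  assert_columns(amounts, c("gene", "tissue", "amount"), "`amounts`")
  assert_columns(kinetics, c("enzyme", "gene", "substrate", "kcat_per_s",
                             "stoichiometry"), "`kinetics`")
  if (!"km_uM" %in% names(kinetics)) kinetics$km_uM <- NA_real_
  out <- kinetics %>%
    dplyr::inner_join(amounts, by = "gene") %>%
    dplyr::mutate(
      amount_used = if (rounding == "report") round(.data$amount)
                    else .data$amount,
      excluded = is.na(.data$kcat_per_s) | is.na(.data$amount),
      relative_turnover = dplyr::if_else(
        .data$excluded, NA_real_,
        .data$amount_used * .data$kcat_per_s * .data$stoichiometry
      )
    )
  if (rounding == "report") {
    out$relative_turnover <- round_turnover(out$relative_turnover)
    out$amount <- out$amount_used
  }
  out %>%
    dplyr::select("enzyme", "gene", "substrate", "tissue",
                  dplyr::any_of("ddct"), "amount", "km_uM", "kcat_per_s",
                  "stoichiometry", "relative_turnover", "excluded")
}

#' Fold difference in turnover potential between two enzymes
#'
#' Ratio of two relative turnover scores in the same tissue; substrate
#' stoichiometry is already part of each score (a synthase condensing two
#' precursor molecules per event counts both).
#'
#' @param enzyme_a,enzyme_b One-row tibbles from [turnover_potential()]
#'   (rows of the same tissue).
#' @return The fold difference `a / b` (numeric).
#' @export
competition_ratio <- function(enzyme_a, enzyme_b) {
  for (x in list(enzyme_a, enzyme_b)) {
    assert_columns(x, c("tissue", "relative_turnover"),
                   "`enzyme_a`/`enzyme_b`")
    if (nrow(x) != 1) {
      abort("`enzyme_a` and `enzyme_b` must be single rows.",
            class = "qpcrflux_parameter_error")
    }
  }
  if (enzyme_a$tissue != enzyme_b$tissue) {
    abort("Turnover potentials must come from the same tissue.",
          class = "qpcrflux_parameter_error")
  }
  a <- enzyme_a$relative_turnover
  b <- enzyme_b$relative_turnover
  if (is.na(a) || is.na(b) || b == 0) {
    warn("Competition ratio undefined (missing or zero turnover).")
    return(NA_real_)
  }
  a / b
}
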