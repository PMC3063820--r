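#' Per-sample stability index of candidate reference genes
#'
#' The index of a sample is the geometric mean of the candidate genes' CT
#' values in that sample (the BestKeeper construction). Samples missing any
#' candidate are excluded with a warning.
#'
#' @param ct_means Tibble of aggregated CT values with columns `gene`,
#'   `tissue`, `ct` (one row per gene and sample; see [qc_triplets()]).
#' @param candidates Genes entering the index (default: all genes present).
#' @return A tibble with columns `tissue`, `index`.
#' @export
stability_index <- function(ct_means, candidates = NULL) {
  assert_columns(ct_means, c("gene", "tissue", "ct"), "`ct_means`")
  candidates <- candidates %||% unique(ct_means$gene)
  if (length(candidates) < 1) {
    abort("At least one candidate gene is required.",
          class = "qpcrflux_parameter_error")
  }
  wide <- ct_means %>%
    dplyr::filter(.data$gene %in% candidates) %>%
    dplyr::group_by(.data$tissue) %>%
    dplyr::summarise(
      complete = sum(!is.na(.data$ct)) == length(candidates),
      index = geometric_mean(.data$ct),
      .groups = "drop"
    )
  dropped <- wide$tissue[!wide$complete]
  if (length(dropped)) {
    warn(sprintf("Sample(s) excluded from the stability index (missing candidate CTs): %s.",
                 paste(dropped, collapse = ", ")))
  }
  wide %>%
    dplyr::filter(.data$complete) %>%
    dplyr::select("tissue", "index")
}

#' Rank candidate reference genes by CT stability
#'
#' BestKeeper-style screening: for each candidate the CT standard deviation
#' and coefficient of variation across samples are computed, together with
#' the Pearson correlation against the per-sample stability index
#' ([stability_index()]). Candidates are ranked by SD ascending; genes with
#' `sd < sd_max` cycles whose index correlation reaches `r_min` (a constant
#' gene has undefined correlation and is kept, flagged by `NA`) are selected,
#' capped at the `top` best. Genes with any non-detected sample are
#' ineligible as references.
#'
#' @inheritParams stability_index
#' @param sd_max Maximum CT standard deviation (cycles) for selection
#'   (BestKeeper's 1-cycle rule of thumb).
#' @param r_min Minimum index correlation for selection.
#' @param top Maximum number of genes selected.
#'
#' @return A tibble of class `stability_report`, ranked by SD: `gene`,
#'   `n_samples`, `mean_ct`, `sd`, `cv`, `r_index`, `eligible`, `selected`.
#' @export
rank_references <- function(ct_means, candidates = NULL, sd_max = 1,
                            r_min = 0.5, top = 3) {
  assert_columns(ct_means, c("gene", "tissue", "ct"), "`ct_means`")
  candidates <- candidates %||% unique(ct_means$gene)
  n_samples <- length(unique(ct_means$tissue))
  if (n_samples < 3) {
    abort("At least 3 samples are required to rank reference candidates.",
          class = "qpcrflux_insufficient_data")
  }
  ## index from fully-detected candidates only
  eligible_genes <- ct_means %>%
    dplyr::filter(.data$gene %in% candidates) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(eligible = !anyNA(.data$ct), .groups = "drop")
  idx <- stability_index(
    ct_means,
    eligible_genes$gene[eligible_genes$eligible]
  )
  out <- ct_means %>%
    dplyr::filter(.data$gene %in% candidates) %>%
    dplyr::left_join(idx, by = "tissue") %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_samples = sum(!is.na(.data$ct)),
      mean_ct = mean(.data$ct, na.rm = TRUE),
      sd = sd(.data$ct, na.rm = TRUE),
      r_index = suppressWarnings(
        cor(.data$ct, .data$index, use = "complete.obs")
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(cv = 100 * .data$sd / .data$mean_ct) %>%
    dplyr::left_join(eligible_genes, by = "gene") %>%
    dplyr::arrange(.data$sd) %>%
    dplyr::mutate(
      selected = .data$eligible & .data$sd < sd_max &
        (is.na(.data$r_index) | .data$r_index >= r_min),
      selected = .data$selected & cumsum(.data$selected) <= top
    ) %>%
    dplyr::select("gene", "n_samples", "mean_ct", "sd", "cv", "r_index",
                  "eligible", "selected")
  class(out) <- c("stability_report", class(out))
  out
}

#' @export
tidy.stability_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_eligible = sum(x$eligible),
    n_selected = sum(x$selected),
    min_sd = min(x$sd, na.rm = TRUE)
  )
}

#' @export
autoplot.stability_report <- function(object, sd_max = 1, ...) {
  df <- dplyr::mutate(object,
                      gene = factor(.data$gene, levels = rev(object$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sd, y = .data$gene,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = sd_max, linetype = "dashed") +
    ggplot2::labs(x = "CT standard deviation across samples (cycles)",
                  y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}
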