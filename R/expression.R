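## Per-well score whose group-mean difference is the log expression ratio:
##   s_w = log(E_t) * CT_t(w) - (1/R) sum_r log(E_r) * CT_r(w)
## so  log ratio = mean(s over control wells) - mean(s over sample wells).
well_scores <- function(ct_target, ct_refs, e_target, e_refs) {
  ct_refs <- as.matrix(ct_refs)
  log(e_target) * ct_target -
    as.vector(ct_refs %*% log(e_refs)) / length(e_refs)
}

#' Efficiency-corrected expression ratio (Pfaffl / REST model)
#'
#' Computes the expression ratio of a target gene in a sample tissue
#' relative to a control tissue, corrected for amplicon-specific
#' amplification efficiencies and normalized to one or more reference genes:
#' \deqn{ratio = \frac{E_t^{\,CT_{t,control} - CT_{t,sample}}}
#'   {\mathrm{geomean}_r\, E_r^{\,CT_{r,control} - CT_{r,sample}}}.}
#'
#' @param ct_target_sample,ct_target_control Mean CT of the target gene in
#'   the sample and control tissue.
#' @param ct_refs_sample,ct_refs_control Mean CTs of the reference genes
#'   (same length and order).
#' @param e_target Amplification efficiency of the target amplicon, in
#'   (1, 2].
#' @param e_refs Efficiencies of the reference amplicons.
#' @return The dimensionless fold change (> 0).
#' @export
#' @examples
#' # perfect doubling, target one cycle earlier in the sample: ratio 2
#' pfaffl_ratio(19, 20, 20, 20, e_target = 2, e_refs = 2)
pfaffl_ratio <- function(ct_target_sample, ct_target_control,
                         ct_refs_sample, ct_refs_control,
                         e_target, e_refs) {
  if (length(e_refs) < 1 || length(ct_refs_sample) < 1) {
    abort("At least one reference gene is required.",
          class = "qpcrflux_normalization_error")
  }
  if (length(ct_refs_sample) != length(ct_refs_control) ||
      length(ct_refs_sample) != length(e_refs)) {
    abort("Reference CTs and efficiencies must have equal length.",
          class = "qpcrflux_parameter_error")
  }
  cts <- c(ct_target_sample, ct_target_control, ct_refs_sample,
           ct_refs_control)
  if (any(!is.finite(cts))) {
    abort("All CT values must be finite.", class = "qpcrflux_parameter_error")
  }
  for (e in c(e_target, e_refs)) {
    assert_number(e, "efficiency", 1, 2, closed_lower = FALSE)
  }
  num <- e_target^(ct_target_control - ct_target_sample)
  den <- geometric_mean(e_refs^(ct_refs_control - ct_refs_sample))
  num / den
}

#' Randomization test for an expression ratio
#'
#' Builds the null distribution of the log expression ratio by randomly
#' reallocating whole replicate CT sets (each replicate's paired target and
#' reference CTs move together) between the sample and control groups, and
#' reports the +1-corrected two-sided p-value
#' \eqn{p = (b + 1)/(n_{iter} + 1)} where `b` counts null statistics at
#' least as extreme as the observed log ratio.
#'
#' @param target_sample,target_control Per-replicate CT vectors of the
#'   target gene.
#' @param refs_sample,refs_control Matrices (replicates x references) of
#'   reference-gene CTs, row-paired with the target vectors.
#' @param e_target,e_refs Amplification efficiencies.
#' @param n_iter Number of random reallocations.
#' @param seed Optional integer seed (fixed seed, identical p).
#' @return The p-value, or `NA` with a warning when either group has fewer
#'   than two replicates (test skipped).
#' @export
randomization_test <- function(target_sample, target_control,
                               refs_sample, refs_control,
                               e_target, e_refs,
                               n_iter = 2000, seed = NULL) {
  n_s <- length(target_sample); n_c <- length(target_control)
  if (n_s < 2 || n_c < 2) {
    warn("Randomization test skipped: fewer than 2 replicates per group.")
    return(NA_real_)
  }
  if (!is.null(seed)) set.seed(seed)
  s_s <- well_scores(target_sample, refs_sample, e_target, e_refs)
  s_c <- well_scores(target_control, refs_control, e_target, e_refs)
  obs <- mean(s_c) - mean(s_s)
  pool <- c(s_s, s_c)
  n <- n_s + n_c
  b <- 0L
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, n_s)
    stat <- mean(pool[-idx]) - mean(pool[idx])
    if (abs(stat) >= abs(obs)) b <- b + 1L
  }
  (b + 1) / (n_iter + 1)
}

#' Percentile bootstrap interval for an expression ratio
#'
#' Resamples replicates with replacement within each group, recomputes the
#' ratio, and returns the percentile interval (widened, if necessary, to
#' contain the point ratio).
#'
#' @inheritParams randomization_test
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval coverage level.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_interval <- function(target_sample, target_control,
                               refs_sample, refs_control,
                               e_target, e_refs,
                               n_boot = 2000, level = 0.95, seed = NULL) {
  n_s <- length(target_sample); n_c <- length(target_control)
  if (n_s < 2 || n_c < 2) {
    warn("Bootstrap skipped: fewer than 2 replicates per group.")
    return(c(ci_low = NA_real_, ci_high = NA_real_))
  }
  if (!is.null(seed)) set.seed(seed)
  s_s <- well_scores(target_sample, refs_sample, e_target, e_refs)
  s_c <- well_scores(target_control, refs_control, e_target, e_refs)
  point <- exp(mean(s_c) - mean(s_s))
  stats <- vapply(seq_len(n_boot), function(i) {
    mean(s_c[sample.int(n_c, n_c, replace = TRUE)]) -
      mean(s_s[sample.int(n_s, n_s, replace = TRUE)])
  }, numeric(1))
  stats <- stats[is.finite(stats)]
  qs <- exp(quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                     names = FALSE))
  c(ci_low = min(qs[1], point), ci_high = max(qs[2], point))
}

#' Expression ratios for all genes and tissues relative to a control tissue
#'
#' For every target gene and non-control tissue, computes the
#' efficiency-corrected expression ratio normalized to the reference genes
#' ([pfaffl_ratio()] on group-mean CTs), a randomization p-value and a
#' percentile bootstrap interval. Replicate pairing is at the well level:
#' a well contributes only when the target and all reference CTs are
#' detected in it.
#'
#' @param ct Well-level CT tibble (`gene`, `tissue`, `bio_rep`, `tech_rep`,
#'   `ct`, `detected`).
#' @param efficiencies Named vector or `gene`/`efficiency` tibble covering
#'   targets and references.
#' @param reference_genes Reference (housekeeping) gene labels.
#' @param control_tissue Calibrator tissue all ratios are relative to.
#' @param target_genes Genes to test (default: all non-reference genes).
#' @param n_iter Randomization iterations ([randomization_test()]).
#' @param n_boot Bootstrap resamples; 0 skips interval estimation.
#' @param level Bootstrap interval level.
#' @param seed Integer seed making the whole table reproducible.
#' @param p_adjust Multiple-testing correction applied across all ratios
#'   (`"none"` by default; e.g. `"BH"` adds a `p_adj` column).
#'
#' @return A tibble of class `expression_ratios`: `gene`, `tissue`,
#'   `control`, `ratio`, `ci_low`, `ci_high`, `p_value`, `n_sample`,
#'   `n_control`.
#' @export
relative_expression <- function(ct, efficiencies, reference_genes,
                                control_tissue, target_genes = NULL,
                                n_iter = 2000, n_boot = 2000, level = 0.95,
                                seed = NULL, p_adjust = "none") {
  assert_columns(ct, c("gene", "tissue", "bio_rep", "tech_rep", "ct",
                       "detected"), "`ct`")
  eff <- as_efficiency_vector(efficiencies)
  if (length(reference_genes) < 1) {
    abort("At least one reference gene is required.",
          class = "qpcrflux_normalization_error")
  }
  if (!control_tissue %in% ct$tissue) {
    abort(sprintf("Control tissue '%s' not present in the CT table.",
                  control_tissue),
          class = "qpcrflux_parameter_error")
  }
  target_genes <- target_genes %||%
    setdiff(unique(ct$gene), reference_genes)
  e_refs <- lookup_efficiency(eff, reference_genes)
  if (!is.null(seed)) set.seed(seed)

  ## wells x genes CT matrix per tissue, complete rows only
  ct_wide <- ct %>%
    dplyr::filter(.data$detected, !is.na(.data$ct)) %>%
    dplyr::select("gene", "tissue", "bio_rep", "tech_rep", "ct") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")

  group_mats <- function(tissue, genes) {
    df <- ct_wide[ct_wide$tissue == tissue, genes, drop = FALSE]
    df <- df[stats::complete.cases(df), , drop = FALSE]
    as.matrix(df)
  }

  tissues <- setdiff(unique(ct$tissue), control_tissue)
  rows <- purrr::map_dfr(target_genes, function(g) {
    e_t <- lookup_efficiency(eff, g)
    purrr::map_dfr(tissues, function(tt) {
      cols <- c(g, reference_genes)
      if (!all(cols %in% names(ct_wide))) {
        return(tibble::tibble())
      }
      m_s <- group_mats(tt, cols)
      m_c <- group_mats(control_tissue, cols)
      n_s <- nrow(m_s); n_c <- nrow(m_c)
      if (n_s < 1 || n_c < 1) {
        return(tibble::tibble(gene = g, tissue = tt,
                              control = control_tissue, ratio = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p_value = NA_real_, n_sample = n_s,
                              n_control = n_c))
      }
      ratio <- pfaffl_ratio(mean(m_s[, g]), mean(m_c[, g]),
                            colMeans(m_s[, reference_genes, drop = FALSE]),
                            colMeans(m_c[, reference_genes, drop = FALSE]),
                            e_t, e_refs)
      p <- if (n_s >= 2 && n_c >= 2) {
        randomization_test(m_s[, g], m_c[, g],
                           m_s[, reference_genes, drop = FALSE],
                           m_c[, reference_genes, drop = FALSE],
                           e_t, e_refs, n_iter = n_iter)
      } else NA_real_
      ci <- if (n_boot > 0 && n_s >= 2 && n_c >= 2) {
        bootstrap_interval(m_s[, g], m_c[, g],
                           m_s[, reference_genes, drop = FALSE],
                           m_c[, reference_genes, drop = FALSE],
                           e_t, e_refs, n_boot = n_boot, level = level)
      } else c(ci_low = NA_real_, ci_high = NA_real_)
      tibble::tibble(gene = g, tissue = tt, control = control_tissue,
                     ratio = ratio, ci_low = ci[["ci_low"]],
                     ci_high = ci[["ci_high"]], p_value = p,
                     n_sample = n_s, n_control = n_c)
    })
  })
  if (p_adjust != "none") {
    rows$p_adj <- p.adjust(rows$p_value, method = p_adjust)
  }
  class(rows) <- c("expression_ratios", class(rows))
  rows
}

#' @export
autoplot.expression_ratios <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("expression ratio vs %s (log scale)",
                              object$control[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
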