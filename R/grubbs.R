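#' Two-sided Grubbs critical value
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The critical value
#'   \eqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}} with \eqn{t}
#'   the upper \eqn{\alpha/(2n)} quantile of Student's t on \eqn{n-2} df.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  assert_number(n, "n", 3)
  assert_number(alpha, "alpha", 0, 1, closed_lower = FALSE,
                closed_upper = FALSE)
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Detect a single outlier in a CT triplet by the Grubbs test
#'
#' Computes \eqn{G = \max_i |x_i - \bar x| / s} (sample SD) and flags the most
#' extreme value when `G` exceeds the two-sided critical value. At most one
#' value is ever flagged (single pass, no iterative re-testing). With fewer
#' than three values the test is skipped with a warning; zero-variance sets
#' flag nothing.
#'
#' @param values Numeric CT values.
#' @param alpha Significance level of the two-sided test.
#' @return Integer index of the flagged value, or `NA_integer_` if none.
#' @export
#' @examples
#' grubbs_outlier(c(20.0, 20.0, 30.0))  # 3
#' grubbs_outlier(c(20.0, 20.1, 20.2))  # NA
grubbs_outlier <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numbers.",
          class = "qpcrflux_parameter_error")
  }
  n <- length(values)
  if (n < 3) {
    warn("Grubbs test skipped: fewer than 3 values.")
    return(NA_integer_)
  }
  s <- sd(values)
  if (s == 0) return(NA_integer_)
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  if (g > grubbs_critical(n, alpha)) which.max(dev) else NA_integer_
}

#' Screen and aggregate technical triplicates
#'
#' Applies the Grubbs test within each (gene, tissue, biological-replicate)
#' triplet of detected CT values, drops at most one flagged outlier, and
#' averages the remaining values. Triplets with fewer than two detected
#' values after screening are reported not-detected.
#'
#' @param ct Well-level CT tibble with columns `gene`, `tissue`, `bio_rep`,
#'   `tech_rep`, `ct`, `detected` (as produced by [simulate_ct_table()] or
#'   [read_ct_csv()]).
#' @param alpha Significance level of the Grubbs test.
#' @param digits Rounding of the reported mean CT (one decimal by the usual
#'   reporting convention); `NULL` keeps full precision.
#'
#' @return A tibble with one row per triplet: `gene`, `tissue`, `bio_rep`,
#'   `ct_mean`, `n_used`, `outlier_removed`, `detected`.
#' @export
qc_triplets <- function(ct, alpha = 0.05, digits = 1) {
  assert_columns(ct, c("gene", "tissue", "bio_rep", "ct", "detected"), "`ct`")
  out <- ct %>%
    dplyr::group_by(.data$gene, .data$tissue, .data$bio_rep) %>%
    dplyr::summarise(
      res = list({
        vals <- .data$ct[.data$detected & !is.na(.data$ct)]
        removed <- FALSE
        if (length(vals) >= 3) {
          idx <- grubbs_outlier(vals, alpha)
          if (!is.na(idx)) {
            vals <- vals[-idx]
            removed <- TRUE
          }
        }
        if (length(vals) >= 2) {
          tibble::tibble(ct_mean = mean(vals), n_used = length(vals),
                         outlier_removed = removed, detected = TRUE)
        } else {
          tibble::tibble(ct_mean = NA_real_, n_used = length(vals),
                         outlier_removed = removed, detected = FALSE)
        }
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res")
  if (!is.null(digits)) out$ct_mean <- round(out$ct_mean, digits)
  out
}
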