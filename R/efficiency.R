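#' Baseline-correct amplification curves
#'
#' Subtracts, per well, the mean fluorescence of the pre-amplification
#' cycles inside the import window (cycles 3–15 by default). Pre-amplification
#' cycles are those whose fluorescence lies within `signal_frac` of the trace
#' range above its minimum, so that a reaction amplifying early does not
#' contaminate its own baseline. The spread of the baseline region is kept in
#' a `baseline_sd` column; [window_of_linearity()] uses it as a noise floor.
#'
#' @param curves Tibble with columns `well`, `cycle`, `fluorescence`
#'   (additional columns such as `gene`, `tissue` are carried through).
#' @param baseline_cycles Two-cycle window `(lo, hi)` searched for baseline
#'   points.
#' @param signal_frac Fraction of the fluorescence range above the trace
#'   minimum below which a cycle counts as pre-amplification.
#'
#' @return The input tibble with corrected `fluorescence` (may contain
#'   non-positive values, which log fits exclude) plus columns `baseline`
#'   and `baseline_sd`.
#' @export
baseline_correct <- function(curves, baseline_cycles = c(3, 15),
                             signal_frac = 0.05) {
  assert_columns(curves, c("well", "cycle", "fluorescence"), "`curves`")
  lo <- baseline_cycles[[1]]; hi <- baseline_cycles[[2]]
  if (lo >= hi) {
    abort("`baseline_cycles` must be an increasing pair.",
          class = "qpcrflux_range_error")
  }
  curves %>%
    dplyr::group_by(.data$well) %>%
    dplyr::group_modify(function(df, key) {
      if (lo < min(df$cycle) || hi > max(df$cycle)) {
        abort(sprintf("Baseline window [%g, %g] lies outside the measured cycles of well %s.",
                      lo, hi, key$well),
              class = "qpcrflux_range_error")
      }
      f <- df$fluorescence
      idx <- which(df$cycle >= lo & df$cycle <= hi)
      rng <- range(f)
      keep <- idx[f[idx] <= rng[1] + signal_frac * diff(rng)]
      if (!length(keep)) keep <- idx
      base <- mean(f[keep])
      df$fluorescence <- f - base
      df$baseline <- base
      df$baseline_sd <- if (length(keep) > 1) sd(f[keep]) else 0
      df
    }) %>%
    dplyr::ungroup()
}

## plateau level if the trace tail is flat, else NA
detect_plateau <- function(fluorescence, k = 4, tol = 0.05) {
  n <- length(fluorescence)
  if (n < k + 1) return(NA_real_)
  tail_f <- fluorescence[(n - k + 1):n]
  if (any(tail_f <= 0)) return(NA_real_)
  if (all(abs(diff(tail_f) / tail_f[-k]) < tol)) mean(tail_f) else NA_real_
}

#' Find the window of linearity of one baseline-corrected trace
#'
#' Scans contiguous windows of `max_points` down to `min_points` cycles over
#' the usable part of the trace and fits a straight line to
#' log10(fluorescence) versus cycle in each. The longest window length with
#' at least one eligible window wins; among windows of that length the one
#' with the highest Pearson correlation is returned (ties resolved to the
#' earlier start). Usable points must be positive, exceed a noise floor of
#' `noise_mult * baseline_sd`, and lie below `upper_frac` of the detected
#' plateau. When the trace visibly saturates (its last cycles are flat), the
#' logistic clamp towards the plateau \eqn{P} is inverted first,
#' \eqn{y = \log_{10} f - \log_{10}(1 - f/P)}, so that the fitted slope
#' reflects the underlying exponential phase rather than the onset of
#' saturation; for non-saturating traces \eqn{y = \log_{10} f} unchanged.
#'
#' @param cycle Integer cycle numbers (strictly increasing).
#' @param fluorescence Baseline-corrected fluorescence values.
#' @param baseline_sd Spread of the baseline region (from
#'   [baseline_correct()]); 0 disables the noise floor.
#' @param min_points,max_points Window lengths scanned (4–6, after the usual
#'   practice of fitting 4–6 points in the log-linear phase).
#' @param noise_mult Noise-floor multiplier.
#' @param upper_frac Points above this fraction of the detected plateau are
#'   excluded from fits.
#'
#' @return A list with elements `window` (first and last cycle), `slope`
#'   (log10 fluorescence per cycle), `correlation`, and `n_points`.
#' @export
window_of_linearity <- function(cycle, fluorescence, baseline_sd = 0,
                                min_points = 4, max_points = 6,
                                noise_mult = 5, upper_frac = 0.9) {
  if (length(cycle) != length(fluorescence)) {
    abort("`cycle` and `fluorescence` must have equal length.",
          class = "qpcrflux_parameter_error")
  }
  if (is.unsorted(cycle, strictly = TRUE)) {
    abort("`cycle` must be strictly increasing.",
          class = "qpcrflux_parameter_error")
  }
  plateau <- detect_plateau(fluorescence)
  floor_ <- if (is.finite(baseline_sd) && baseline_sd > 0) {
    noise_mult * baseline_sd
  } else 0
  ok <- fluorescence > pmax(floor_, 0)
  y <- rep(NA_real_, length(fluorescence))
  if (!is.na(plateau)) {
    ok <- ok & fluorescence < upper_frac * plateau
    y[ok] <- log10(fluorescence[ok]) -
      log10(pmax(1 - fluorescence[ok] / plateau, .Machine$double.xmin))
  } else {
    y[ok] <- log10(fluorescence[ok])
  }
  if (sum(ok) < min_points) {
    abort(sprintf("Fewer than %d usable points for the log-linear fit.",
                  min_points),
          class = "qpcrflux_insufficient_data")
  }
  best <- NULL
  for (np in seq(max_points, min_points)) {
    n_start <- length(cycle) - np + 1
    if (n_start < 1) next
    for (st in seq_len(n_start)) {
      ii <- st:(st + np - 1)
      if (!all(ok[ii])) next
      x <- cycle[ii]; yy <- y[ii]
      r <- suppressWarnings(cor(x, yy))
      if (!is.finite(r)) next
      if (is.null(best) || r > best$correlation + 1e-15) {
        best <- list(window = range(x),
                     slope = cov(x, yy) / var(x),
                     correlation = r,
                     n_points = np)
      }
    }
    if (!is.null(best)) break  # prefer longer windows; fall back only if none fit
  }
  if (is.null(best)) {
    abort("No contiguous window of usable points found.",
          class = "qpcrflux_insufficient_data")
  }
  best
}

#' Convert a log10-slope to an amplification efficiency
#'
#' @param slope Fitted slope of log10(fluorescence) per cycle.
#' @return The per-cycle efficiency `E = 10^slope` (2 = perfect doubling,
#'   1 = no amplification).
#' @export
#' @examples
#' efficiency_from_slope(log10(2))  # 2
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope))) {
    abort("`slope` must be finite.", class = "qpcrflux_parameter_error")
  }
  10^slope
}

#' Estimate per-reaction amplification efficiencies
#'
#' Baseline-corrects each well (unless `baseline_corrected = TRUE`), locates
#' its window of linearity and converts the fitted log10-slope to an
#' efficiency. Wells whose trace yields no usable window are returned with
#' `NA` efficiency and the failure reason.
#'
#' @inheritParams baseline_correct
#' @param baseline_corrected Set to `TRUE` when `curves` have already been
#'   baseline-corrected (a `baseline_sd` column is then used if present).
#' @param ... Passed on to [window_of_linearity()].
#'
#' @return A tibble of class `efficiency_fit` with one row per well:
#'   `well`, `gene`, `tissue`, `window_start`, `window_end`, `n_points`,
#'   `slope`, `correlation`, `efficiency`, `note`.
#' @export
estimate_efficiency <- function(curves, baseline_cycles = c(3, 15),
                                signal_frac = 0.05,
                                baseline_corrected = FALSE, ...) {
  assert_columns(curves, c("well", "cycle", "fluorescence"), "`curves`")
  if (!baseline_corrected) {
    curves <- baseline_correct(curves, baseline_cycles, signal_frac)
  }
  if (!"baseline_sd" %in% names(curves)) curves$baseline_sd <- 0
  if (!"gene" %in% names(curves)) curves$gene <- NA_character_
  if (!"tissue" %in% names(curves)) curves$tissue <- NA_character_
  out <- curves %>%
    dplyr::group_by(.data$well, .data$gene, .data$tissue) %>%
    dplyr::group_modify(function(df, key) {
      fit <- tryCatch(
        window_of_linearity(df$cycle, df$fluorescence,
                            baseline_sd = df$baseline_sd[[1]], ...),
        qpcrflux_insufficient_data = function(e) e
      )
      if (inherits(fit, "condition")) {
        return(tibble::tibble(window_start = NA_integer_,
                              window_end = NA_integer_,
                              n_points = NA_integer_, slope = NA_real_,
                              correlation = NA_real_, efficiency = NA_real_,
                              note = conditionMessage(fit)))
      }
      tibble::tibble(window_start = fit$window[1], window_end = fit$window[2],
                     n_points = fit$n_points, slope = fit$slope,
                     correlation = fit$correlation,
                     efficiency = efficiency_from_slope(fit$slope),
                     note = NA_character_)
    }) %>%
    dplyr::ungroup()
  class(out) <- c("efficiency_fit", class(out))
  out
}

#' Mean amplification efficiency per amplicon
#'
#' Averages per-reaction efficiencies that pass the correlation filter
#' (`r >= min_r`, 0.998 by default) for each gene, reporting how many
#' reactions were excluded. Estimates outside (1, 2] are also excluded as
#' unphysical.
#'
#' @param fits An `efficiency_fit` tibble from [estimate_efficiency()].
#' @param min_r Minimum correlation for a reaction to be accepted.
#' @param digits Rounding applied to the reported mean efficiency (two
#'   decimals by convention); use `NULL` for full precision.
#'
#' @return A tibble with columns `gene`, `mean_efficiency`, `n_reactions`,
#'   `n_excluded`, `mean_r`.
#' @export
mean_amplicon_efficiency <- function(fits, min_r = 0.998, digits = 2) {
  assert_columns(fits, c("gene", "efficiency", "correlation"), "`fits`")
  out <- fits %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_total = dplyr::n(),
      n_reactions = sum(!is.na(.data$efficiency) &
                          .data$correlation >= min_r &
                          .data$efficiency > 1 & .data$efficiency <= 2),
      mean_efficiency = mean(.data$efficiency[!is.na(.data$efficiency) &
                                                .data$correlation >= min_r &
                                                .data$efficiency > 1 &
                                                .data$efficiency <= 2]),
      mean_r = mean(.data$correlation[!is.na(.data$efficiency) &
                                        .data$correlation >= min_r &
                                        .data$efficiency > 1 &
                                        .data$efficiency <= 2]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_excluded = .data$n_total - .data$n_reactions) %>%
    dplyr::select("gene", "mean_efficiency", "n_reactions", "n_excluded",
                  "mean_r")
  rejected <- out$gene[out$n_reactions == 0]
  if (length(rejected)) {
    abort(sprintf("All reactions rejected by the quality filter for gene(s): %s.",
                  paste(rejected, collapse = ", ")),
          class = "qpcrflux_quality_error")
  }
  if (!is.null(digits)) {
    out$mean_efficiency <- round(out$mean_efficiency, digits)
  }
  out
}

#' @export
glance.efficiency_fit <- function(x, ...) {
  tibble::tibble(
    n_wells = nrow(x),
    n_fitted = sum(!is.na(x$efficiency)),
    mean_efficiency = mean(x$efficiency, na.rm = TRUE),
    sd_efficiency = sd(x$efficiency, na.rm = TRUE),
    mean_r = mean(x$correlation, na.rm = TRUE)
  )
}

#' @export
tidy.efficiency_fit <- function(x, ...) {
  tibble::as_tibble(x)
}
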