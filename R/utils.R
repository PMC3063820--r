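## internal helpers

geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  exp(mean(log(x)))
}

## labels are matched case-insensitively with spaces/hyphens collapsed to "_"
normalize_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "qpcrflux_parameter_error")
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s.",
                  name, x, if (closed_lower) "[" else "(", lower, upper,
                  if (closed_upper) "]" else ")"),
          class = "qpcrflux_parameter_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "qpcrflux_format_error")
  }
  invisible(df)
}

## accept either a named numeric vector or a tibble with gene/efficiency cols
as_efficiency_vector <- function(efficiencies) {
  if (is.data.frame(efficiencies)) {
    assert_columns(efficiencies, c("gene", "efficiency"), "efficiency table")
    eff <- setNames(efficiencies$efficiency, efficiencies$gene)
  } else if (is.numeric(efficiencies) && !is.null(names(efficiencies))) {
    eff <- efficiencies
  } else {
    abort("`efficiencies` must be a named numeric vector or a data frame with columns gene, efficiency.",
          class = "qpcrflux_parameter_error")
  }
  bad <- eff[!is.na(eff) & (eff <= 1 | eff > 2)]
  if (length(bad)) {
    abort(sprintf("Amplification efficiencies must lie in (1, 2]; offending gene(s): %s.",
                  paste(names(bad), collapse = ", ")),
          class = "qpcrflux_parameter_error")
  }
  eff
}

lookup_efficiency <- function(eff, genes) {
  missing <- setdiff(genes, names(eff))
  if (length(missing)) {
    abort(sprintf("No efficiency supplied for gene(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "qpcrflux_configuration_error")
  }
  unname(eff[genes])
}
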