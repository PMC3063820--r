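#' Read a well-level CT table from CSV
#'
#' The dialect is a plain CSV with header
#' `gene,tissue,bio_rep,tech_rep,ct,detected`; `ct` entries `"n.d."` or
#' empty are mapped to not-detected (the `detected` column, when present,
#' must agree). Malformed rows and duplicate
#' (gene, tissue, bio_rep, tech_rep) combinations are rejected with the
#' offending line numbers.
#'
#' @param path CSV file path.
#' @return A well-level CT tibble (`gene`, `tissue`, `bio_rep`, `tech_rep`,
#'   `ct`, `detected`).
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("CT file not found: %s.", path),
          class = "qpcrflux_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    abort(sprintf("CT file %s contains no data rows.", path),
          class = "qpcrflux_io_error")
  }
  required <- c("gene", "tissue", "bio_rep", "tech_rep", "ct")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("CT file %s is missing column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "qpcrflux_io_error")
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  nd <- is.na(raw$ct) | raw$ct %in% c("", "n.d.", "nd", "NA")
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(!nd & is.na(ct))
  if (length(bad)) {
    abort(sprintf("Malformed CT value(s) in %s at line(s): %s.", path,
                  paste(line_no[head(bad, 5)], collapse = ", ")),
          class = "qpcrflux_io_error")
  }
  bio <- suppressWarnings(as.integer(raw$bio_rep))
  tech <- suppressWarnings(as.integer(raw$tech_rep))
  bad_rep <- which(is.na(bio) | is.na(tech))
  if (length(bad_rep)) {
    abort(sprintf("Malformed replicate index in %s at line(s): %s.", path,
                  paste(line_no[head(bad_rep, 5)], collapse = ", ")),
          class = "qpcrflux_io_error")
  }
  detected <- if ("detected" %in% names(raw)) {
    as.logical(raw$detected) & !nd
  } else {
    !nd
  }
  dup <- duplicated(raw[, c("gene", "tissue", "bio_rep", "tech_rep")])
  if (any(dup)) {
    abort(sprintf("Duplicate (gene, tissue, bio_rep, tech_rep) row(s) in %s at line(s): %s.",
                  path, paste(line_no[head(which(dup), 5)], collapse = ", ")),
          class = "qpcrflux_io_error")
  }
  tibble::tibble(gene = raw$gene, tissue = raw$tissue, bio_rep = bio,
                 tech_rep = tech,
                 ct = dplyr::if_else(detected, ct, NA_real_),
                 detected = detected)
}

#' Write a well-level CT table to CSV
#'
#' Inverse of [read_ct_csv()]: not-detected reactions are written as
#' `"n.d."` so that `read_ct_csv(write_ct_csv(x))` round-trips.
#'
#' @param ct Well-level CT tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path) {
  assert_columns(ct, c("gene", "tissue", "bio_rep", "tech_rep", "ct",
                       "detected"), "`ct`")
  out <- ct %>%
    dplyr::mutate(ct = dplyr::if_else(.data$detected,
                                      sprintf("%.17g", .data$ct), "n.d."))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write amplification curves
#'
#' CSV dialect with header `well,gene,tissue,cycle,fluorescence`
#' (1-based integer cycles), emulating a thermocycler export.
#'
#' @param path CSV file path.
#' @return `read_curves_csv()`: a curves tibble; `write_curves_csv()`:
#'   `path`, invisibly.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Curves file not found: %s.", path),
          class = "qpcrflux_io_error")
  }
  out <- readr::read_csv(path, col_types = "cccid", progress = FALSE)
  assert_columns(out, c("well", "gene", "tissue", "cycle", "fluorescence"),
                 sprintf("Curves file %s", path))
  if (any(!is.finite(out$fluorescence))) {
    abort(sprintf("Non-finite fluorescence values in %s.", path),
          class = "qpcrflux_io_error")
  }
  out
}

#' @param curves Curves tibble (`well`, `gene`, `tissue`, `cycle`,
#'   `fluorescence`).
#' @rdname read_curves_csv
#' @export
write_curves_csv <- function(curves, path) {
  assert_columns(curves, c("well", "gene", "tissue", "cycle",
                           "fluorescence"), "`curves`")
  readr::write_csv(
    dplyr::select(curves, "well", "gene", "tissue", "cycle", "fluorescence"),
    path, progress = FALSE)
  invisible(path)
}
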