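#' Parameters for a simulated amplification curve
#'
#' Bundles the ground-truth parameters of a single qPCR amplification curve.
#' The fluorescence model is an exponentially growing signal with a logistic
#' clamp towards the plateau:
#' \deqn{F(c) = baseline + \frac{A\,E^c}{1 + A\,E^c/(plateau - baseline)} + \epsilon_c,}
#' where \eqn{E} is the per-cycle amplification efficiency (2 = perfect
#' doubling), \eqn{A} the initial signal in fluorescence units and
#' \eqn{\epsilon_c} additive Gaussian noise. While \eqn{A E^c} is small
#' relative to the plateau span the trace is log-linear with slope
#' \eqn{\log_{10} E} per cycle.
#'
#' @param true_efficiency Fold-increase of product per cycle, in (1, 2].
#' @param initial_amount Starting signal in arbitrary fluorescence units (> 0).
#'   The default places the half-rise of the curve near cycle 28 for
#'   typical efficiencies.
#' @param baseline Constant fluorescence offset of the instrument.
#' @param plateau Saturating fluorescence; must exceed `baseline`. Set it far
#'   above `baseline + initial_amount * true_efficiency^n_cycles` to obtain a
#'   curve that stays exponential over the whole run.
#' @param noise_sd Standard deviation of additive Gaussian noise, in the same
#'   units as `plateau`.
#' @param n_cycles Number of PCR cycles measured (>= 10; 40 is the usual
#'   two-step protocol length).
#' @param seed Optional integer seed giving bit-identical traces.
#'
#' @return An object of class `curve_params` (a named list).
#' @seealso [simulate_curves()]
#' @export
#' @examples
#' p <- curve_params(true_efficiency = 1.88, noise_sd = 0)
#' curves <- simulate_curves(p)
curve_params <- function(true_efficiency = 1.9,
                         initial_amount = 1e-4,
                         baseline = 50,
                         plateau = 5050,
                         noise_sd = 0,
                         n_cycles = 40,
                         seed = NULL) {
  assert_number(true_efficiency, "true_efficiency", 1, 2, closed_lower = FALSE)
  assert_number(initial_amount, "initial_amount", 0, closed_lower = FALSE)
  assert_number(baseline, "baseline")
  assert_number(plateau, "plateau")
  if (plateau <= baseline) {
    abort("`plateau` must exceed `baseline`.", class = "qpcrflux_parameter_error")
  }
  assert_number(noise_sd, "noise_sd", 0)
  assert_number(n_cycles, "n_cycles", 10)
  if (n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be an integer.", class = "qpcrflux_parameter_error")
  }
  structure(
    list(true_efficiency = true_efficiency, initial_amount = initial_amount,
         baseline = baseline, plateau = plateau, noise_sd = noise_sd,
         n_cycles = as.integer(n_cycles), seed = seed),
    class = "curve_params"
  )
}

#' Simulate amplification curves
#'
#' Generates one or more fluorescence traces from a common set of
#' ground-truth parameters (see [curve_params()] for the curve model).
#'
#' @param params A [curve_params()] object.
#' @param n_curves Number of independent wells to simulate.
#' @param gene,tissue Labels attached to the simulated wells.
#' @param seed Integer seed; overrides `params$seed` when given.
#' @param well_prefix Prefix for generated well ids.
#'
#' @return A tibble with columns `well`, `gene`, `tissue`, `cycle`,
#'   `fluorescence` (one row per well and cycle), carrying `params` in the
#'   `"curve_params"` attribute as ground truth.
#' @export
simulate_curves <- function(params, n_curves = 1, gene = "target",
                            tissue = "sample", seed = NULL,
                            well_prefix = "W") {
  if (!inherits(params, "curve_params")) {
    abort("`params` must be created by curve_params().",
          class = "qpcrflux_parameter_error")
  }
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  cyc <- seq_len(params$n_cycles)
  span <- params$plateau - params$baseline
  signal <- params$initial_amount * params$true_efficiency^cyc
  mean_f <- params$baseline + signal / (1 + signal / span)
  out <- purrr::map_dfr(seq_len(n_curves), function(i) {
    tibble::tibble(
      well = sprintf("%s%02d", well_prefix, i),
      gene = gene,
      tissue = tissue,
      cycle = as.integer(cyc),
      fluorescence = mean_f + rnorm(length(cyc), 0, params$noise_sd)
    )
  })
  attr(out, "curve_params") <- params
  out
}

#' Design of a simulated CT experiment
#'
#' Describes a gene-by-tissue qPCR experiment with known ground truth:
#' per-gene fold changes relative to a control tissue, designated reference
#' genes (fold change fixed at 1 everywhere), replicate structure, outlier
#' contamination and a non-detect threshold.
#'
#' @param genes Character vector of amplicon labels.
#' @param tissues Character vector of sample labels; the first is taken as
#'   control unless `control_tissue` says otherwise.
#' @param control_tissue Label of the calibrator tissue.
#' @param fold_changes Either `NULL` (all genes unchanged) or a tibble with
#'   columns `gene`, `tissue`, `fold_change` giving expression relative to
#'   the control tissue. Unlisted combinations default to 1.
#' @param reference_genes Genes whose fold change must be (and is checked to
#'   be) 1 in every tissue.
#' @param n_technical Technical replicates per reaction (>= 2; triplicates by
#'   default, matching routine practice).
#' @param n_biological Independent runs from different plants (default 2).
#' @param base_ct Named numeric vector of control-tissue CT values per gene;
#'   defaults to 25 cycles for every gene.
#' @param tech_sd Gaussian SD of technical replicate noise, in cycles.
#' @param bio_sd Gaussian SD of the per-run shift shared by all technical
#'   replicates of a biological run, in cycles.
#' @param outlier_rate Probability that a triplet contains one displaced CT.
#' @param outlier_shift Range (cycles) of the displacement added to the
#'   outlying replicate.
#' @param nondetect_ct CT threshold above which a reaction is flagged
#'   not-detected (recorded as missing, never as the threshold value).
#'
#' @return An object of class `ct_design`.
#' @seealso [simulate_ct_table()]
#' @export
ct_design <- function(genes, tissues, control_tissue = tissues[[1]],
                      fold_changes = NULL, reference_genes = character(),
                      n_technical = 3, n_biological = 2,
                      base_ct = NULL, tech_sd = 0.15, bio_sd = 0.2,
                      outlier_rate = 0, outlier_shift = c(5, 10),
                      nondetect_ct = 40) {
  genes <- as.character(genes)
  tissues <- as.character(tissues)
  if (!control_tissue %in% tissues) {
    abort("`control_tissue` must be one of `tissues`.",
          class = "qpcrflux_parameter_error")
  }
  if (anyDuplicated(genes) || anyDuplicated(tissues)) {
    abort("`genes` and `tissues` must not contain duplicates.",
          class = "qpcrflux_parameter_error")
  }
  assert_number(n_technical, "n_technical", 2)
  assert_number(n_biological, "n_biological", 1)
  assert_number(tech_sd, "tech_sd", 0)
  assert_number(bio_sd, "bio_sd", 0)
  assert_number(outlier_rate, "outlier_rate", 0, 1)
  assert_number(nondetect_ct, "nondetect_ct", 0)
  if (length(outlier_shift) != 2L || outlier_shift[1] > outlier_shift[2]) {
    abort("`outlier_shift` must be an increasing pair of cycle shifts.",
          class = "qpcrflux_parameter_error")
  }
  fc <- tidyr::expand_grid(gene = genes, tissue = tissues) %>%
    dplyr::mutate(fold_change = 1)
  if (!is.null(fold_changes)) {
    assert_columns(fold_changes, c("gene", "tissue", "fold_change"),
                   "`fold_changes`")
    bad <- setdiff(fold_changes$gene, genes)
    if (length(bad)) {
      abort(sprintf("`fold_changes` names unknown gene(s): %s.",
                    paste(bad, collapse = ", ")),
            class = "qpcrflux_parameter_error")
    }
    fc <- fc %>%
      dplyr::left_join(fold_changes, by = c("gene", "tissue"),
                       suffix = c("", ".new")) %>%
      dplyr::mutate(fold_change = dplyr::coalesce(.data$fold_change.new,
                                                  .data$fold_change)) %>%
      dplyr::select(-"fold_change.new")
  }
  ref_bad <- fc %>%
    dplyr::filter(.data$gene %in% reference_genes, .data$fold_change != 1)
  if (nrow(ref_bad)) {
    abort(sprintf("Reference gene(s) must have fold change 1 everywhere: %s.",
                  paste(unique(ref_bad$gene), collapse = ", ")),
          class = "qpcrflux_parameter_error")
  }
  if (is.null(base_ct)) {
    base_ct <- setNames(rep(25, length(genes)), genes)
  }
  missing_base <- setdiff(genes, names(base_ct))
  if (length(missing_base)) {
    abort(sprintf("`base_ct` is missing gene(s): %s.",
                  paste(missing_base, collapse = ", ")),
          class = "qpcrflux_parameter_error")
  }
  structure(
    list(genes = genes, tissues = tissues, control_tissue = control_tissue,
         fold_changes = fc, reference_genes = reference_genes,
         n_technical = as.integer(n_technical),
         n_biological = as.integer(n_biological),
         base_ct = base_ct, tech_sd = tech_sd, bio_sd = bio_sd,
         outlier_rate = outlier_rate, outlier_shift = outlier_shift,
         nondetect_ct = nondetect_ct),
    class = "ct_design"
  )
}

#' Simulate a CT table with known ground truth
#'
#' Draws well-level CT values under a [ct_design()]. The expected CT obeys
#' \deqn{C_T(g, t) = C_T(g, control) - \log_{E_g}(\mathrm{fold\ change}_{g,t}),}
#' so a doubling of expression under perfect doubling efficiency lowers CT by
#' exactly one cycle. Biological runs share a per-run Gaussian shift
#' (`bio_sd`), wells add technical noise (`tech_sd`), contaminated triplets
#' contain exactly one replicate displaced upwards, and CT values beyond the
#' non-detect threshold are recorded as missing with `detected = FALSE`.
#'
#' @param design A [ct_design()].
#' @param efficiencies Named numeric vector, or tibble with columns `gene`
#'   and `efficiency`, covering every gene in the design.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `gene`, `tissue`, `bio_rep`, `tech_rep`,
#'   `ct`, `detected`, carrying the design in the `"ct_design"` attribute.
#' @export
simulate_ct_table <- function(design, efficiencies, seed = NULL) {
  if (!inherits(design, "ct_design")) {
    abort("`design` must be created by ct_design().",
          class = "qpcrflux_parameter_error")
  }
  eff <- as_efficiency_vector(efficiencies)
  lookup_efficiency(eff, design$genes)  # errors on missing genes
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(
    gene = design$genes, tissue = design$tissues,
    bio_rep = seq_len(design$n_biological)
  ) %>%
    dplyr::left_join(design$fold_changes, by = c("gene", "tissue")) %>%
    dplyr::mutate(
      expected_ct = design$base_ct[.data$gene] -
        log(.data$fold_change) / log(unname(eff[.data$gene]))
    )

  ## one shared shift per (tissue, bio_rep): biological runs are independent
  run_shift <- grid %>%
    dplyr::distinct(.data$tissue, .data$bio_rep) %>%
    dplyr::mutate(run_shift = rnorm(dplyr::n(), 0, design$bio_sd))

  out <- grid %>%
    dplyr::left_join(run_shift, by = c("tissue", "bio_rep")) %>%
    dplyr::mutate(row_id = dplyr::row_number()) %>%
    dplyr::group_by(.data$row_id) %>%
    dplyr::reframe(
      gene = .data$gene, tissue = .data$tissue, bio_rep = .data$bio_rep,
      tech_rep = seq_len(design$n_technical),
      ct = .data$expected_ct + .data$run_shift +
        rnorm(design$n_technical, 0, design$tech_sd)
    ) %>%
    dplyr::select(-"row_id")

  if (design$outlier_rate > 0) {
    n_trip <- nrow(out) / design$n_technical
    hit <- runif(n_trip) < design$outlier_rate
    pos <- sample.int(design$n_technical, n_trip, replace = TRUE)
    shift <- runif(n_trip, design$outlier_shift[1], design$outlier_shift[2])
    idx <- (which(hit) - 1L) * design$n_technical + pos[hit]
    out$ct[idx] <- out$ct[idx] + shift[hit]
  }

  out <- out %>%
    dplyr::mutate(
      detected = .data$ct <= design$nondetect_ct,
      ct = dplyr::if_else(.data$detected, .data$ct, NA_real_)
    )
  attr(out, "ct_design") <- design
  out
}
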