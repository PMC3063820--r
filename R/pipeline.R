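#' Configuration of the end-to-end quantification pipeline
#'
#' Collects the inputs and parameters of a full run:
#' triplicate QC ([qc_triplets()]) then reference-gene screening
#' ([rank_references()]), expression ratios ([relative_expression()]) and,
#' when a calibrator and kinetics table are given, 2^-ddCt amounts and
#' turnover scores ([amount_matrix()], [turnover_potential()]).
#'
#' @param ct Well-level CT table: a tibble or a CSV path
#'   ([read_ct_csv()] dialect).
#' @param efficiencies Per-gene amplification efficiencies: named vector,
#'   `gene`/`efficiency` tibble, or CSV path.
#' @param reference_genes Reference genes used for ratio normalization; when
#'   `NULL` the top-ranked genes from the stability report are used.
#' @param control_tissue Control tissue for expression ratios.
#' @param ddct_reference Reference gene of the 2^-ddCt analysis (defaults to
#'   the first reference gene).
#' @param calibrator Optional `c(gene, tissue)` pair defining amount 1.
#' @param kinetics Optional kinetics tibble or CSV path (see
#'   [turnover_potential()]).
#' @param grubbs_alpha Grubbs test level of the triplicate QC.
#' @param n_iter,n_boot Randomization iterations and bootstrap resamples.
#' @param rounding Rounding mode of the amount/turnover tables.
#' @param seed Integer seed controlling all randomized stages.
#' @param out_dir Output directory for CSVs, the figure and the manifest;
#'   `NULL` disables writing.
#' @param write_figure Whether to render the log-scale ratio figure.
#'
#' @return An object of class `qpcr_config`.
#' @export
qpcr_config <- function(ct, efficiencies, reference_genes = NULL,
                        control_tissue, ddct_reference = NULL,
                        calibrator = NULL, kinetics = NULL,
                        grubbs_alpha = 0.05, n_iter = 2000, n_boot = 2000,
                        rounding = c("exact", "report"), seed = 1,
                        out_dir = NULL, write_figure = TRUE) {
  rounding <- match.arg(rounding)
  if (is.character(ct) && length(ct) == 1) ct <- read_ct_csv(ct)
  assert_columns(ct, c("gene", "tissue", "bio_rep", "tech_rep", "ct",
                       "detected"), "`ct`")
  if (is.character(efficiencies) && length(efficiencies) == 1) {
    efficiencies <- readr::read_csv(efficiencies, col_types = "cd",
                                    progress = FALSE)
  }
  eff <- as_efficiency_vector(efficiencies)
  if (is.character(kinetics) && length(kinetics) == 1) {
    kinetics <- readr::read_csv(kinetics, show_col_types = FALSE,
                                progress = FALSE)
  }
  if (!is.null(calibrator) && length(calibrator) != 2) {
    abort("`calibrator` must be a (gene, tissue) pair.",
          class = "qpcrflux_parameter_error")
  }
  structure(
    list(ct = ct, efficiencies = eff, reference_genes = reference_genes,
         control_tissue = control_tissue, ddct_reference = ddct_reference,
         calibrator = calibrator, kinetics = kinetics,
         grubbs_alpha = grubbs_alpha, n_iter = n_iter, n_boot = n_boot,
         rounding = rounding, seed = as.integer(seed), out_dir = out_dir,
         write_figure = write_figure),
    class = "qpcr_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "qpcrflux_stage_error", parent = e)
  })
}

#' Run the full quantification pipeline
#'
#' Executes triplicate QC, reference-gene stability ranking, expression
#' ratios with randomization p-values and bootstrap intervals, and (when
#' configured) 2^-ddCt amounts plus turnover-potential scores; optionally
#' writes every stage's table as CSV, a log-scale ratio figure, and a JSON
#' manifest recording parameters and seed so any stage can be re-run in
#' isolation.
#'
#' @param config A [qpcr_config()].
#' @return A list (invisibly when writing to disk) with elements
#'   `ct_clean`, `stability`, `ratios`, and when configured `amounts` and
#'   `turnover`, plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "qpcr_config")) {
    abort("`config` must be created by qpcr_config().",
          class = "qpcrflux_parameter_error")
  }
  set.seed(config$seed)

  ct_clean <- run_stage("qc", qc_triplets(config$ct, config$grubbs_alpha))

  ## gene x tissue means across biological runs feed the stability ranking
  ct_means <- ct_clean %>%
    dplyr::group_by(.data$gene, .data$tissue) %>%
    dplyr::summarise(
      ct = if (any(.data$detected)) mean(.data$ct_mean[.data$detected])
           else NA_real_,
      .groups = "drop"
    )
  ## the stability ranking needs >= 3 samples; with fewer it is skipped,
  ## which is only acceptable when reference genes are configured
  stability <- NULL
  if (length(unique(ct_means$tissue)) >= 3) {
    stability <- run_stage("stability", rank_references(ct_means))
  } else if (is.null(config$reference_genes)) {
    abort("Pipeline stage 'stability' needs at least 3 samples; configure `reference_genes` explicitly for smaller designs.",
          class = "qpcrflux_stage_error")
  }

  reference_genes <- config$reference_genes %||%
    stability$gene[stability$selected]
  if (length(reference_genes) == 0) {
    abort("Pipeline stage 'stability' selected no reference genes and none were configured.",
          class = "qpcrflux_stage_error")
  }

  ratios <- run_stage("express", relative_expression(
    config$ct, config$efficiencies, reference_genes,
    config$control_tissue, n_iter = config$n_iter, n_boot = config$n_boot,
    seed = config$seed
  ))

  amounts <- NULL
  turnover <- NULL
  if (!is.null(config$calibrator)) {
    ddct_ref <- config$ddct_reference %||% reference_genes[[1]]
    amounts <- run_stage("ddct", amount_matrix(
      ct_means, reference_gene = ddct_ref,
      calibrator_gene = config$calibrator[[1]],
      calibrator_tissue = config$calibrator[[2]],
      rounding = config$rounding
    ))
    if (!is.null(config$kinetics)) {
      turnover <- run_stage("turnover", turnover_potential(
        amounts, config$kinetics, rounding = config$rounding
      ))
    }
  }

  manifest <- list(
    package = "qpcrflux",
    version = as.character(utils::packageVersion("qpcrflux")),
    seed = config$seed,
    parameters = list(
      grubbs_alpha = config$grubbs_alpha, n_iter = config$n_iter,
      n_boot = config$n_boot, rounding = config$rounding,
      control_tissue = config$control_tissue,
      reference_genes = reference_genes,
      ddct_reference = config$ddct_reference %||% reference_genes[[1]],
      calibrator = config$calibrator
    ),
    n_wells = nrow(config$ct),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  bundle <- list(ct_clean = ct_clean, ct_means = ct_means,
                 stability = stability, ratios = ratios,
                 amounts = amounts, turnover = turnover,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    readr::write_csv(ct_clean, p("ct_clean.csv"), progress = FALSE)
    if (!is.null(stability)) {
      readr::write_csv(stability, p("stability.csv"), progress = FALSE)
    }
    readr::write_csv(ratios, p("ratios.csv"), progress = FALSE)
    if (!is.null(amounts)) {
      readr::write_csv(amounts, p("amounts.csv"), progress = FALSE)
    }
    if (!is.null(turnover)) {
      readr::write_csv(turnover, p("turnover.csv"), progress = FALSE)
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    if (isTRUE(config$write_figure)) {
      ggplot2::ggsave(p("ratios.png"), autoplot(ratios),
                      width = 8, height = 6, dpi = 150)
    }
    return(invisible(bundle))
  }
  bundle
}
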