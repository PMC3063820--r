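## shared builders for synthetic test data

## a curve whose plateau lies far above the measured range: the trace stays
## exponential across all 40 cycles
exponential_params <- function(E, initial_amount = 1e-4, baseline = 50,
                               noise_sd = 0, seed = NULL) {
  span <- initial_amount * E^40 * 1e7   # clamp stays below 1e-7 everywhere
  curve_params(true_efficiency = E, initial_amount = initial_amount,
               baseline = baseline, plateau = baseline + span,
               noise_sd = noise_sd, n_cycles = 40, seed = seed)
}

## a realistically saturating curve: plateau span 5000, half-rise ~cycle 28
saturating_params <- function(E, noise_sd = 0, seed = NULL) {
  curve_params(true_efficiency = E, initial_amount = 5000 * E^-28,
               baseline = 50, plateau = 5050, noise_sd = noise_sd,
               n_cycles = 40, seed = seed)
}

## small two-tissue design with three reference genes
two_tissue_design <- function(targets = "T1", fold_changes = NULL,
                              n_biological = 3, tech_sd = 0.15,
                              bio_sd = 0.2, ...) {
  ct_design(
    genes = c(targets, "R1", "R2", "R3"),
    tissues = c("control", "treated"),
    control_tissue = "control",
    fold_changes = fold_changes,
    reference_genes = c("R1", "R2", "R3"),
    n_biological = n_biological, tech_sd = tech_sd, bio_sd = bio_sd,
    ...
  )
}

uniform_efficiencies <- function(genes, value = 1.9) {
  stats::setNames(rep(value, length(genes)), genes)
}
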