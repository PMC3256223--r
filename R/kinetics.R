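#' Kinetic configuration for Petri-net simulation
#'
#' Bundles the per-reaction-class default kinetic parameters, the
#' multi-timescale decay policy, and engine controls. The class defaults
#' are the published simulation constants: complex formation 0.55,
#' phosphorylation 0.35, dephosphorylation 0.01 (0.15 for the enzyme-driven
#' variant), transcription 0.5, explicit decay reactions 0.02, translocation
#' 0.8 (0.5 for mRNA translocation), inhibitory parameter 1.5, all other
#' classes 0.35. The decay policy applies rate 0.09 every step to proteins
#' and compounds and rate 0.2 every 10 steps to ligand-receptor complexes.
#'
#' @param consume_enzyme If `TRUE` (the worked-example firing convention,
#'   which the printed example tables follow) enzyme arcs move mass on
#'   firing like substrate arcs; the default `FALSE` is conventional
#'   non-consuming catalysis, used for all perturbation studies.
#' @param steps Default simulation step budget.
#' @param tol Quasi-steady-state tolerance on the max absolute marking
#'   change per step.
#' @param activation_epsilon Absolute concentration (nM) above which a
#'   readout counts as activated in threshold scans.
#' @param ... Named overrides for any default field.
#' @return A list of class `mirpetri_config`.
#' @export
kinetic_config <- function(consume_enzyme = FALSE, steps = 500, tol = 1e-9,
                           activation_epsilon = 1e-3, ...) {
  cfg <- list(
    k_default = c(
      transcription        = 0.5,
      miRNA_transcription  = 0.5,
      translation          = 0.35,
      decay                = 0.02,
      complex_formation    = 0.55,
      translocation        = 0.8,
      translocation_mRNA   = 0.5,
      phosphorylation      = 0.35,
      dephosphorylation    = 0.01,
      dephosphorylation_enzyme = 0.15,
      activation           = 0.35,
      miRNA_binding        = 0.55,
      anti_miRNA_binding   = 0.55,
      other                = 0.35),
    inhibitory_parameter = 1.5,
    decay_protein_rate = 0.09,
    decay_protein_period = 1L,
    decay_ligand_receptor_rate = 0.2,
    decay_ligand_receptor_period = 10L,
    consume_enzyme = consume_enzyme,
    steps = as.integer(steps),
    tol = tol,
    activation_epsilon = activation_epsilon)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg$k_default)) cfg$k_default[[nm]] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "mirpetri_config")
}

default_k <- function(rtype, cfg, mRNA_translocation = FALSE) {
  if (rtype == "translocation" && mRNA_translocation)
    return(cfg$k_default[["translocation_mRNA"]])
  cfg$k_default[[rtype]]
}
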