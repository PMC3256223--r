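#' @title Motif-based network construction
#' @name motifs
#' @description
#' Models are assembled from three recurring motifs: the central-dogma chain
#' of a protein-coding gene (nuclear transcription, transcript translocation,
#' cytoplasmic translation, transcript and protein decay), the lumped
#' two-step miRNA biogenesis chain (transcription+cropping, translocation,
#' decay), and the lumped RISC binding of a mature miRNA to a target mRNA
#' that sequesters the transcript into a decaying complex. Anti-miRNA
#' inhibitors are pseudo-objects that titrate the mature miRNA into an inert
#' complex.
#'
#' Id conventions: gene `G` produces transcript `mRNA-G@nuc` (nucleus),
#' `mRNA-G` (cytoplasm) and protein `G-1`; miRNA gene `m` produces mature
#' `m-mat@nuc` and `m-mat`; the inhibitor of `m` is `anti-m`.
NULL

mrna_nuc_id <- function(gene) paste0("mRNA-", gene, "@nuc")
mrna_id     <- function(gene) paste0("mRNA-", gene)
protein_id  <- function(gene) paste0(gene, "-1")
mirna_mat_nuc_id <- function(m) paste0(m, "-mat@nuc")
mirna_mat_id     <- function(m) paste0(m, "-mat")
anti_id          <- function(m) paste0("anti-", m)

#' Add the gene-expression motif for one protein-coding gene
#'
#' Creates the gene place (nucleus), a one-step basal transcription reaction
#' producing the nuclear transcript, its translocation to the cytoplasm,
#' transcript decay, translation into the cytoplasmic protein, and protein
#' decay: 4 entities and 5 reactions.
#'
#' @param model A `mirpetri_model`.
#' @param gene_id Gene symbol; must be unused.
#' @param members Optional member gene ids for a set entity (e.g. a MEK set
#'   standing for MAP2K1/MAP2K2).
#' @return The updated model, with attribute `"created"` listing new ids.
#' @export
add_gene_expression_motif <- function(model, gene_id,
                                      members = character(0)) {
  g <- gene_id
  mn <- mrna_nuc_id(g); mc <- mrna_id(g); pr <- protein_id(g)
  model <- add_entity(model, g, "gene", "nucleus", members = members)
  model <- add_entity(model, mn, "mRNA", "nucleus", members = members)
  model <- add_entity(model, mc, "mRNA", "cytoplasm", members = members)
  model <- add_entity(model, pr, "protein", "cytoplasm", members = members)
  model <- add_reaction(model, paste0("transcription:", g), "transcription",
                        arcs_frame(enzymes = g, products = mn))
  model <- add_reaction(model, paste0("translocation:", mc), "translocation",
                        arcs_frame(substrates = mn, products = mc),
                        kclass = "translocation_mRNA")
  model <- add_reaction(model, paste0("decay:", mc), "decay",
                        arcs_frame(substrates = mc))
  model <- add_reaction(model, paste0("translation:", g), "translation",
                        arcs_frame(substrates = mc, products = pr))
  model <- add_reaction(model, paste0("decay:", pr), "decay",
                        arcs_frame(substrates = pr))
  attr(model, "created") <- c(g, mn, mc, pr,
                              paste0(c("transcription:", "translation:"), g),
                              paste0("translocation:", mc),
                              paste0("decay:", c(mc, pr)))
  model
}

#' Add the lumped miRNA biogenesis motif
#'
#' One reaction lumps miRNA gene transcription with microprocessor
#' (Drosha/DGCR8) cropping; the mature miRNA then translocates to the
#' cytoplasm where it decays: 3 entities and 3 reactions. With `member_ids`
#' the gene place is a set entity standing for a miRNA family with shared
#' targets.
#'
#' @param model A `mirpetri_model`.
#' @param mirna_id miRNA (or miRNA-set) id; must be unused.
#' @param member_ids Optional member miRNA gene ids.
#' @return The updated model, with attribute `"created"` listing new ids.
#' @export
add_mirna_motif <- function(model, mirna_id, member_ids = character(0)) {
  m <- mirna_id
  mn <- mirna_mat_nuc_id(m); mc <- mirna_mat_id(m)
  model <- add_entity(model, m, "gene", "nucleus", members = member_ids)
  model <- add_entity(model, mn, "miRNA", "nucleus", members = member_ids)
  model <- add_entity(model, mc, "miRNA", "cytoplasm", members = member_ids)
  model <- add_reaction(model, paste0("miRNA_transcription:", m),
                        "miRNA_transcription",
                        arcs_frame(enzymes = m, products = mn))
  model <- add_reaction(model, paste0("translocation:", mc), "translocation",
                        arcs_frame(substrates = mn, products = mc))
  model <- add_reaction(model, paste0("decay:", mc), "decay",
                        arcs_frame(substrates = mc))
  attr(model, "created") <- c(m, mn, mc,
                              paste0("miRNA_transcription:", m),
                              paste0("translocation:", mc),
                              paste0("decay:", mc))
  model
}

#' Add a lumped RISC miRNA-target binding reaction
#'
#' The cytoplasmic mature miRNA and the cytoplasmic target transcript are
#' consumed into an mRNA-miRNA complex with its own decay reaction, removing
#' the transcript from the translatable pool (stoichiometric sequestration).
#'
#' @param model A `mirpetri_model`.
#' @param mirna_id miRNA id whose mature species exists.
#' @param target_gene_id Target gene whose cytoplasmic mRNA exists.
#' @return The updated model, with attribute `"reaction"` naming the binding
#'   reaction id.
#' @export
add_mirna_binding <- function(model, mirna_id, target_gene_id) {
  mir <- mirna_mat_id(mirna_id)
  tgt <- mrna_id(target_gene_id)
  missing <- setdiff(c(mir, tgt), entity_ids(model))
  if (length(missing))
    stop("unknown_participant: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cplx <- paste0(tgt, ":", mirna_id)
  rid <- paste0("miRNA_binding:", mirna_id, ":", target_gene_id)
  model <- add_entity(model, cplx, "complex", "cytoplasm")
  model <- add_reaction(model, rid, "miRNA_binding",
                        arcs_frame(substrates = c(mir, tgt),
                                   products = cplx))
  model <- add_reaction(model, paste0("decay:", cplx), "decay",
                        arcs_frame(substrates = cplx))
  attr(model, "reaction") <- rid
  model
}

#' Add an anti-miRNA inhibitor pseudo-object for a miRNA
#'
#' Creates the inhibitor place (`anti-<mirna>`, a clampable experimental
#' input, initial concentration 0) and a binding reaction that sequesters
#' the mature miRNA into an inert decaying complex.
#'
#' @param model A `mirpetri_model`.
#' @param mirna_id miRNA id whose mature cytoplasmic species exists.
#' @return The updated model, with attribute `"created"` =
#'   c(inhibitor id, reaction id).
#' @export
add_anti_mirna <- function(model, mirna_id) {
  mir <- mirna_mat_id(mirna_id)
  if (!mir %in% entity_ids(model))
    stop("unknown_participant: ", mir, call. = FALSE)
  inh <- anti_id(mirna_id)
  cplx <- paste0(mir, ":", inh)
  rid <- paste0("anti_miRNA_binding:", mirna_id)
  model <- add_entity(model, inh, "pseudo_object", "cytoplasm")
  model <- add_entity(model, cplx, "complex", "cytoplasm")
  model <- add_reaction(model, rid, "anti_miRNA_binding",
                        arcs_frame(substrates = c(mir, inh),
                                   products = cplx))
  model <- add_reaction(model, paste0("decay:", cplx), "decay",
                        arcs_frame(substrates = cplx))
  attr(model, "created") <- c(inh, rid)
  model
}

#' Add a signaling reaction (complex formation, translocation,
#' (de)phosphorylation, activation, or other)
#'
#' @param model A `mirpetri_model`.
#' @param rtype One of complex_formation, translocation, phosphorylation,
#'   dephosphorylation, activation, other.
#' @param substrates,products Participant entity ids (must exist).
#' @param enzyme Optional catalyst id; required for phosphorylation.
#' @param inhibitors Optional inhibitor ids (enter the flux divisor).
#' @param weights Optional named numeric of arc weights (default 1).
#' @param k Kinetic parameter override; `NA` uses the class default.
#' @param id Optional reaction id; autogenerated otherwise.
#' @param reversible Whether the transition may fire backward.
#' @return The updated model, with attribute `"reaction"` naming the id.
#' @export
add_signaling_reaction <- function(model, rtype, substrates, products,
                                   enzyme = NULL, inhibitors = NULL,
                                   weights = NULL, k = NA_real_,
                                   id = NULL, reversible = FALSE) {
  rtype <- match.arg(rtype, c("complex_formation", "translocation",
                              "phosphorylation", "dephosphorylation",
                              "activation", "other"))
  if (!length(substrates))
    stop("malformed_reaction: signaling reaction needs >=1 substrate",
         call. = FALSE)
  if (rtype == "phosphorylation" && is.null(enzyme))
    stop("malformed_reaction: phosphorylation requires an enzyme arc",
         call. = FALSE)
  parts <- c(substrates, products, enzyme, inhibitors)
  unknown <- setdiff(parts, entity_ids(model))
  if (length(unknown))
    stop("unknown_participant: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(id))
    id <- paste0(rtype, ":", paste(substrates, collapse = "+"), ">",
                 paste(products, collapse = "+"))
  model <- add_reaction(model, id, rtype,
                        arcs_frame(substrates = substrates,
                                   products = products,
                                   enzymes = enzyme %||% character(0),
                                   inhibitors = inhibitors %||% character(0),
                                   weights = weights),
                        k = k, reversible = reversible)
  attr(model, "reaction") <- id
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
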