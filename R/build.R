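#' Build a full model from a pathway specification and a target table
#'
#' Applies the gene-expression motif to every gene, the miRNA biogenesis
#' motif to every miRNA, adds the declared standalone entities and
#' signaling reactions, one lumped RISC binding reaction per target-table
#' row whose miRNA and target are present in the pathway (other rows are
#' skipped with a warning), optionally one anti-miRNA inhibitor per miRNA,
#' and finally an explicit decay reaction for every protein and cytoplasmic
#' transcript that does not yet have one. Gene expression levels are
#' clamped (default 0.1 nM for protein-coding genes, 0 for miRNA genes, i.e.
#' miRNA expression is omitted unless perturbed). Output is deterministic
#' for identical inputs.
#'
#' @param pathway_spec A specification list as returned by
#'   [read_pathway_spec()].
#' @param table A `mirpetri_targets` table (or NULL for none).
#' @param with_anti_mirnas Add one anti-miRNA pseudo-object per miRNA.
#' @return A validated `mirpetri_model`.
#' @export
build_model <- function(pathway_spec, table = NULL,
                        with_anti_mirnas = FALSE) {
  spec <- pathway_spec
  model <- new_model()
  gene_level_default <- spec$gene_level %||% 0.1
  for (g in names(spec$genes)) {
    opts <- spec$genes[[g]] %||% list()
    model <- add_gene_expression_motif(model, g,
                                       members = opts$members %||%
                                         character(0))
    model <- set_clamp(model, g, opts$level %||% gene_level_default)
  }
  for (m in names(spec$mirnas)) {
    opts <- spec$mirnas[[m]] %||% list()
    model <- add_mirna_motif(model, m,
                             member_ids = opts$members %||% character(0))
    model <- set_clamp(model, m, opts$level %||% 0)
  }
  for (id in names(spec$entities)) {
    e <- spec$entities[[id]]
    model <- add_entity(model, id, e$role %||% "protein",
                        e$compartment %||% "cytoplasm",
                        members = e$members %||% character(0),
                        tags = unlist(e$tags) %||% character(0),
                        initial = e$initial %||% 0)
  }
  for (r in spec$reactions) {
    model <- add_signaling_reaction(
      model, r$rtype,
      substrates = unlist(r$substrates),
      products = unlist(r$products),
      enzyme = unlist(r$enzyme),
      inhibitors = unlist(r$inhibitors),
      weights = r$weights,
      k = r$k %||% NA_real_,
      id = r$id,
      reversible = isTRUE(r$reversible))
  }
  if (!is.null(table)) {
    skipped <- character(0)
    for (i in seq_len(nrow(table))) {
      mir <- table$mirna[i]; tgt <- table$target[i]
      if (mirna_mat_id(mir) %in% entity_ids(model) &&
          mrna_id(tgt) %in% entity_ids(model)) {
        model <- add_mirna_binding(model, mir, tgt)
      } else {
        skipped <- c(skipped, paste0(mir, "->", tgt))
      }
    }
    if (length(skipped))
      warning("skipped ", length(skipped),
              " target-table row(s) referencing unknown species: ",
              paste(utils::head(skipped, 5), collapse = ", "),
              if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  }
  if (with_anti_mirnas)
    for (m in names(spec$mirnas)) model <- add_anti_mirna(model, m)
  model <- ensure_decay(model)
  for (id in names(spec$clamps)) model <- set_clamp(model, id,
                                                    spec$clamps[[id]])
  validate_model(model)
  attr(model, "created") <- NULL
  attr(model, "reaction") <- NULL
  model
}

#' Add missing decay reactions for proteins and cytoplasmic transcripts
#'
#' @param model A `mirpetri_model`.
#' @return The updated model.
#' @export
ensure_decay <- function(model) {
  has_decay <- character(0)
  for (r in model$reactions)
    if (r$rtype == "decay")
      has_decay <- c(has_decay, r$arcs$place[r$arcs$direction == "input"])
  for (e in model$entities) {
    needs <- (e$role == "protein") ||
      (e$role == "mRNA" && e$compartment == "cytoplasm")
    if (needs && !e$id %in% has_decay)
      model <- add_reaction(model, paste0("decay:", e$id), "decay",
                            arcs_frame(substrates = e$id))
  }
  model
}
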