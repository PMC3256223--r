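#' @title Bio-Petri-net model containers
#' @name model
#' @description
#' A signaling/miRNA network is represented as a bipartite Petri net:
#' *places* are typed molecular species (genes, mRNAs, miRNAs, proteins,
#' compounds, complexes and pseudo-objects such as miRNA inhibitors), each
#' living in one of four compartments; *transitions* are typed biochemical
#' reactions connected to places by weighted substrate/product/enzyme/
#' inhibitor arcs. The marking assigns every place a concentration in nM.
NULL

COMPARTMENTS <- c("nucleus", "cytoplasm", "plasma_membrane", "extracellular")

ENTITY_ROLES <- c("gene", "mRNA", "miRNA", "protein", "compound",
                  "complex", "pseudo_object")

REACTION_TYPES <- c("transcription", "miRNA_transcription", "translation",
                    "decay", "complex_formation", "translocation",
                    "phosphorylation", "dephosphorylation", "activation",
                    "miRNA_binding", "anti_miRNA_binding", "other")

ARC_ROLES <- c("substrate", "product", "enzyme", "inhibitor")

#' Create an empty Petri-net model
#'
#' @return An object of class `mirpetri_model` with no entities, reactions,
#'   clamps or initial marking.
#' @export
new_model <- function() {
  structure(
    list(entities = list(), reactions = list(),
         clamps = stats::setNames(numeric(0), character(0)),
         initial_marking = stats::setNames(numeric(0), character(0))),
    class = "mirpetri_model")
}

#' @export
print.mirpetri_model <- function(x, ...) {
  cat("<mirpetri_model>", length(x$entities), "places,",
      length(x$reactions), "transitions,", length(x$clamps), "clamps\n")
  invisible(x)
}

entity_ids <- function(model) names(model$entities)
reaction_ids <- function(model) names(model$reactions)

assert_new_id <- function(model, id) {
  if (id %in% entity_ids(model) || id %in% reaction_ids(model)) {
    stop("duplicate_id: '", id, "' already used as a place or transition id",
         call. = FALSE)
  }
}

#' Add a molecular species (place) to a model
#'
#' @param model A `mirpetri_model`.
#' @param id Unique species id.
#' @param role One of the seven component classes: gene, mRNA, miRNA,
#'   protein, compound, complex, pseudo_object.
#' @param compartment One of nucleus, cytoplasm, plasma_membrane,
#'   extracellular.
#' @param members Optional character vector of member ids for set entities
#'   (a single place standing for a gene/miRNA family); metadata only.
#' @param tags Optional character tags; `"ligand_receptor"` marks complexes
#'   that follow the slow decay timescale.
#' @param initial Initial concentration (nM), default 0.
#' @return The updated model.
#' @export
add_entity <- function(model, id, role, compartment, members = character(0),
                       tags = character(0), initial = 0) {
  stopifnot(is.character(id), nzchar(id))
  role <- match.arg(role, ENTITY_ROLES)
  compartment <- match.arg(compartment, COMPARTMENTS)
  assert_new_id(model, id)
  model$entities[[id]] <- list(id = id, role = role,
                               compartment = compartment,
                               members = as.character(members),
                               tags = as.character(tags))
  model$initial_marking[id] <- initial
  model
}

new_arc <- function(place, role, weight = 1) {
  role <- match.arg(role, ARC_ROLES)
  stopifnot(weight > 0)
  data.frame(place = place,
             direction = if (role == "product") "output" else "input",
             role = role, weight = as.numeric(weight),
             stringsAsFactors = FALSE)
}

arcs_frame <- function(substrates = character(0), products = character(0),
                       enzymes = character(0), inhibitors = character(0),
                       weights = NULL) {
  w <- function(ids) {
    if (is.null(weights)) rep(1, length(ids))
    else vapply(ids, function(i) if (i %in% names(weights)) weights[[i]] else 1,
                numeric(1))
  }
  rows <- list()
  if (length(substrates))
    rows <- c(rows, Map(new_arc, substrates, "substrate", w(substrates)))
  if (length(products))
    rows <- c(rows, Map(new_arc, products, "product", w(products)))
  if (length(enzymes))
    rows <- c(rows, Map(new_arc, enzymes, "enzyme", w(enzymes)))
  if (length(inhibitors))
    rows <- c(rows, Map(new_arc, inhibitors, "inhibitor", w(inhibitors)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Add a reaction (transition) to a model
#'
#' Every reaction needs at least one input arc and, except for decay
#' reactions, at least one output arc. All arc places must already exist.
#'
#' @param model A `mirpetri_model`.
#' @param id Unique reaction id.
#' @param rtype Reaction class (see `REACTION_TYPES`).
#' @param arcs Arc data frame built by the motif helpers.
#' @param k Kinetic parameter; `NA` picks the per-class default from the
#'   [kinetic_config()] in force at simulation time.
#' @param reversible Whether the transition may fire backward.
#' @param flux_override Optional fixed flux (nM/step) replacing the
#'   mass-action rate law; used to reproduce printed worked examples where
#'   the rate law itself is not identifiable.
#' @param kclass Kinetic-parameter class used to resolve a default `k`
#'   (defaults to `rtype`; mRNA translocation uses its own slower constant).
#' @return The updated model.
#' @export
add_reaction <- function(model, id, rtype, arcs, k = NA_real_,
                         reversible = FALSE, flux_override = NA_real_,
                         kclass = rtype) {
  rtype <- match.arg(rtype, REACTION_TYPES)
  assert_new_id(model, id)
  if (is.null(arcs) || !nrow(arcs[arcs$direction == "input", , drop = FALSE]))
    stop("malformed_reaction: '", id, "' has no input arcs", call. = FALSE)
  if (rtype != "decay" &&
      !nrow(arcs[arcs$direction == "output", , drop = FALSE]))
    stop("malformed_reaction: '", id, "' has no output arcs", call. = FALSE)
  unknown <- setdiff(arcs$place, entity_ids(model))
  if (length(unknown))
    stop("unknown_participant: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model$reactions[[id]] <- list(id = id, rtype = rtype, arcs = arcs,
                                k = k, reversible = reversible,
                                flux_override = flux_override,
                                kclass = kclass)
  model
}

#' Clamp a species at a fixed concentration
#'
#' Clamped species (ligands such as EGF, metabolites such as ATP/ADP, gene
#' expression levels, applied anti-miRNA doses) are reset to their clamp
#' value after every simulation step.
#'
#' @param model A `mirpetri_model`.
#' @param id Species id.
#' @param value Concentration in nM.
#' @return The updated model.
#' @export
set_clamp <- function(model, id, value) {
  if (!id %in% entity_ids(model))
    stop("unknown_participant: ", id, call. = FALSE)
  stopifnot(value >= 0)
  model$clamps[id] <- value
  model$initial_marking[id] <- value
  model
}

#' Validate the structural invariants of a model
#'
#' Checks bipartiteness (arcs only connect a place and a transition),
#' disjointness of place and transition id sets, arc weight positivity, and
#' that every cytoplasmic mRNA and every protein takes part in exactly one
#' decay reaction (nuclear transcripts are cleared by translocation).
#'
#' @param model A `mirpetri_model`.
#' @return Invisibly `TRUE`; stops with a named error otherwise.
#' @export
validate_model <- function(model) {
  pids <- entity_ids(model)
  tids <- reaction_ids(model)
  if (length(intersect(pids, tids)))
    stop("invariant_violation: place and transition id sets overlap",
         call. = FALSE)
  decay_count <- stats::setNames(integer(length(pids)), pids)
  for (r in model$reactions) {
    if (any(!r$arcs$place %in% pids))
      stop("invariant_violation: arc references non-place id in '",
           r$id, "'", call. = FALSE)
    if (any(r$arcs$weight <= 0))
      stop("invariant_violation: non-positive arc weight in '", r$id, "'",
           call. = FALSE)
    if (r$rtype == "decay") {
      inp <- r$arcs$place[r$arcs$direction == "input"]
      decay_count[inp] <- decay_count[inp] + 1L
    }
  }
  for (e in model$entities) {
    needs_decay <- (e$role == "protein") ||
      (e$role == "mRNA" && e$compartment == "cytoplasm")
    if (needs_decay && decay_count[[e$id]] != 1L)
      stop("invariant_violation: '", e$id, "' (", e$role, ") participates ",
           "in ", decay_count[[e$id]], " decay reactions, expected 1",
           call. = FALSE)
    if (length(e$members)) {
      if (!e$role %in% c("gene", "miRNA", "mRNA", "protein"))
        stop("invariant_violation: set entity '", e$id,
             "' has unsupported role", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Census of model components and reactions
#'
#' Tabulates entities by component class and reactions by reaction class,
#' with totals, mirroring the standard model summary table.
#'
#' @param model A `mirpetri_model`.
#' @return A list with `components` (named integer vector over the seven
#'   entity roles plus `Sum`) and `reactions` (named integer vector over the
#'   reaction classes plus `Sum`).
#' @export
census <- function(model) {
  comp <- stats::setNames(integer(length(ENTITY_ROLES)), ENTITY_ROLES)
  for (e in model$entities) comp[e$role] <- comp[e$role] + 1L
  rxn <- stats::setNames(integer(length(REACTION_TYPES)), REACTION_TYPES)
  for (r in model$reactions) rxn[r$rtype] <- rxn[r$rtype] + 1L
  list(components = c(comp, Sum = sum(comp)),
       reactions = c(rxn, Sum = sum(rxn)))
}
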