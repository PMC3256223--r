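#' Read a miRNA-target interaction table
#'
#' Expects a TSV with header `mirna<TAB>target<TAB>reference`. Duplicate
#' (mirna, target) pairs are removed with a warning; empty ids are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `mirpetri_targets` with columns `mirna`,
#'   `target`, `reference`.
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mirna", "target", "reference")
  if (!all(need %in% names(df)))
    stop("bad_target_table: header must contain ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[need]
  if (any(!nzchar(df$mirna)) || any(!nzchar(df$target)))
    stop("bad_target_table: empty miRNA or target id", call. = FALSE)
  dup <- duplicated(df[c("mirna", "target")])
  if (any(dup)) {
    warning(sum(dup), " duplicate miRNA-target pair(s) removed",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("mirpetri_targets", "data.frame")
  df
}

#' Write a miRNA-target interaction table
#'
#' @param table Data frame with columns `mirna`, `target`, `reference`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_target_table <- function(table, path) {
  utils::write.table(table[c("mirna", "target", "reference")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway specification from YAML
#'
#' The specification lists `genes:` and `mirnas:` (each optionally with
#' `members` for set entities and `level` for the clamped gene expression
#' level in nM), standalone `entities:` (ligands, metabolites and signaling
#' products with `role`, `compartment`, optional `tags`), `reactions:`
#' (rtype, substrates, products, enzyme, inhibitors, optional `k` and
#' `weights`), and `clamps:`.
#'
#' @param path YAML file path.
#' @return The parsed specification list.
#' @export
read_pathway_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  for (fld in c("genes", "mirnas", "entities", "reactions", "clamps"))
    if (is.null(spec[[fld]])) spec[[fld]] <- list()
  spec
}

## --- SBML ---------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MP_NS <- "https://mirpetri.r-lib.org/schema"

sanitize_sid <- function(ids) {
  out <- gsub("[^A-Za-z0-9_]", "_", ids)
  bad <- !grepl("^[A-Za-z_]", out)
  out[bad] <- paste0("x", out[bad])
  while (any(d <- duplicated(out))) out[d] <- paste0(out[d], "_")
  out
}

#' Write a model as SBML Level 3
#'
#' Species map to places (true ids kept in the `name` attribute, clamped
#' species flagged as boundary conditions), reactions to transitions with
#' reactant/product stoichiometries as arc weights and enzyme/inhibitor
#' arcs as modifiers; entity roles, tags, member lists and kinetic
#' parameters are stored in a package annotation namespace.
#'
#' @param model A `mirpetri_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sbml <- function(model, path) {
  ids <- entity_ids(model)
  sid <- stats::setNames(sanitize_sid(ids), ids)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:mp" = MP_NS, level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "mirpetri_model")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in COMPARTMENTS)
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (e in model$entities) {
    sp <- xml2::xml_add_child(
      los, "species", id = sid[[e$id]], name = e$id,
      compartment = e$compartment,
      initialConcentration =
        format(model$initial_marking[[e$id]], digits = 17),
      boundaryCondition = tolower(e$id %in% names(model$clamps)),
      hasOnlySubstanceUnits = "false", constant = "false")
    ann <- xml2::xml_add_child(sp, "annotation")
    xml2::xml_add_child(ann, "mp:entity", role = e$role,
                        members = paste(e$members, collapse = ","),
                        tags = paste(e$tags, collapse = ","))
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = sanitize_sid(r$id),
                              name = r$id,
                              reversible = tolower(isTRUE(r$reversible)))
    ann <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(ann, "mp:reaction", rtype = r$rtype,
                        k = ifelse(is.na(r$k), "", format(r$k, digits = 17)),
                        kclass = r$kclass %||% r$rtype,
                        fluxOverride = ifelse(is.na(r$flux_override), "",
                                              format(r$flux_override,
                                                     digits = 17)))
    p <- arc_split(r)
    if (nrow(p$sub)) {
      lst <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in seq_len(nrow(p$sub)))
        xml2::xml_add_child(lst, "speciesReference",
                            species = sid[[p$sub$place[i]]],
                            stoichiometry = format(p$sub$weight[i],
                                                   digits = 17),
                            constant = "true")
    }
    if (nrow(p$prod)) {
      lst <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in seq_len(nrow(p$prod)))
        xml2::xml_add_child(lst, "speciesReference",
                            species = sid[[p$prod$place[i]]],
                            stoichiometry = format(p$prod$weight[i],
                                                   digits = 17),
                            constant = "true")
    }
    mods <- rbind(p$enz, p$inh)
    if (nrow(mods)) {
      lst <- xml2::xml_add_child(rx, "listOfModifiers")
      for (i in seq_len(nrow(mods)))
        xml2::xml_add_child(lst, "modifierSpeciesReference",
                            species = sid[[mods$place[i]]],
                            "mp:role" = mods$role[i],
                            "mp:weight" = format(mods$weight[i],
                                                 digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML Level 3
#'
#' Reads the dialect written by [write_sbml()]: species compartments must
#' map to the four-compartment enum, boundary-condition species become
#' clamps, and the package annotations restore entity roles and reaction
#' kinetics.
#'
#' @param path SBML file path.
#' @return A `mirpetri_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("sbml_parse_error: ", conditionMessage(e),
                         call. = FALSE))
  ns <- c(s = SBML_NS, mp = MP_NS)
  if (!length(xml2::xml_find_all(doc, "/s:sbml/s:model", ns)))
    stop("sbml_parse_error: no <model> element in SBML namespace",
         call. = FALSE)
  model <- new_model()
  sp_nodes <- xml2::xml_find_all(doc, "//s:species", ns)
  sid2name <- character(0)
  clamps <- list()
  for (sp in sp_nodes) {
    sid <- xml2::xml_attr(sp, "id")
    nm <- xml2::xml_attr(sp, "name")
    if (is.na(nm)) nm <- sid
    sid2name[sid] <- nm
    cp <- xml2::xml_attr(sp, "compartment")
    if (!cp %in% COMPARTMENTS)
      stop("sbml_parse_error: unknown compartment '", cp, "'",
           call. = FALSE)
    ent <- xml2::xml_find_first(sp, ".//mp:entity", ns)
    role <- if (inherits(ent, "xml_missing")) "protein"
            else xml2::xml_attr(ent, "role")
    split_csv <- function(x) if (is.na(x) || !nzchar(x)) character(0)
                             else strsplit(x, ",", fixed = TRUE)[[1]]
    members <- if (inherits(ent, "xml_missing")) character(0)
               else split_csv(xml2::xml_attr(ent, "members"))
    tags <- if (inherits(ent, "xml_missing")) character(0)
            else split_csv(xml2::xml_attr(ent, "tags"))
    init <- suppressWarnings(
      as.numeric(xml2::xml_attr(sp, "initialConcentration")))
    if (is.na(init)) init <- 0
    model <- add_entity(model, nm, role, cp, members = members, tags = tags,
                        initial = init)
    if (identical(xml2::xml_attr(sp, "boundaryCondition"), "true"))
      clamps[[nm]] <- init
  }
  rx_nodes <- xml2::xml_find_all(doc, "//s:reaction", ns)
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "name")
    if (is.na(rid)) rid <- xml2::xml_attr(rx, "id")
    ann <- xml2::xml_find_first(rx, ".//mp:reaction", ns)
    rtype <- if (inherits(ann, "xml_missing")) "other"
             else xml2::xml_attr(ann, "rtype")
    kc <- if (inherits(ann, "xml_missing")) rtype
          else xml2::xml_attr(ann, "kclass")
    num_or_na <- function(x) if (is.na(x) || !nzchar(x)) NA_real_
                             else as.numeric(x)
    k <- if (inherits(ann, "xml_missing")) NA_real_
         else num_or_na(xml2::xml_attr(ann, "k"))
    fo <- if (inherits(ann, "xml_missing")) NA_real_
          else num_or_na(xml2::xml_attr(ann, "fluxOverride"))
    rows <- list()
    grab <- function(xpath, role) {
      for (sr in xml2::xml_find_all(rx, xpath, ns)) {
        w <- suppressWarnings(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
        if (is.na(w)) {
          w <- suppressWarnings(as.numeric(xml2::xml_attr(sr, "mp:weight")))
          if (is.na(w)) w <- 1
        }
        rl <- role
        if (role == "modifier") {
          rl <- xml2::xml_attr(sr, "mp:role")
          if (is.na(rl)) rl <- "enzyme"
        }
        rows[[length(rows) + 1L]] <<-
          new_arc(sid2name[[xml2::xml_attr(sr, "species")]], rl, w)
      }
    }
    grab("./s:listOfReactants/s:speciesReference", "substrate")
    grab("./s:listOfProducts/s:speciesReference", "product")
    grab("./s:listOfModifiers/s:modifierSpeciesReference", "modifier")
    arcs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    model <- add_reaction(model, rid, rtype, arcs, k = k,
                          reversible = identical(
                            xml2::xml_attr(rx, "reversible"), "true"),
                          flux_override = fo, kclass = kc)
  }
  for (nm in names(clamps)) model <- set_clamp(model, nm, clamps[[nm]])
  model
}
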