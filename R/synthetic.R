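#' @title Fixture and random-network generation
#' @name synthetic
#' @description
#' The package ships a desk-scale fixture of the EGFR cascade
#' (EGF+EGFR -> PI3K -> PIP3 -> PDPK1 -> AKT -> substrate proteins, with a
#' parallel MEK/ERK branch and PTEN acting on PIP3) together with every
#' literature-curated miRNA-target relation used in the analyses:
#' mir-192 (6 targets), mir-181c (2), mir-489 (4), mir-34a (14), and the
#' five-member miRNA family set mir-TRDD with its four shared
#' biogenesis-machinery targets. Functionally redundant kinase families
#' (MEK, ERK, AKT, PKC, CAMK, CDKN1) are single set entities whose member
#' lists are metadata. Seeded random networks with the same cascade shape
#' and a truncated-geometric target-degree distribution support
#' property-based testing of the screening statistics.
NULL

FIXTURE_TARGETS <- list(
  "mir-192"  = c("MDM2", "EGFR", "PIK3CA", "TP53", "PTEN", "CDKN1"),
  "mir-181c" = c("AKT", "MYC"),
  "mir-489"  = c("CDKN1", "PIK3CA", "TP53", "AKT"),
  "mir-34a"  = c("MTOR", "ERK", "MDM2", "PIK3R1", "EGFR", "RPS6KA5",
                 "CAMK", "TP53", "PTEN", "PKC", "PDPK1", "MYC", "CDKN1",
                 "ELK1"),
  "mir-TRDD" = c("TARBP2", "RNASEN", "DICER1", "DGCR8"))

FIXTURE_SET_MEMBERS <- list(
  MEK = c("MAP2K1", "MAP2K2"),
  ERK = c("MAPK1", "MAPK3"),
  AKT = c("AKT1", "AKT2", "AKT3"),
  PKC = c("PRKCA", "PRKCB"),
  CAMK = c("CAMK2A", "CAMK2B"),
  CDKN1 = c("CDKN1A", "CDKN1B"))

MIR_TRDD_MEMBERS <- c("mir-631", "mir-608", "mir-604", "mir-492",
                      "mir-30a")

phospho_id <- function(gene) paste0("P-", protein_id(gene))
active_id <- function(gene) paste0("Active-", gene)

#' The packaged EGFR/miRNA pathway fixture
#'
#' @return A list with `spec` (pathway specification list) and `table`
#'   (`mirpetri_targets` data frame), deterministic and version-frozen.
#' @export
paper_fixture <- function() {
  genes <- c("EGFR", "PIK3CA", "PIK3R1", "PDPK1", "AKT", "BAD", "MEK",
             "ERK", "ELK1", "MYC", "TP53", "PTEN", "MDM2", "CDKN1",
             "MTOR", "RPS6KA5", "CAMK", "PKC", "TARBP2", "RNASEN",
             "DICER1", "DGCR8")
  gene_specs <- stats::setNames(lapply(genes, function(g) {
    if (g %in% names(FIXTURE_SET_MEMBERS))
      list(members = FIXTURE_SET_MEMBERS[[g]])
    else list()
  }), genes)
  mirna_specs <- list(
    "mir-192" = list(), "mir-181c" = list(), "mir-489" = list(),
    "mir-34a" = list(), "mir-TRDD" = list(members = MIR_TRDD_MEMBERS))
  entities <- list(
    EGF = list(role = "protein", compartment = "extracellular"),
    ATP = list(role = "compound", compartment = "cytoplasm"),
    ADP = list(role = "compound", compartment = "cytoplasm"),
    PIP2 = list(role = "compound", compartment = "plasma_membrane"),
    PIP3 = list(role = "compound", compartment = "plasma_membrane"),
    "EGF:EGFR" = list(role = "complex", compartment = "plasma_membrane",
                      tags = "ligand_receptor"),
    "Active-PIK3CA" = list(role = "protein",
                           compartment = "plasma_membrane"),
    "Active-PDPK1" = list(role = "protein",
                          compartment = "plasma_membrane"),
    "Active-MEK" = list(role = "protein", compartment = "cytoplasm",
                        members = FIXTURE_SET_MEMBERS$MEK))
  for (g in c("AKT", "BAD", "TP53", "MDM2", "CDKN1", "ERK", "ELK1",
              "MYC"))
    entities[[phospho_id(g)]] <- list(role = "protein",
                                      compartment = "cytoplasm")
  phos <- function(g, enz) list(
    rtype = "phosphorylation",
    substrates = c(protein_id(g), "ATP"),
    products = c(phospho_id(g), "ADP"), enzyme = enz)
  reactions <- list(
    list(rtype = "complex_formation",
         substrates = c("EGF", protein_id("EGFR")),
         products = "EGF:EGFR"),
    list(rtype = "activation",
         substrates = c(protein_id("PIK3CA"), protein_id("PIK3R1")),
         products = "Active-PIK3CA", enzyme = "EGF:EGFR"),
    list(rtype = "other", substrates = "PIP2", products = "PIP3",
         enzyme = "Active-PIK3CA"),
    list(rtype = "dephosphorylation", substrates = "PIP3",
         products = "PIP2", enzyme = protein_id("PTEN"), k = 0.15),
    list(rtype = "activation", substrates = protein_id("PDPK1"),
         products = "Active-PDPK1", enzyme = "PIP3"),
    phos("AKT", "Active-PDPK1"),
    phos("BAD", phospho_id("AKT")),
    list(rtype = "dephosphorylation", substrates = phospho_id("BAD"),
         products = protein_id("BAD")),
    phos("TP53", phospho_id("AKT")),
    phos("MDM2", phospho_id("AKT")),
    phos("CDKN1", phospho_id("AKT")),
    list(rtype = "activation", substrates = protein_id("MEK"),
         products = "Active-MEK", enzyme = "EGF:EGFR"),
    phos("ERK", "Active-MEK"),
    phos("ELK1", phospho_id("ERK")),
    phos("MYC", phospho_id("ERK")))
  spec <- list(genes = gene_specs, mirnas = mirna_specs,
               entities = entities, reactions = reactions,
               clamps = list(EGF = 1, ATP = 1, ADP = 1, PIP2 = 1),
               gene_level = 0.1)
  rows <- do.call(rbind, lapply(names(FIXTURE_TARGETS), function(m) {
    data.frame(mirna = m, target = FIXTURE_TARGETS[[m]],
               reference = "curated", stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("mirpetri_targets", "data.frame")
  list(spec = spec, table = rows)
}

#' Build the packaged fixture model
#'
#' @param with_anti_mirnas Add anti-miRNA pseudo-objects.
#' @return A validated `mirpetri_model`.
#' @export
fixture_model <- function(with_anti_mirnas = FALSE) {
  fx <- paper_fixture()
  build_model(fx$spec, fx$table, with_anti_mirnas = with_anti_mirnas)
}

#' Default readout sets of the fixture
#'
#' @return A list with `actives` (phosphorylated/active proteins downstream
#'   of the receptor), `akt_dependent` (the AKT-branch subset used for
#'   activation-threshold scans), and `mrnas` (all cytoplasmic transcripts).
#' @export
fixture_readouts <- function() {
  list(
    actives = c("P-AKT-1", "P-BAD-1", "P-TP53-1", "P-MDM2-1",
                "P-CDKN1-1", "Active-MEK", "P-ERK-1", "P-ELK1-1",
                "P-MYC-1"),
    akt_dependent = c("P-AKT-1", "P-BAD-1", "P-TP53-1", "P-MDM2-1",
                      "P-CDKN1-1"),
    mrnas = paste0("mRNA-", names(paper_fixture()$spec$genes)))
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a seeded random signaling/miRNA network
#'
#' Produces a linear phosphorylation cascade of the stated depth behind a
#' ligand-receptor pair, remaining genes as terminal-kinase substrates, and
#' miRNAs whose target-set sizes follow a truncated geometric distribution
#' (most miRNAs few targets, a tail with many). A configurable fraction of
#' miRNAs additionally targets a cascade key component (the receptor or
#' the terminal kinase); with `key_frac = 0` no miRNA touches either.
#' Generation is a pure function of the parameters and seed.
#'
#' @param n_genes Number of protein-coding genes (>= cascade_depth + 1).
#' @param n_mirnas Number of miRNAs.
#' @param cascade_depth Number of kinases in the chain behind the receptor.
#' @param degree_p Success probability of the geometric target-degree
#'   distribution (mean degree roughly `1 + (1-p)/p`).
#' @param key_frac Fraction of miRNAs forced to target a key component.
#' @param seed Integer seed.
#' @return A list with `spec` and `table` as in [paper_fixture()].
#' @export
random_network <- function(n_genes = 8, n_mirnas = 5, cascade_depth = 3,
                           degree_p = 0.4, key_frac = 0, seed = 1) {
  stopifnot(n_genes >= cascade_depth + 1, n_mirnas >= 1,
            cascade_depth >= 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  receptor <- genes[1]
  chain <- genes[seq_len(cascade_depth) + 1L]
  terminal <- chain[length(chain)]
  leaves <- setdiff(genes, c(receptor, chain))
  key <- c(receptor, terminal)
  entities <- list(
    LIG = list(role = "protein", compartment = "extracellular"),
    ATP = list(role = "compound", compartment = "cytoplasm"),
    ADP = list(role = "compound", compartment = "cytoplasm"),
    "LIG:R" = list(role = "complex", compartment = "plasma_membrane",
                   tags = "ligand_receptor"))
  reactions <- list(
    list(rtype = "complex_formation",
         substrates = c("LIG", protein_id(receptor)),
         products = "LIG:R"))
  prev <- "LIG:R"
  for (g in chain) {
    entities[[phospho_id(g)]] <- list(role = "protein",
                                      compartment = "cytoplasm")
    reactions[[length(reactions) + 1L]] <- list(
      rtype = "phosphorylation",
      substrates = c(protein_id(g), "ATP"),
      products = c(phospho_id(g), "ADP"), enzyme = prev)
    prev <- phospho_id(g)
  }
  for (g in leaves) {
    entities[[phospho_id(g)]] <- list(role = "protein",
                                      compartment = "cytoplasm")
    reactions[[length(reactions) + 1L]] <- list(
      rtype = "phosphorylation",
      substrates = c(protein_id(g), "ATP"),
      products = c(phospho_id(g), "ADP"),
      enzyme = phospho_id(terminal))
  }
  mirnas <- sprintf("mir-s%02d", seq_len(n_mirnas))
  n_key <- round(key_frac * n_mirnas)
  pool <- setdiff(genes, key)
  if (!length(pool))
    stop("infeasible_degree: no non-key genes available as targets",
         call. = FALSE)
  table <- with_preserved_rng(seed, {
    rows <- lapply(seq_len(n_mirnas), function(i) {
      deg <- 1L + min(stats::rgeom(1, degree_p), length(pool) - 1L)
      tg <- sample(pool, deg)
      if (i <= n_key) tg <- unique(c(sample(key, 1), tg))
      data.frame(mirna = mirnas[i], target = sort(tg),
                 reference = "synthetic", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(table) <- NULL
  class(table) <- c("mirpetri_targets", "data.frame")
  spec <- list(
    genes = stats::setNames(rep(list(list()), n_genes), genes),
    mirnas = stats::setNames(rep(list(list()), n_mirnas), mirnas),
    entities = entities, reactions = reactions,
    clamps = list(LIG = 1, ATP = 1, ADP = 1), gene_level = 0.1)
  list(spec = spec, table = table)
}

#' Write a synthetic stand-in for a supplementary miRNA-target list
#'
#' Emulates the TSV dialect of a curated reference list of miRNA-target
#' pairs so the reading/counting code paths can be exercised without the
#' original file. Rows are unique (mirna, target) pairs.
#'
#' @param n_rows Number of rows.
#' @param seed Integer seed.
#' @param path Output path (default a temp file).
#' @return The path, invisibly; the file parses with
#'   [read_target_table()].
#' @export
s1_emulator <- function(n_rows = 200, seed = 1, path = tempfile(
                          fileext = ".tsv")) {
  tab <- with_preserved_rng(seed, {
    mirnas <- sprintf("mir-e%03d", seq_len(max(10, n_rows %/% 5)))
    targets <- sprintf("GENE%03d", seq_len(max(10, n_rows %/% 4)))
    pairs <- expand.grid(mirna = mirnas, target = targets,
                         stringsAsFactors = FALSE)
    sel <- sample(nrow(pairs), min(n_rows, nrow(pairs)))
    data.frame(mirna = pairs$mirna[sel], target = pairs$target[sel],
               reference = sprintf("PMID:%07d",
                                   sample.int(9999999, length(sel))),
               stringsAsFactors = FALSE)
  })
  write_target_table(tab, path)
  invisible(path)
}
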