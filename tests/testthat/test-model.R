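test_that("gene expression motif creates the central-dogma chain", {
  m <- add_gene_expression_motif(new_model(), "BAD")
  expect_length(m$entities, 4)
  expect_length(m$reactions, 5)
  roles <- vapply(m$entities, `[[`, "", "role")
  expect_equal(unname(table(roles)[c("gene", "mRNA", "protein")]),
               c(1L, 2L, 1L), ignore_attr = TRUE)
  comps <- vapply(m$entities, `[[`, "", "compartment")
  expect_equal(unname(comps[c("BAD", "mRNA-BAD@nuc", "mRNA-BAD", "BAD-1")]),
               c("nucleus", "nucleus", "cytoplasm", "cytoplasm"))
  rtypes <- sort(vapply(m$reactions, `[[`, "", "rtype"))
  expect_equal(unname(rtypes),
               c("decay", "decay", "transcription", "translation",
                 "translocation"))
  expect_error(add_gene_expression_motif(m, "BAD"), "duplicate_id")
})

test_that("miRNA motif lumps biogenesis into 3 entities and 3 reactions", {
  m <- add_mirna_motif(new_model(), "mir-192")
  expect_length(m$entities, 3)
  expect_length(m$reactions, 3)
  trdd <- add_mirna_motif(new_model(), "mir-TRDD",
                          member_ids = c("mir-631", "mir-608", "mir-604",
                                         "mir-492", "mir-30a"))
  expect_length(trdd$entities[["mir-TRDD"]]$members, 5)
  expect_error(add_mirna_motif(m, "mir-192"), "duplicate_id")
})

test_that("RISC binding sequesters the transcript into a decaying complex", {
  m <- add_gene_expression_motif(new_model(), "EGFR")
  m <- add_mirna_motif(m, "mir-192")
  m <- add_mirna_binding(m, "mir-192", "EGFR")
  rid <- attr(m, "reaction")
  r <- m$reactions[[rid]]
  expect_equal(r$rtype, "miRNA_binding")
  expect_setequal(r$arcs$place[r$arcs$role == "substrate"],
                  c("mir-192-mat", "mRNA-EGFR"))
  cplx <- r$arcs$place[r$arcs$role == "product"]
  expect_equal(m$entities[[cplx]]$role, "complex")
  expect_true(paste0("decay:", cplx) %in% names(m$reactions))
  expect_error(add_mirna_binding(m, "mir-9000", "EGFR"),
               "unknown_participant")
})

test_that("n miRNAs against one mRNA create n distinct binding reactions", {
  m <- add_gene_expression_motif(new_model(), "EGFR")
  for (mir in c("mir-a", "mir-b", "mir-c")) {
    m <- add_mirna_motif(m, mir)
    m <- add_mirna_binding(m, mir, "EGFR")
  }
  expect_equal(unname(census(m)$reactions["miRNA_binding"]), 3L)
})

test_that("anti-miRNA pseudo-object binds only its cognate miRNA", {
  m <- add_gene_expression_motif(new_model(), "TP53")
  m <- add_mirna_motif(m, "mir-34a")
  m <- add_mirna_binding(m, "mir-34a", "TP53")
  m <- add_anti_mirna(m, "mir-34a")
  expect_equal(m$entities[["anti-mir-34a"]]$role, "pseudo_object")
  r <- m$reactions[["anti_miRNA_binding:mir-34a"]]
  expect_setequal(r$arcs$place[r$arcs$role == "substrate"],
                  c("mir-34a-mat", "anti-mir-34a"))
  # the inhibitor never touches the target transcript directly
  expect_false("mRNA-TP53" %in% r$arcs$place)
  expect_error(add_anti_mirna(m, "mir-21"), "unknown_participant")
})

test_that("signaling reactions validate participants and arc roles", {
  m <- add_gene_expression_motif(new_model(), "BAD")
  m <- add_entity(m, "ATP", "compound", "cytoplasm")
  m <- add_entity(m, "ADP", "compound", "cytoplasm")
  m <- add_entity(m, "P-AKT", "protein", "plasma_membrane")
  m <- add_entity(m, "P-BAD-1", "protein", "cytoplasm")
  expect_error(add_signaling_reaction(m, "phosphorylation",
                                      substrates = c("BAD-1", "ATP"),
                                      products = c("P-BAD-1", "ADP")),
               "requires an enzyme")
  expect_error(add_signaling_reaction(m, "phosphorylation",
                                      substrates = character(0),
                                      products = "P-BAD-1",
                                      enzyme = "P-AKT"),
               "malformed_reaction")
  expect_error(add_signaling_reaction(m, "phosphorylation",
                                      substrates = c("BAD-1", "GTP"),
                                      products = "P-BAD-1",
                                      enzyme = "P-AKT"),
               "unknown_participant")
  m <- add_signaling_reaction(m, "phosphorylation",
                              substrates = c("BAD-1", "ATP"),
                              products = c("P-BAD-1", "ADP"),
                              enzyme = "P-AKT")
  r <- m$reactions[[attr(m, "reaction")]]
  expect_equal(miRpetri:::resolve_k(r, kinetic_config()), 0.35)
})

test_that("kinetic defaults match the published parameter table", {
  k <- kinetic_config()$k_default
  expect_equal(unname(k[c("complex_formation", "phosphorylation",
                          "dephosphorylation", "transcription", "decay",
                          "translocation", "translocation_mRNA",
                          "dephosphorylation_enzyme", "other")]),
               c(0.55, 0.35, 0.01, 0.5, 0.02, 0.8, 0.5, 0.15, 0.35))
  cfg <- kinetic_config()
  expect_equal(cfg$inhibitory_parameter, 1.5)
  expect_equal(cfg$decay_protein_rate, 0.09)
  expect_equal(cfg$decay_protein_period, 1L)
  expect_equal(cfg$decay_ligand_receptor_rate, 0.2)
  expect_equal(cfg$decay_ligand_receptor_period, 10L)
})

test_that("build_model applies motifs, bindings and structural invariants", {
  fx <- paper_fixture()
  mod <- build_model(fx$spec, fx$table, with_anti_mirnas = TRUE)
  expect_silent(validate_model(mod))
  cz <- census(mod)
  # one binding reaction per table row (all fixture targets are present)
  expect_equal(unname(cz$reactions["miRNA_binding"]), nrow(fx$table))
  # one pseudo-object per miRNA
  expect_equal(unname(cz$components["pseudo_object"]),
               length(fx$spec$mirnas))
  # empty table -> no binding reactions
  mod0 <- build_model(fx$spec, fx$table[0, ])
  expect_equal(unname(census(mod0)$reactions["miRNA_binding"]), 0L)
  # unknown targets skipped with a warning, not an error
  tab <- rbind(fx$table,
               data.frame(mirna = "mir-192", target = "NOSUCH",
                          reference = "x"))
  class(tab) <- class(fx$table)
  expect_warning(modw <- build_model(fx$spec, tab), "skipped 1")
  expect_equal(census(modw)$reactions["miRNA_binding"],
               census(build_model(fx$spec, fx$table))$reactions[
                 "miRNA_binding"])
})

test_that("build_model output is deterministic", {
  fx <- paper_fixture()
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_sbml(build_model(fx$spec, fx$table, with_anti_mirnas = TRUE), f1)
  write_sbml(build_model(fx$spec, fx$table, with_anti_mirnas = TRUE), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("census tabulates by role and reaction class and sums", {
  expect_true(all(census(new_model())$components == 0))
  m <- add_gene_expression_motif(new_model(), "BAD")
  cz <- census(m)
  expect_equal(unname(cz$components[c("gene", "mRNA", "protein", "Sum")]),
               c(1L, 2L, 1L, 4L))
  expect_equal(unname(cz$reactions["Sum"]), 5L)
})

test_that("model invariants reject broken networks", {
  m <- add_gene_expression_motif(new_model(), "BAD")
  # drop the protein decay reaction -> invariant violation
  m$reactions[["decay:BAD-1"]] <- NULL
  expect_error(validate_model(m), "invariant_violation")
})
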