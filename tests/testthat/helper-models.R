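# Shared builders; the fixture model is cached per session because several
# files probe the same steady states.

worked_example_model <- function() {
  m <- new_model()
  m <- add_entity(m, "BAD-1", "protein", "cytoplasm", initial = 1.0)
  m <- add_entity(m, "ATP", "compound", "cytoplasm", initial = 2.0)
  m <- add_entity(m, "P-AKT", "protein", "plasma_membrane", initial = 3.0)
  m <- add_entity(m, "P-BAD-1", "protein", "cytoplasm", initial = 0)
  m <- add_entity(m, "ADP", "compound", "cytoplasm", initial = 0)
  add_reaction(m, "t1", "phosphorylation",
               miRpetri:::arcs_frame(substrates = c("BAD-1", "ATP"),
                                     products = c("P-BAD-1", "ADP"),
                                     enzymes = "P-AKT"),
               flux_override = 0.05)
}

.cache <- new.env(parent = emptyenv())

fx_model <- function(anti = TRUE) {
  key <- paste0("fx_", anti)
  if (is.null(.cache[[key]])) .cache[[key]] <- fixture_model(anti)
  .cache[[key]]
}

fx_compiled <- function(cfg = kinetic_config()) {
  if (is.null(.cache$cmp)) .cache$cmp <- compile_network(fx_model(), cfg)
  .cache$cmp
}

# steady state of the anti-enabled fixture under clamp overrides, cached
fx_ss <- function(overrides = numeric(0), cfg = kinetic_config()) {
  key <- paste0("ss_", paste(names(overrides), overrides,
                             collapse = "|"))
  if (is.null(.cache[[key]])) {
    mod <- fx_model()
    .cache[[key]] <- miRpetri:::ss_clamped(mod, fx_compiled(cfg),
                                           overrides, cfg)
  }
  .cache[[key]]
}

# all-miRNAs-silenced override vector for the fixture
fx_off <- function() {
  mod <- fx_model()
  mg <- miRpetri:::mirna_gene_ids(mod)
  stats::setNames(rep(0, length(mg)), mg)
}

fixture_target_map <- function() miRpetri:::FIXTURE_TARGETS
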