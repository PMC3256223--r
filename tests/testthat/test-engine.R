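we_cfg <- kinetic_config(consume_enzyme = TRUE)

test_that("one step reproduces the printed worked example exactly", {
  m <- worked_example_model()
  cmp <- compile_network(m, we_cfg)
  m1 <- step_marking(cmp, m$initial_marking[cmp$ids], 1, we_cfg)
  expect_identical(unname(m1[c("BAD-1", "ATP", "P-AKT", "P-BAD-1", "ADP")]),
                   c(1.0 - 0.05 - 0.09,
                     2.0 - 0.05 - 0.18,
                     3.0 - 0.05 - 0.27,
                     0.05 - 0.05 * 0.09,
                     0.05 - 0.05 * 0.09))
})

test_that("flux vanishes with any absent substrate or enzyme", {
  m <- worked_example_model()
  r <- m$reactions[["t1"]]
  mk <- m$initial_marking
  expect_gt(transition_flux(r, mk, we_cfg), 0)
  for (sp in c("BAD-1", "ATP", "P-AKT")) {
    mk0 <- mk; mk0[sp] <- 0
    expect_identical(transition_flux(r, mk0, we_cfg), 0)
  }
  expect_error(transition_flux(r, mk[c("BAD-1", "ATP")], we_cfg),
               "missing_place")
})

test_that("flux is non-decreasing in enzyme concentration", {
  m <- new_model()
  m <- add_entity(m, "S", "protein", "cytoplasm")
  m <- add_entity(m, "P", "protein", "cytoplasm")
  m <- add_entity(m, "E", "protein", "cytoplasm")
  m <- add_reaction(m, "r", "phosphorylation",
                    miRpetri:::arcs_frame(substrates = "S", products = "P",
                                          enzymes = "E"))
  r <- m$reactions[["r"]]
  cfg <- kinetic_config()
  for (s in c(0.1, 1, 5)) {
    fl <- vapply(c(0, 0.5, 1, 2, 4, 8),
                 function(e) transition_flux(r, c(S = s, P = 0, E = e), cfg),
                 numeric(1))
    expect_true(all(diff(fl) >= 0))
  }
})

test_that("inhibitor arcs damp the flux by the inhibitory parameter", {
  m <- new_model()
  m <- add_entity(m, "S", "protein", "cytoplasm")
  m <- add_entity(m, "P", "protein", "cytoplasm")
  m <- add_entity(m, "I", "protein", "cytoplasm")
  m <- add_reaction(m, "r", "other",
                    miRpetri:::arcs_frame(substrates = "S", products = "P",
                                          inhibitors = "I"))
  r <- m$reactions[["r"]]
  cfg <- kinetic_config()
  f0 <- transition_flux(r, c(S = 2, P = 0, I = 0), cfg)
  f1 <- transition_flux(r, c(S = 2, P = 0, I = 1), cfg)
  expect_equal(f1, f0 / (1 + 1.5 * 1))
})

test_that("firing_state distinguishes forward, backward and inactive", {
  m <- new_model()
  m <- add_entity(m, "A", "protein", "cytoplasm")
  m <- add_entity(m, "B", "protein", "cytoplasm")
  m <- add_reaction(m, "r", "phosphorylation",
                    miRpetri:::arcs_frame(substrates = "A", products = "B"),
                    reversible = TRUE)
  r <- m$reactions[["r"]]
  cfg <- kinetic_config()
  expect_equal(firing_state(r, c(A = 1, B = 0), cfg), "forward")
  expect_equal(firing_state(r, c(A = 0, B = 1), cfg), "backward")
  expect_equal(firing_state(r, c(A = 0, B = 0), cfg), "inactive")
  r$reversible <- FALSE
  expect_equal(firing_state(r, c(A = 0, B = 1), cfg), "inactive")
})

test_that("fire moves weighted mass and truncates at the supply limit", {
  m <- worked_example_model()
  r <- m$reactions[["t1"]]
  mk <- m$initial_marking
  # at the consumption limit the full flux passes
  m1 <- fire(r, mk, 1.0, we_cfg)
  expect_equal(unname(m1["BAD-1"]), 0)
  expect_equal(unname(m1["P-BAD-1"]), 1.0)
  # above the limit the flux is truncated, never negative
  m2 <- fire(r, mk, 5.0, we_cfg)
  expect_true(all(m2 >= 0))
  expect_equal(unname(m2["P-BAD-1"]), 1.0)
  # zero flux leaves the marking untouched
  expect_identical(fire(r, mk, 0, we_cfg), mk)
})

test_that("complex formation conserves mass of each component", {
  m <- new_model()
  m <- add_entity(m, "A", "miRNA", "cytoplasm", initial = 2)
  m <- add_entity(m, "B", "miRNA", "cytoplasm", initial = 3)
  m <- add_entity(m, "AB", "miRNA", "cytoplasm")
  m <- add_reaction(m, "cf", "complex_formation",
                    miRpetri:::arcs_frame(substrates = c("A", "B"),
                                          products = "AB"))
  cfg <- kinetic_config()
  cmp <- compile_network(m, cfg)
  mk <- m$initial_marking[cmp$ids]
  for (i in 1:20) {
    mk2 <- step_marking(cmp, mk, i, cfg)
    expect_equal(mk2[["A"]] + mk2[["AB"]], mk[["A"]] + mk[["AB"]])
    expect_equal(mk2[["B"]] + mk2[["AB"]], mk[["B"]] + mk[["AB"]])
    mk <- mk2
  }
  # the inert complex accumulates monotonically while both inputs last
  expect_gt(mk[["AB"]], 0)
})

test_that("policy decay follows the closed-form geometric curve", {
  m <- new_model()
  m <- add_entity(m, "X", "protein", "cytoplasm", initial = 5)
  cfg <- kinetic_config()
  cmp <- compile_network(m, cfg)
  mk <- m$initial_marking
  for (i in 1:10) mk <- step_marking(cmp, mk, i, cfg)
  expect_equal(unname(mk["X"]), 5 * (1 - 0.09)^10)
})

test_that("ligand-receptor complexes decay only every tenth step", {
  m <- new_model()
  m <- add_entity(m, "LR", "complex", "plasma_membrane",
                  tags = "ligand_receptor", initial = 1)
  cfg <- kinetic_config()
  cmp <- compile_network(m, cfg)
  mk <- m$initial_marking
  for (i in 1:9) mk <- step_marking(cmp, mk, i, cfg)
  expect_equal(unname(mk["LR"]), 1)
  mk <- step_marking(cmp, mk, 10, cfg)
  expect_equal(unname(mk["LR"]), 0.8)
})

test_that("decay base is the start-of-step concentration for existing species", {
  # a species both produced and decaying in one step: the printed
  # convention subtracts rate * starting concentration
  pol <- list(rate = c(X = 0.1), period = c(X = 1L))
  m_start <- c(X = 2)
  m_post <- c(X = 2.5) # after production
  expect_equal(apply_decay(m_post, 1, pol, m_start), c(X = 2.5 - 0.2))
  # freshly created species decay on their post-fire concentration
  expect_equal(apply_decay(c(X = 0.5), 1, pol, c(X = 0)),
               c(X = 0.5 - 0.05))
})

test_that("clamped species keep their clamp value through any step", {
  mod <- fx_model()
  cfg <- kinetic_config()
  tr <- simulate_model(mod, n_steps = 25, cfg = cfg, record_every = 1)
  for (cl in names(mod$clamps))
    expect_true(all(tr$marking[, cl] == mod$clamps[[cl]]))
})

test_that("markings stay non-negative along the whole trajectory", {
  mod <- fx_model()
  tr <- simulate_model(mod, n_steps = 60, cfg = kinetic_config(),
                       record_every = 1)
  expect_true(all(tr$marking >= 0))
})

test_that("a synchronous step equals sequential firing on disjoint nets", {
  m <- new_model()
  m <- add_entity(m, "A", "miRNA", "cytoplasm", initial = 4)
  m <- add_entity(m, "B", "miRNA", "cytoplasm")
  m <- add_entity(m, "C", "miRNA", "cytoplasm", initial = 2)
  m <- add_entity(m, "D", "miRNA", "cytoplasm")
  m <- add_reaction(m, "r1", "other",
                    miRpetri:::arcs_frame(substrates = "A", products = "B"))
  m <- add_reaction(m, "r2", "other",
                    miRpetri:::arcs_frame(substrates = "C", products = "D"))
  cfg <- kinetic_config()
  cmp <- compile_network(m, cfg)
  mk <- m$initial_marking[cmp$ids]
  sync <- step_marking(cmp, mk, 1, cfg)
  seq_m <- mk
  for (rid in c("r1", "r2")) {
    r <- m$reactions[[rid]]
    seq_m <- fire(r, seq_m, transition_flux(r, mk, cfg), cfg)
  }
  pol <- decay_policy(m, cfg)
  seq_m <- apply_decay(seq_m, 1, pol, mk)
  expect_equal(sync, seq_m[names(sync)])
})

test_that("compiled fluxes agree with per-reaction evaluation", {
  mod <- fx_model()
  cfg <- kinetic_config()
  cmp <- fx_compiled(cfg)
  set.seed(42)
  for (rep in 1:5) {
    mk <- stats::setNames(stats::runif(cmp$np, 0, 2), cmp$ids)
    mk[sample(cmp$np, 20)] <- 0
    fc <- miRpetri:::compiled_flux(cmp, mk, cfg)
    fr <- vapply(mod$reactions, transition_flux, numeric(1), m = mk,
                 cfg = cfg)
    expect_equal(unname(fc), unname(fr), tolerance = 1e-12)
  }
})

test_that("a reaction with a zero substrate never changes the marking", {
  m <- new_model()
  m <- add_entity(m, "A", "miRNA", "cytoplasm", initial = 0)
  m <- add_entity(m, "B", "miRNA", "cytoplasm", initial = 1)
  m <- add_entity(m, "AB", "miRNA", "cytoplasm", initial = 0)
  m <- add_reaction(m, "cf", "complex_formation",
                    miRpetri:::arcs_frame(substrates = c("A", "B"),
                                          products = "AB"))
  cfg <- kinetic_config()
  tr <- simulate_model(m, n_steps = 20, cfg = cfg)
  expect_identical(tr$final, m$initial_marking[names(tr$final)])
})

test_that("trajectories are bit-identical across repeated runs", {
  mod <- fx_model()
  cfg <- kinetic_config()
  t1 <- simulate_model(mod, n_steps = 40, cfg = cfg)
  t2 <- simulate_model(mod, n_steps = 40, cfg = cfg)
  expect_identical(t1$marking, t2$marking)
})

test_that("with all genes silenced every species stays at zero", {
  fx <- paper_fixture()
  fx$spec$gene_level <- 0
  fx$spec$clamps <- list(EGF = 0, ATP = 0, ADP = 0, PIP2 = 0)
  mod <- build_model(fx$spec, fx$table)
  tr <- simulate_model(mod, n_steps = 30, cfg = kinetic_config())
  expect_true(all(tr$marking == 0))
})

test_that("trajectory export round-trips through the wide TSV", {
  mod <- fx_model()
  tr <- simulate_model(mod, n_steps = 10, cfg = kinetic_config(),
                       record_every = 5)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$step, tr$steps)
  expect_equal(as.matrix(back[, -1]), tr$marking, ignore_attr = TRUE)
})
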