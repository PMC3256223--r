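cfg <- kinetic_config()

test_that("the control state is reproducible and self-consistent", {
  mod <- fx_model()
  c1 <- control_state(mod, cfg)
  c2 <- control_state(mod, cfg)
  expect_identical(c1, c2)
  expect_true(all(log2_ratio(c1, c1) == 0))
  # expressed genes drive their proteins above zero at baseline
  prot <- paste0(names(paper_fixture()$spec$genes), "-1")
  expect_true(all(c1[prot] > 0))
})

test_that("over-expression at level zero reproduces the control exactly", {
  mod <- fx_model()
  lr <- overexpression_experiment(mod, "mir-192", 0, cfg = cfg)
  expect_true(all(lr == 0))
})

test_that("over-expression represses all and only direct targets", {
  mod <- fx_model()
  for (m in c("mir-489", "mir-TRDD")) {
    lr <- overexpression_experiment(mod, m, 100, cfg = cfg)
    tg <- paste0("mRNA-", fixture_target_map()[[m]])
    expect_true(all(lr[tg] < -0.001))
    expect_true(all(abs(lr[setdiff(names(lr), tg)]) < 0.001))
  }
})

test_that("a single-level dose scan matches the over-expression state", {
  mod <- fx_model()
  ro <- paste0("mRNA-", fixture_target_map()[["mir-489"]])
  ds <- dose_scan(mod, "mir-489", c(0, 100), readouts = ro, cfg = cfg)
  lr <- overexpression_experiment(mod, "mir-489", 100, readouts = ro,
                                  cfg = cfg)
  expect_equal(log2(unlist(ds[2, ro]) / unlist(ds[1, ro])), lr,
               ignore_attr = TRUE)
  expect_error(dose_scan(mod, "mir-489", 100, readouts = ro, cfg = cfg))
})

test_that("activation threshold returns the sentinel when never active", {
  mod <- fx_model()
  thr <- activation_threshold(mod, "EGFR", c(1e-4, 1e-3), "P-AKT-1",
                              epsilon = 1e6, cfg = cfg)
  expect_identical(thr, Inf)
  expect_error(activation_threshold(mod, "EGFR", c(1, 1), "P-AKT-1",
                                    cfg = cfg))
})

test_that("threshold is non-decreasing in the repressor miRNA level", {
  mod <- fx_model()
  levels <- 10^seq(-4, 0, by = 0.5)
  ro <- fixture_readouts()$akt_dependent
  thr <- vapply(c(0, 0.5, 1), function(lv)
    activation_threshold(mod, "EGFR", levels, ro,
                         keep = c("mir-181c" = lv), cfg = cfg),
    numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("paired t-test matches an independent t-distribution oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 30
    ctrl <- stats::setNames(stats::runif(n, 0, 5), paste0("c", 1:n))
    st <- ctrl + stats::rnorm(n, mean = 0.3, sd = 0.2)
    p <- t_test_p_value(st, ctrl)
    # oracle 1: textbook t CDF
    d <- unname(st - ctrl)
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    expect_equal(p, 2 * stats::pt(-abs(tstat), n - 1), tolerance = 1e-12)
    # oracle 2: stats::t.test
    expect_equal(p, stats::t.test(st, ctrl, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  ctrl <- c(a = 1, b = 2, c = 3)
  expect_identical(t_test_p_value(ctrl, ctrl), 1)
  expect_error(t_test_p_value(c(a = 1), c(b = 1)), "differ")
})

test_that("larger uniform shifts give smaller p at fixed dispersion", {
  set.seed(7)
  n <- 25
  ctrl <- stats::setNames(stats::runif(n, 1, 2), paste0("x", 1:n))
  noise <- stats::rnorm(n, sd = 0.1)
  p <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
              function(shift) t_test_p_value(ctrl + shift + noise, ctrl),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("welch variant agrees with the unpaired unequal-variance test", {
  set.seed(13)
  n <- 20
  ctrl <- stats::setNames(stats::runif(n, 0, 4), paste0("x", 1:n))
  st <- ctrl * 1.4 + stats::rnorm(n, sd = 0.3)
  expect_equal(t_test_p_value(st, ctrl, variant = "welch"),
               stats::t.test(st, ctrl)$p.value, tolerance = 1e-10)
})

test_that("anti-miRNA dose returns direct targets toward the control", {
  mod <- fx_model()
  scr <- anti_mirna_screen(mod, anti_ids = "mir-489",
                           dose_levels = c(0, 1, 10, 100),
                           overexpress_level = 1, cfg = cfg)
  pa <- scr$per_anti[["mir-489"]]
  tg_prot <- paste0(fixture_target_map()[["mir-489"]], "-1")
  lvl <- vapply(pa$states, function(s) min(s[tg_prot]), numeric(1))
  # target protein levels are non-decreasing in inhibitor dose
  expect_true(all(diff(lvl) >= 0))
})

test_that("an anti-miRNA of an unexpressed miRNA changes nothing", {
  mod <- fx_model()
  base <- fx_ss(fx_off(), cfg)
  with_anti <- fx_ss(c(fx_off(), "anti-mir-489" = 50), cfg)
  keep <- setdiff(names(base), c("anti-mir-489",
                                 "mir-489-mat:anti-mir-489"))
  expect_identical(base[keep], with_anti[keep])
})

test_that("screen ranking sorts ascending with lexicographic ties", {
  scr <- structure(list(per_anti = list(
    "mir-b" = list(p_value = 0.01),
    "mir-a" = list(p_value = 0.01),
    "mir-c" = list(p_value = 0.20))), class = "mirpetri_screen")
  rk <- rank_anti_mirnas(scr, alpha = 0.05)
  expect_equal(rk$anti_mirna, c("anti-mir-a", "anti-mir-b", "anti-mir-c"))
  expect_equal(rk$top, c(TRUE, TRUE, FALSE))
  empty <- structure(list(per_anti = list()), class = "mirpetri_screen")
  expect_equal(nrow(rank_anti_mirnas(empty)), 0)
})

test_that("heatmap masking flags but keeps negligible entries", {
  v <- matrix(c(0, 5e-4, -0.2, 0.3), 2, 2,
              dimnames = list(c("a", "b"), c("r1", "r2")))
  h <- heatmap_result(v)
  expect_identical(unname(h$mask), matrix(c(TRUE, TRUE, FALSE, FALSE),
                                          2, 2))
  expect_identical(h$values, v)
})

test_that("target counts also tabulate miRNAs per target", {
  fx <- paper_fixture()
  cnt <- target_count_histogram(fx$table)
  expect_equal(unname(cnt$per_target["TP53"]), 3L) # mir-192/489/34a
  expect_equal(unname(cnt$per_target["DICER1"]), 1L)
  cnt2 <- target_count_histogram(fx$table, mirnas = c("mir-34a", "mir-x"))
  expect_equal(unname(cnt2$per_mirna), c(14L, 0L))
})
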