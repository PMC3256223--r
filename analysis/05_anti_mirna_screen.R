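#!/usr/bin/env Rscript
# The inhibitor studies: (1) anti-mir-489 / anti-mir-34a dose series
# showing restoration of direct and downstream readouts to the control
# state; (2) the full one-at-a-time anti-miRNA screen of the fixture with
# paired t-test ranking and target-count histogram.

library(miRpetri)

dir.create("results", showWarnings = FALSE)
cfg <- kinetic_config()
model <- fixture_model(with_anti_mirnas = TRUE)
fx <- paper_fixture()
ro <- fixture_readouts()

## dose series for the two archetype inhibitors
scr2 <- anti_mirna_screen(model, anti_ids = c("mir-489", "mir-34a"),
                          dose_levels = c(0, 1, 10, 100),
                          overexpress_level = 1, cfg = cfg)
for (m in c("mir-489", "mir-34a")) {
  pa <- scr2$per_anti[[m]]
  tg <- paste0(fx$table$target[fx$table$mirna == m], "-1")
  tab <- do.call(rbind, lapply(names(pa$states), function(d)
    data.frame(dose = as.numeric(d), t(pa$states[[d]][c(tg, ro$actives)]),
               check.names = FALSE)))
  f <- sprintf("results/05_anti_%s_doses.tsv", gsub("-", "_", m))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  top <- pa$states[[length(pa$states)]]
  message(sprintf(
    "anti-%s at %g nM: max |log2 vs miRNA-over-expressed control| on %d readouts = %.3f",
    m, max(scr2$dose_levels), length(c(tg, ro$actives)),
    max(abs(log2_ratio(top, pa$control, c(tg, ro$actives))))))
}

## full screen and ranking
scr <- anti_mirna_screen(model, overexpress_level = 1, cfg = cfg)
rk <- rank_anti_mirnas(scr, alpha = 0.05)
print(rk)
export_ranking(rk, "results/05_anti_mirna_ranking.tsv")
render_heatmap(scr$heatmap, "results/05_screen_heatmap.png",
               main = "anti-miRNA screen: log2 vs over-expressed control")

cnt <- target_count_histogram(fx$table, mirnas = sub("^anti-", "",
                                                     rk$anti_mirna))
message("ranking vs target count (Spearman): ",
        round(suppressWarnings(
          cor(cnt$per_mirna, -log10(rk$p_value), method = "spearman")), 3))
write.table(data.frame(mirna = names(cnt$per_mirna),
                       n_targets = cnt$per_mirna,
                       p_value = rk$p_value, row.names = NULL),
            "results/05_targets_vs_p.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
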