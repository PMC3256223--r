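#!/usr/bin/env Rscript
# Builds the packaged EGFR/miRNA pathway model from the shipped pathway
# specification and curated miRNA-target table, reports its census, and
# exports the network as SBML for downstream stages.

library(miRpetri)

dir.create("results", showWarnings = FALSE)

spec <- read_pathway_spec(system.file("extdata", "egfr_mirna_pathway.yaml",
                                      package = "miRpetri"))
table <- read_target_table(system.file("extdata", "egfr_mirna_targets.tsv",
                                       package = "miRpetri"))
model <- build_model(spec, table, with_anti_mirnas = TRUE)
validate_model(model)

cz <- census(model)
message("model census: ", cz$components[["Sum"]], " entities, ",
        cz$reactions[["Sum"]], " reactions (",
        cz$reactions[["miRNA_binding"]], " miRNA-binding, ",
        cz$components[["pseudo_object"]], " anti-miRNA pseudo-objects)")

census_df <- data.frame(
  class = c(names(cz$components), names(cz$reactions)),
  kind = rep(c("component", "reaction"),
             c(length(cz$components), length(cz$reactions))),
  count = c(cz$components, cz$reactions), row.names = NULL)
write.table(census_df, "results/01_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_sbml(model, "results/01_model.sbml.xml")

cnt <- target_count_histogram(table)
write.table(data.frame(mirna = names(cnt$per_mirna),
                       n_targets = cnt$per_mirna, row.names = NULL),
            "results/01_targets_per_mirna.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("targets per miRNA: ",
        paste(names(cnt$per_mirna), cnt$per_mirna, sep = "=",
              collapse = ", "))

run_manifest(c("results/01_census.tsv", "results/01_model.sbml.xml",
               "results/01_targets_per_mirna.tsv"),
             config = list(stage = "build", fixture = "packaged"),
             "results/01_manifest.json")
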