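#!/usr/bin/env Rscript
# Stage 4: hypergeometric over-representation per polyphenol class
# (BH < 0.1, coverage > 0.1) and the category roll-up, checked against the
# planted pathway.

library(polyphenome)

sim <- "results/sim"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

classified <- read.delim("results/classify/classification.tsv",
                         na.strings = character(0))
classified[is.na(classified)] <- ""
stitch <- filter_interactions(parse_stitch_like(file.path(sim, "stitch.tsv")))
net <- merge_interactions(stitch,
                          parse_sif_like(file.path(sim, "interactions.sif")),
                          parse_bindingdb_like(file.path(sim, "bindingdb.tsv")))
gene_sets <- read_gmt(file.path(sim, "pathways.gmt"))
ontology <- read_pathway_ontology(file.path(sim, "ontology.tsv"))

res <- enrich_by_class(net, classified, gene_sets,
                       alpha = 0.1, min_coverage = 0.1)
write.table(res, file.path(out, "class_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- res[res$significant, c("query_label", "pathway_id", "k", "K",
                              "coverage", "p_bh")]
cat("significant (class, pathway) pairs:\n"); print(sig, row.names = FALSE)

led <- jsonlite::read_json(file.path(sim, "ledger.json"),
                           simplifyVector = TRUE)
pl <- led$pathways$planted_enrichments
target <- pl$query_label[pl$pathway_id == "pw_0001"]
cat("planted pathway pw_0001 (class", target, ") recovered:",
    any(sig$query_label == target & sig$pathway_id == "pw_0001"), "\n")

cs <- category_summary(res, ontology)
write.table(cs$percent, file.path(out, "category_percent.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cs$coverage, file.path(out, "category_coverage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("categories with a significant pathway:\n")
print(cs$percent[cs$percent$n_significant > 0, ], row.names = FALSE)
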