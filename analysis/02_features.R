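#!/usr/bin/env Rscript
# Extract the per-individual-per-task feature table (individual speech
# features + dyadic interactional features) from the synthetic corpus and
# check that the planted group effects come out with the planted signs.
# Writes results/feature_table.csv and results/planted_effect_recovery.csv.

suppressPackageStartupMessages(library(dyadsync))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 1L)
corp <- generate_corpus(cfg)
cat("Extracting features for", length(corp$records), "conversations ...\n")
ft <- compute_feature_table(corp$records)
write_feature_table(ft, "results/feature_table.csv")

rec <- planted_effect_report(corp$truth, ft)
write.csv(rec, "results/planted_effect_recovery.csv", row.names = FALSE)
cat("Planted-effect recovery (standardised differences):\n")
print(rec, digits = 3)
ok <- all(rec$sign == c(-1, -1, -1, 1, 1, 1))
cat(if (ok) "All planted effect directions recovered.\n" else
    "WARNING: at least one planted effect came out with the wrong sign.\n")
cat("Wrote results/feature_table.csv and",
    "results/planted_effect_recovery.csv\n")
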