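#!/usr/bin/env Rscript
# Step 2 — synthetic validation corpora.
#
# Generates two 5000-chain corpora from the road-transport scenario model:
# one with the planted second-order dependency (a collision reached from a
# slippery road overwhelmingly rolls the vehicle over) and a null variant
# with the identical first-order backbone and no dependency. Both are
# written as plain chain files for the next steps.

suppressPackageStartupMessages(library(honcausal))

seed <- 2026L
out <- "results/chains"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (kind in c("planted", "null")) {
  model <- example_chain_model(planted = kind == "planted")
  chains <- generate_chains(model, n_chains = 5000, seed = seed)
  path <- file.path(out, paste0(kind, "_chains.txt"))
  write_chains(chains, path)
  message(sprintf("%s corpus: %d chains, %d transitions -> %s", kind,
                  length(chains), sum(lengths(chains) - 1L), path))
}
write_chain_model(example_chain_model(TRUE),
                  file.path(out, "planted_model.yaml"))
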