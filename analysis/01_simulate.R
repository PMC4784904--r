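#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Builds the default 590-gene study: 500 host genes, 30 ancient and 20
# recent transfers interleaved on long contigs, 40 symbiont genes alone on
# short contigs, plus every table the screen consumes (protein and
# nucleotide search results, taxon map, expression, GO annotations,
# external gene-family flags) and the truth table used to score recovery.

suppressPackageStartupMessages(library(alienscreen))

seed <- as.integer(Sys.getenv("ALIENSCREEN_SEED", "1"))
out <- "results/sim"

params <- simulation_params(seed = seed)
sim <- simulate_all(params)
write_simulation(sim, out, pipeline_config(seed = seed))

cat(sprintf("Simulated %d genes on %d contigs (%.2f Mb) with seed %d\n",
            nrow(sim$genome$genes), length(sim$genome$contigs),
            sum(Biostrings::width(sim$genome$contigs)) / 1e6, seed))
print(table(sim$genome$truth$class))
cat(sprintf("Wrote study to %s/\n", out))
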