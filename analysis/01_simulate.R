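#!/usr/bin/env Rscript
# Stage 1: generate the full synthetic input bundle.
#
# Emulated study design: a two-replicon marine bacterial genome with 69
# cis- and 30 trans-encoded sRNAs planted among 500 genes; negative-binomial
# counts for 3 C-limited vs 3 N-limited chemostat replicates with 14/99
# sRNAs differentially expressed; strand-specific 50 nt read coverage; a
# directed metabolic network in which sRNA-target genes carry a 20%
# connectivity deficit; and an 8-standard gel ladder with gamma noise.

suppressPackageStartupMessages(library(srnapipe))

cfg <- simulation_config(seed = 1)
ds <- simulate_dataset(cfg)
paths <- write_dataset(ds, "results/inputs")

tr <- ds$truth$srnas
message(sprintf("genome: %s bp over %d replicons, %d genes",
                format(sum(cfg$replicon_lengths), big.mark = ","),
                length(cfg$replicon_lengths), nrow(ds$annotation$genes)))
message(sprintf("planted sRNAs: %d cis, %d trans, sizes %d-%d nt",
                sum(tr$mode == "cis"), sum(tr$mode == "trans"),
                min(tr$size), max(tr$size)))
message(sprintf("planted DE: %d sRNAs, %d genes",
                sum(ds$truth$features$log2fc != 0 &
                      ds$truth$features$type == "srna"),
                sum(ds$truth$features$log2fc != 0 &
                      ds$truth$features$type == "gene")))
message(sprintf("network: %d nodes (%d targets), %d edges",
                nrow(ds$network$network$nodes),
                sum(ds$network$network$nodes$is_target),
                nrow(ds$network$network$edges)))
message("inputs written under results/inputs/")
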