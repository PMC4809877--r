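#!/usr/bin/env Rscript
# Stage 5: connectedness of cis-sRNA target genes in the directed metabolic
# network: degree comparison, the dyadic-independent edge-probability model
# (edges + node-covariate ERGM, exact logistic MLE), and network-membership
# proportions with a two-proportion Z-test.

suppressPackageStartupMessages(library(srnapipe))

ann <- read_gff3("results/inputs/annotation.gff3")
calls <- tibble::as_tibble(read.delim("results/srna_calls.tsv"))
net <- build_network("results/inputs/network_edges.tsv",
                     "results/inputs/network_targets.txt")
targets <- unique(calls$antisense_locus[calls$mode == "cis"])

deg <- degree_summary(net)
fit <- fit_edge_model(net)
mem <- membership_proportions(ann, targets, net)

message(sprintf("degrees: targets %.2f vs others %.2f (deficit %.0f%%)",
                deg$mean_degree_target, deg$mean_degree_nontarget,
                100 * deg$relative_deficit))
message(sprintf("edge model: theta_target = %.3f (SE %.3f)",
                fit$theta_target, fit$se_target))
message(sprintf("  tie probability at one target endpoint / baseline = %.2f",
                fit$tie_prob_ratio))
message(sprintf("membership: %.0f%% of targets vs %.0f%% of all genes in the network (z = %.2f, p = %.3g)",
                100 * mem$prop_targets_in_network,
                100 * mem$prop_genes_in_network, mem$z, mem$p))
jsonlite::write_json(
  list(degrees = deg,
       ergm = fit[c("theta_edges", "theta_target", "se_edges", "se_target",
                    "tie_prob_ratio", "loglik")],
       membership = mem),
  "results/network.json", auto_unbox = TRUE, digits = NA)
message("results written to results/network.json")
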