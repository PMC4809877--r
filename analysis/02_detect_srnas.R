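#!/usr/bin/env Rscript
# Stage 2: call sRNAs from strand-specific coverage.
#
# Expressed intervals (depth >= 5, gaps <= 25 nt merged, 50-700 nt) are
# called per strand, 5'-UTR-like candidates dropped, and the remainder
# classified as cis (antisense to a gene) or trans (intergenic). Calls are
# compared against the planted truth.

suppressPackageStartupMessages(library(srnapipe))

ann <- read_gff3("results/inputs/annotation.gff3")
cov <- read_bedgraph_pair("results/inputs/coverage_plus.bedGraph",
                          "results/inputs/coverage_minus.bedGraph", ann)
calls <- detect_srnas(cov, ann)

truth <- jsonlite::fromJSON("results/inputs/truth.json")
calls <- match_calls_to_features(calls, truth$srnas)
write.table(calls, "results/srna_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("called %d sRNAs: %d cis, %d trans", nrow(calls),
                sum(calls$mode == "cis"), sum(calls$mode == "trans")))
message(sprintf("planted sRNAs recovered: %d / %d",
                length(intersect(calls$feature, truth$srnas$id)),
                nrow(truth$srnas)))
message(sprintf("median |boundary error|: %d nt", {
  i <- match(calls$feature, truth$srnas$id)
  ok <- !is.na(i)
  as.integer(median(abs(calls$start[ok] - truth$srnas$start[i[ok]])))
}))
message("calls written to results/srna_calls.tsv")
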