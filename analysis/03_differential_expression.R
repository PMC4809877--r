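#!/usr/bin/env Rscript
# Stage 3: test every feature (genes and sRNAs together, so the trimmed-mean
# normalization can assume most features unchanged) for differential
# expression between C and N limitation with the exact negative-binomial
# test, then summarize the regulated sRNA set.

suppressPackageStartupMessages(library(srnapipe))

cm <- read_count_matrix("results/inputs/counts.tsv",
                        "results/inputs/samples.tsv")
de <- run_diffexp(cm)
write.table(de, "results/diffexp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- jsonlite::fromJSON("results/inputs/truth.json")
is_srna <- de$feature %in% truth$srnas$id
called <- de$q <= 0.05
message(sprintf("features tested: %d (%d sRNAs, %d genes)", nrow(de),
                sum(is_srna), sum(!is_srna)))
message(sprintf("differentially expressed at q <= 0.05: %d sRNAs, %d genes",
                sum(called & is_srna, na.rm = TRUE),
                sum(called & !is_srna, na.rm = TRUE)))
planted <- truth$features$feature[truth$features$log2fc != 0]
message(sprintf("of the called sRNAs, %d are planted effects",
                sum(de$feature[called & is_srna] %in% planted, na.rm = TRUE)))
up <- sum(called & is_srna & de$log2fc > 0, na.rm = TRUE)
message(sprintf("%d of the regulated sRNAs are higher under C limitation", up))
message("results written to results/diffexp.tsv")
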