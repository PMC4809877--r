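#!/usr/bin/env Rscript
# Stage 4: assign each cis-sRNA its antisense target, write the report
# table, and test whether sRNA and target fold-changes co-vary by regressing
# target on sRNA log2 fold-change and comparing the observed F statistic to
# a null built from 10,000 random re-pairings. Also demonstrates the
# seed-complementarity trans-target screen on a few sRNAs.

suppressPackageStartupMessages(library(srnapipe))

ann <- read_gff3("results/inputs/annotation.gff3")
calls <- tibble::as_tibble(read.delim("results/srna_calls.tsv"))
de <- tibble::as_tibble(read.delim("results/diffexp.tsv"))

cis_targets <- assign_cis_targets(calls, ann)
de_calls <- de[match(calls$feature, de$feature), ]
de_calls$feature <- calls$id
de_calls <- de_calls[!is.na(calls$feature), ]
write_srna_table(calls, de_calls, cis_targets, "results/srna_table.tsv")

pairs <- pair_fold_changes(calls, cis_targets,
                           dplyr::bind_rows(de_calls, de))
reg <- fit_fc_regression(pairs)
null <- bootstrap_f_null(pairs, n_iter = 10000, seed = 1)
message(sprintf("fold-change regression over %d cis-sRNA/target pairs:",
                reg$n))
message(sprintf("  slope %.2f, R^2 %.2f, F(1, %d) = %.1f",
                reg$slope, reg$r2, reg$df[2], reg$f))
message(sprintf("  re-pairing null: median F %.2f, empirical p %.4f",
                null$median_f, null$p_emp))
jsonlite::write_json(
  list(regression = reg[c("n", "intercept", "slope", "r2", "f")],
       null = list(n_iter = null$n_iter, seed = null$seed,
                   median_f = null$median_f, p_emp = null$p_emp)),
  "results/regression.json", auto_unbox = TRUE, digits = NA)

# trans-target screen for the three longest trans calls against the
# megaplasmid gene set (synthetic genome sequence: random GC-rich DNA, so
# hits reflect the null, not biology)
genome <- random_genome_sequence(ann, seed = 1)
pla <- names(ann$replicons)[length(ann$replicons)]
ann_screen <- genome_annotation(ann$replicons,
                                ann$genes[ann$genes$replicon == pla, ])
trans <- calls[calls$mode == "trans", ]
trans <- trans[order(-trans$size), ][seq_len(min(3, nrow(trans))), ]
screen <- dplyr::bind_rows(lapply(seq_len(nrow(trans)), function(i) {
  srna_seq <- substr(genome[[trans$replicon[i]]], trans$start[i] + 1,
                     trans$end[i])
  hits <- predict_trans_targets(srna_seq, ann_screen, genome,
                                n_shuffles = 100, seed = 100 + i)
  if (nrow(hits)) cbind(srna_id = trans$id[i], hits) else NULL
}))
message(sprintf(
  "trans screen: %d predictions at p < 0.01 (%d sRNAs x %d gene windows)",
  if (is.null(screen)) 0L else nrow(screen), nrow(trans),
  nrow(ann_screen$genes)))
if (!is.null(screen) && nrow(screen))
  write.table(screen, "results/trans_targets.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
message("report in results/srna_table.tsv, regression in results/regression.json")
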