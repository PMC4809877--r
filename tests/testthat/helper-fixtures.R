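# shared fixture builders; everything is generated in code

toy_annotation <- function() {
  genome_annotation(
    c(chr = 2000, pla = 800),
    tibble::tibble(
      locus_tag = c("G1", "G2", "G3"),
      replicon = c("chr", "chr", "pla"),
      start = c(500L, 1200L, 100L),
      end = c(900L, 1600L, 400L),
      strand = c("+", "-", "+"),
      product = c("ABC transporter, permease", "hypothetical protein",
                  "acetate kinase"),
      category = c("Transport", NA, "Energy production")))
}

# paint a rectangular depth block, 0-based half-open
paint <- function(cov, replicon, strand, start, end, depth) {
  cov[[replicon]][[strand]][(start + 1):end] <-
    cov[[replicon]][[strand]][(start + 1):end] + depth
  cov
}

# a small, fast simulation configuration
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 60,
         replicon_lengths = c(chr = 100000, pla = 30000),
         n_cis_srnas = 8, n_trans_srnas = 4),
    list(...))
  do.call(simulation_config, args)
}

random_pairs <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(srna_log2fc = rnorm(n), target_log2fc = rnorm(n))
}
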