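#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generator. Defaults
#' emulate the study design the pipeline is aimed at: a two-replicon marine
#' alphaproteobacterial genome carrying 69 cis- and 30 trans-encoded sRNAs of
#' 101-562 nt, sequenced as 3 vs 3 replicates under C vs N limitation with
#' 50 nt reads, with 14/99 of sRNAs (and 10% of genes) differentially
#' expressed, target genes about 20% less connected in the metabolic network,
#' and an 8-standard electrophoresis ladder with gamma noise.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so a fixed seed gives bit-identical output.
#' @param replicon_lengths Named vector of replicon lengths (bp). The toy
#'   genome is deliberately smaller than a real 4.6 Mb genome so that
#'   full-pipeline runs stay desk-scale; densities are kept realistic.
#' @param n_genes Number of protein-coding genes to place.
#' @param gene_length_range,gene_gap_range Gene length and intergenic gap
#'   ranges (bp), sampled uniformly.
#' @param n_cis_srnas,n_trans_srnas Numbers of planted antisense and
#'   intergenic sRNAs.
#' @param srna_size_range Planted sRNA sizes (nt), sampled uniformly.
#' @param intergenic_margin Minimum distance (bp) between a planted trans
#'   sRNA and any gene boundary, so planted trans sRNAs are never UTR-like.
#' @param n_replicates_per_condition Replicates per condition.
#' @param conditions Two condition labels; the first is the numerator of all
#'   fold-changes.
#' @param de_fraction Fraction of sRNAs with planted differential expression.
#' @param prop_up_in_first Of the DE sRNAs, fraction higher under the first
#'   condition.
#' @param gene_de_fraction Fraction of genes with planted DE (sign 50/50).
#' @param cis_coupling_slope,cis_coupling_sd Genes hosting a cis sRNA get
#'   `log2fc = slope x sRNA log2fc + N(0, sd)`, emulating sRNAs that act
#'   predominantly as positive regulators of their antisense transcript; set
#'   the slope to 0 for independent fold-changes.
#' @param planted_log2fc_range Magnitude range of planted log2 fold-changes.
#' @param dispersion_range Per-feature NB dispersion, log-uniform.
#' @param gene_expression_range,srna_expression_range Base mean counts per
#'   replicate, log-uniform.
#' @param libsize_factor_range Per-sample library-size factors, uniform.
#' @param read_length Read length (nt) used to lay counts down as coverage.
#' @param background_rate Poisson background depth per base per strand.
#' @param network_fraction,target_network_fraction Probability that a
#'   non-target (resp. sRNA-target) gene is a node of the metabolic network.
#' @param network_mean_degree Expected total degree of a baseline node.
#' @param network_degree_deficit Relative tie-odds reduction for dyads
#'   incident to a target node; applied on the log-odds scale, so the
#'   generator is the exact twin of the edge model fitted by
#'   [fit_edge_model()].
#' @param ladder_sizes Ladder standard sizes (nt).
#' @param ladder_b0,ladder_b1 True inverse-link coefficients: mean size =
#'   1 / (b0 + b1 * distance).
#' @param ladder_shape Gamma shape of ladder size noise (`Inf` = noiseless).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              replicon_lengths = c(chromosome = 600000,
                                                   megaplasmid = 150000),
                              n_genes = 500,
                              gene_length_range = c(400, 1200),
                              gene_gap_range = c(150, 800),
                              n_cis_srnas = 69,
                              n_trans_srnas = 30,
                              srna_size_range = c(101, 562),
                              intergenic_margin = 80,
                              n_replicates_per_condition = 3,
                              conditions = c("C", "N"),
                              de_fraction = 14 / 99,
                              prop_up_in_first = 10 / 14,
                              gene_de_fraction = 0.10,
                              cis_coupling_slope = 0.5,
                              cis_coupling_sd = 0.6,
                              planted_log2fc_range = c(1, 2.5),
                              dispersion_range = c(0.05, 0.3),
                              gene_expression_range = c(20, 500),
                              srna_expression_range = c(20, 2000),
                              libsize_factor_range = c(0.7, 1.4),
                              read_length = 50,
                              background_rate = 0.05,
                              network_fraction = 0.39,
                              target_network_fraction = 0.22,
                              network_mean_degree = 8,
                              network_degree_deficit = 0.20,
                              ladder_sizes = c(100, 150, 200, 300, 400,
                                               500, 700, 1000),
                              ladder_b0 = 5e-4,
                              ladder_b1 = 9e-4,
                              ladder_shape = 50) {
  cfg <- as.list(environment())
  abort_if(n_genes <= 0 || n_replicates_per_condition <= 0,
           "counts must be > 0")
  abort_if(de_fraction < 0 || de_fraction > 1, "de_fraction must be in [0,1]")
  abort_if(srna_size_range[1] < 50 || srna_size_range[2] > 1000 ||
             srna_size_range[1] >= srna_size_range[2],
           "srna_size_range must be an increasing interval within [50, 1000]")
  abort_if(network_degree_deficit < 0 || network_degree_deficit >= 1,
           "network_degree_deficit must be in [0, 1)")
  abort_if(length(conditions) != 2, "exactly two conditions")
  abort_if(read_length < 1, "read_length must be >= 1")
  structure(cfg, class = "simulation_config")
}

gene_product_pool <- function() {
  tibble::tibble(
    product = c("hypothetical protein", "ABC transporter, permease",
                "ABC transporter, ATP-binding protein",
                "ABC transporter, periplasmic substrate-binding protein",
                "sensor histidine kinase", "response regulator",
                "LysR family transcriptional regulator",
                "acetate kinase", "flagellar hook protein",
                "glyoxalase family protein",
                "S-adenosylmethionine synthetase",
                "type I secretion target repeat protein"),
    category = c(NA, "Transport", "Transport", "Transport",
                 "Signal transduction", "Signal transduction",
                 "Transcriptional regulation", "Energy production",
                 "Motility", "Resistance", "Amino acid metabolism",
                 "Cell-cell interaction"),
    weight = c(8, 2, 2, 2, 1.5, 1.5, 2, 1, 1, 1, 1, 1))
}

#' Generate a toy annotated genome with planted sRNAs
#'
#' Places non-overlapping genes along each replicon (alternating gaps), then
#' plants cis sRNAs strictly inside gene bodies on the opposite strand and
#' trans sRNAs in intergenic gaps at least `intergenic_margin` bp from any
#' gene boundary (in particular from same-strand gene starts, so they cannot
#' be mistaken for 5' UTRs). Expression means, dispersions and planted log2
#' fold-changes for every feature are recorded in the truth set.
#'
#' @param config A [simulation_config()].
#' @return A list with `annotation` (a [genome_annotation()]) and `truth`, a
#'   list holding `srnas` (planted calls) and `features` (per-feature mean,
#'   dispersion, true log2fc).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed + 1L)
  pool <- gene_product_pool()
  lens <- config$replicon_lengths
  n_per <- setNames(pmax(1L, round(config$n_genes * lens / sum(lens))),
                    names(lens))
  n_per[1] <- config$n_genes - sum(n_per[-1])

  genes <- list(); gaps <- list()
  gi <- 0L
  for (r in names(lens)) {
    cursor <- 0
    placed <- 0L
    while (placed < n_per[[r]]) {
      gap <- round(runif(1, config$gene_gap_range[1], config$gene_gap_range[2]))
      len <- round(runif(1, config$gene_length_range[1],
                         config$gene_length_range[2]))
      g_start <- cursor + gap
      g_end <- g_start + len
      abort_if(g_end > lens[[r]] - config$gene_gap_range[1],
               "infeasible packing: replicon %s cannot hold %d genes", r,
               n_per[[r]])
      gi <- gi + 1L
      placed <- placed + 1L
      k <- sample.int(nrow(pool), 1, prob = pool$weight)
      genes[[gi]] <- tibble::tibble(
        locus_tag = sprintf("SYN%04d", gi), replicon = r,
        start = as.integer(g_start), end = as.integer(g_end),
        strand = sample(c("+", "-"), 1),
        product = pool$product[k], category = pool$category[k])
      gaps[[gi]] <- tibble::tibble(replicon = r, start = cursor,
                                   end = g_start)
      cursor <- g_end
    }
  }
  genes <- dplyr::bind_rows(genes)
  gaps <- dplyr::bind_rows(gaps)
  annotation <- genome_annotation(lens, genes)

  srnas <- list()
  # cis: strictly inside a gene body, opposite strand
  pad <- 5L
  eligible <- which(genes$end - genes$start >=
                      config$srna_size_range[1] + 2 * pad)
  abort_if(length(eligible) < config$n_cis_srnas,
           "infeasible packing: only %d genes can host a cis sRNA",
           length(eligible))
  host <- sample(eligible, config$n_cis_srnas)
  for (i in seq_along(host)) {
    g <- genes[host[i], ]
    smax <- min(config$srna_size_range[2], g$end - g$start - 2 * pad)
    size <- round(runif(1, config$srna_size_range[1], smax))
    start <- round(runif(1, g$start + pad, g$end - pad - size))
    srnas[[length(srnas) + 1L]] <- tibble::tibble(
      id = sprintf("cis%d", i), replicon = g$replicon,
      start = as.integer(start), end = as.integer(start + size),
      strand = ifelse(g$strand == "+", "-", "+"), size = as.integer(size),
      mode = "cis", antisense_locus = g$locus_tag)
  }
  # trans: inside an intergenic gap, margin away from any gene boundary
  m <- config$intergenic_margin
  gaps$room <- gaps$end - gaps$start - 2 * m
  open <- which(gaps$room >= config$srna_size_range[1])
  abort_if(length(open) < config$n_trans_srnas,
           "infeasible packing: only %d gaps can host a trans sRNA",
           length(open))
  picked <- sample(open, config$n_trans_srnas,
                   prob = gaps$room[open] / sum(gaps$room[open]))
  for (i in seq_along(picked)) {
    gp <- gaps[picked[i], ]
    smax <- min(config$srna_size_range[2], gp$room)
    size <- round(runif(1, config$srna_size_range[1], smax))
    start <- round(runif(1, gp$start + m, gp$end - m - size))
    srnas[[length(srnas) + 1L]] <- tibble::tibble(
      id = sprintf("trans%d", i), replicon = gp$replicon,
      start = as.integer(start), end = as.integer(start + size),
      strand = sample(c("+", "-"), 1), size = as.integer(size),
      mode = "trans", antisense_locus = NA_character_)
  }
  srnas <- dplyr::bind_rows(srnas)
  if (nrow(srnas) == 0)
    srnas <- tibble::tibble(id = character(), replicon = character(),
                            start = integer(), end = integer(),
                            strand = character(), size = integer(),
                            mode = character(), antisense_locus = character())

  features <- plant_expression(genes, srnas, config)
  list(annotation = annotation,
       truth = list(srnas = srnas, features = features, config = config))
}

# draw per-feature expression mean, dispersion and planted log2fc
plant_expression <- function(genes, srnas, config) {
  runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
  feat <- tibble::tibble(
    feature = c(genes$locus_tag, srnas$id),
    type = rep(c("gene", "srna"), c(nrow(genes), nrow(srnas))),
    mean = c(runif_log(nrow(genes), config$gene_expression_range),
             runif_log(nrow(srnas), config$srna_expression_range)),
    dispersion = runif_log(nrow(genes) + nrow(srnas),
                           config$dispersion_range),
    log2fc = 0)
  draw_fc <- function(n, p_up) {
    mag <- runif(n, config$planted_log2fc_range[1],
                 config$planted_log2fc_range[2])
    n_up <- round(p_up * n)
    mag * sample(rep(c(1, -1), c(n_up, n - n_up)))
  }
  is_srna <- feat$type == "srna"
  n_de_s <- round(config$de_fraction * sum(is_srna))
  if (n_de_s > 0) {
    idx <- sample(which(is_srna), n_de_s)
    feat$log2fc[idx] <- draw_fc(n_de_s, config$prop_up_in_first)
  }
  n_de_g <- round(config$gene_de_fraction * sum(!is_srna))
  if (n_de_g > 0) {
    idx <- sample(which(!is_srna), n_de_g)
    feat$log2fc[idx] <- draw_fc(n_de_g, 0.5)
  }
  # genes hosting a cis sRNA co-vary with it (antisense co-regulation)
  host <- srnas[srnas$mode == "cis", ]
  if (nrow(host) > 0 && config$cis_coupling_slope != 0) {
    srna_fc <- feat$log2fc[match(host$id, feat$feature)]
    feat$log2fc[match(host$antisense_locus, feat$feature)] <-
      config$cis_coupling_slope * srna_fc +
      rnorm(nrow(host), 0, config$cis_coupling_sd)
  }
  feat
}

#' Simulate a negative-binomial count matrix
#'
#' Each feature x sample count is drawn from a negative binomial with mean
#' `mean * libfactor * 2^(+/- log2fc / 2)` (so the planted fold-change
#' between conditions is `2^log2fc`, first condition over second) and the
#' feature's dispersion. Dispersion 0 degenerates to Poisson.
#'
#' @param truth Truth set from [generate_genome()].
#' @param config A [simulation_config()].
#' @return A [count_matrix()]; sample library factors are kept in
#'   `attr(, "lib_factors")`.
#' @export
simulate_counts <- function(truth, config) {
  set.seed(config$seed + 2L)
  feat <- truth$features
  abort_if(!all(is.finite(feat$mean)) || !all(is.finite(feat$dispersion)),
           "non-finite feature mean or dispersion")
  nrep <- config$n_replicates_per_condition
  condition <- rep(config$conditions, each = nrep)
  samples <- paste0(condition, rep(seq_len(nrep), 2))
  sf <- runif(length(samples), config$libsize_factor_range[1],
              config$libsize_factor_range[2])
  shift <- ifelse(condition == config$conditions[1], 0.5, -0.5)
  counts <- matrix(0L, nrow(feat), length(samples),
                   dimnames = list(feat$feature, samples))
  for (j in seq_along(samples)) {
    mu <- feat$mean * sf[j] * 2^(feat$log2fc * shift[j])
    y <- ifelse(feat$dispersion < 1e-12,
                rpois(nrow(feat), mu),
                rnbinom(nrow(feat), mu = mu, size = 1 / feat$dispersion))
    counts[, j] <- as.integer(y)
  }
  cm <- count_matrix(counts, factor(condition, levels = config$conditions))
  attr(cm, "lib_factors") <- setNames(sf, samples)
  cm
}

#' Lay counts down as strand-specific read coverage
#'
#' Pools each feature's counts across samples and realizes them as reads of
#' the configured length placed uniformly within the feature on its strand
#' (reads are truncated to the feature when it is shorter than a read).
#' Poisson background depth is added on both strands.
#'
#' @param truth Truth set from [generate_genome()] (gene coordinates are
#'   taken from `annotation`).
#' @param annotation The matching [genome_annotation()].
#' @param counts A [count_matrix()] over the truth features.
#' @param config A [simulation_config()].
#' @return A `strand_coverage` object.
#' @export
simulate_coverage <- function(truth, annotation, counts, config) {
  set.seed(config$seed + 3L)
  loci <- dplyr::bind_rows(
    tibble::tibble(feature = annotation$genes$locus_tag,
                   replicon = annotation$genes$replicon,
                   start = annotation$genes$start, end = annotation$genes$end,
                   strand = annotation$genes$strand),
    tibble::tibble(feature = truth$srnas$id, replicon = truth$srnas$replicon,
                   start = truth$srnas$start, end = truth$srnas$end,
                   strand = truth$srnas$strand))
  n_reads <- rowSums(counts$counts)[loci$feature]
  abort_if(anyNA(n_reads), "counts missing for some located features")
  cov <- strand_coverage(annotation)
  rl <- config$read_length
  starts <- rep(loci$start, n_reads)
  ends <- rep(loci$end, n_reads)
  width <- pmin(rl, ends - starts)
  s <- floor(runif(length(starts), starts, ends - width + 1))
  key <- rep(paste(loci$replicon, loci$strand), n_reads)
  for (r in names(cov)) {
    L <- length(cov[[r]][["+"]])
    for (st in c("+", "-")) {
      sel <- key == paste(r, st)
      depth <- numeric(L)
      if (any(sel))
        depth <- as.numeric(IRanges::coverage(
          IRanges::IRanges(start = s[sel] + 1L, width = width[sel]),
          width = L))
      if (config$background_rate > 0)
        depth <- depth + rpois(L, config$background_rate)
      cov[[r]][[st]] <- depth
    }
  }
  cov
}

#' Simulate a directed metabolic network with a target-connectivity deficit
#'
#' Genes enter the network with probability `network_fraction`
#' (`target_network_fraction` for sRNA-target genes). Each ordered dyad of
#' distinct nodes carries a tie independently with log-odds
#' `theta_edges + theta_target * (is_target(i) + is_target(j))` where
#' `theta_target = log(1 - network_degree_deficit)`: the generative twin of
#' the model fitted by [fit_edge_model()].
#'
#' @param annotation A [genome_annotation()].
#' @param target_set Character vector of target gene locus tags.
#' @param config A [simulation_config()].
#' @return A list with `network` (a [metabolic_network()]) and the true
#'   coefficients `theta_edges`, `theta_target`.
#' @export
simulate_network <- function(annotation, target_set, config) {
  abort_if(config$network_degree_deficit >= 1, "deficit must be < 1")
  set.seed(config$seed + 4L)
  genes <- annotation$genes$locus_tag
  abort_if(!all(target_set %in% genes), "target_set outside annotation")
  is_t <- genes %in% target_set
  p_in <- ifelse(is_t, config$target_network_fraction,
                 config$network_fraction)
  nodes <- genes[runif(length(genes)) < p_in]
  abort_if(length(nodes) < 3, "network too small; raise network_fraction")
  node_t <- nodes %in% target_set
  n <- length(nodes)
  theta_target <- log(1 - config$network_degree_deficit)
  p0 <- config$network_mean_degree / (2 * (n - 1))
  abort_if(p0 <= 0 || p0 >= 1, "network_mean_degree infeasible for %d nodes", n)
  theta_edges <- log(p0 / (1 - p0))
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, ]
  eta <- theta_edges + theta_target * (node_t[ij$i] + node_t[ij$j])
  tie <- rbinom(nrow(ij), 1, plogis(eta)) == 1
  edges <- tibble::tibble(source = nodes[ij$i[tie]],
                          target = nodes[ij$j[tie]])
  net <- metabolic_network(edges, target_set = target_set,
                           nodes = nodes)
  list(network = net, theta_edges = theta_edges, theta_target = theta_target)
}

#' Simulate an electrophoresis ladder
#'
#' For each standard size s, the migration distance is placed on the true
#' inverse-link curve (`mean size = 1 / (b0 + b1 * distance)`) and the
#' observed size is drawn from a gamma distribution with that mean and the
#' configured shape, mimicking band-measurement noise.
#'
#' @param config A [simulation_config()].
#' @return A list with `ladder` (tibble `size_nt`, `distance`) and the true
#'   `b0`, `b1`, `shape`.
#' @export
simulate_ladder <- function(config) {
  set.seed(config$seed + 5L)
  s <- config$ladder_sizes
  abort_if(length(s) == 0 || any(s <= 0), "ladder_sizes must be positive")
  d <- (1 / s - config$ladder_b0) / config$ladder_b1
  abort_if(any(d <= 0) || any(1 / s <= 0),
           "ladder coefficients imply non-positive mean over the size range")
  obs <- if (is.infinite(config$ladder_shape)) s else
    rgamma(length(s), shape = config$ladder_shape,
           rate = config$ladder_shape / s)
  list(ladder = tibble::tibble(size_nt = obs, distance = d),
       b0 = config$ladder_b0, b1 = config$ladder_b1,
       shape = config$ladder_shape)
}

#' Simulate a complete input bundle
#'
#' Runs every generator in sequence from one seeded configuration: genome and
#' planted sRNAs, NB counts, strand-specific coverage, metabolic network
#' (target set = genes antisense to the planted cis sRNAs), and ladder.
#'
#' @param config A [simulation_config()].
#' @return A list with `annotation`, `truth`, `counts`, `coverage`,
#'   `network` (with true coefficients), `ladder`, and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  g <- generate_genome(config)
  counts <- simulate_counts(g$truth, config)
  coverage <- simulate_coverage(g$truth, g$annotation, counts, config)
  targets <- unique(g$truth$srnas$antisense_locus)
  targets <- targets[!is.na(targets)]
  network <- simulate_network(g$annotation, targets, config)
  ladder <- simulate_ladder(config)
  list(annotation = g$annotation, truth = g$truth, counts = counts,
       coverage = coverage, network = network, ladder = ladder,
       config = config)
}

#' Write a simulated bundle to disk in the pipeline's exchange formats
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gff3(dataset$annotation, p("annotation.gff3"))
  write_bedgraph_pair(dataset$coverage, p("coverage_plus.bedGraph"),
                      p("coverage_minus.bedGraph"))
  write_count_matrix(dataset$counts, p("counts.tsv"), p("samples.tsv"))
  write_edge_list(dataset$network$network$edges, p("network_edges.tsv"))
  writeLines(dataset$network$network$nodes$gene[
    dataset$network$network$nodes$is_target], p("network_targets.txt"))
  write_ladder(dataset$ladder$ladder, p("ladder.tsv"))
  truth <- dataset$truth
  truth$config <- NULL
  jsonlite::write_json(truth, p("truth.json"), digits = NA)
  invisible(c(gff3 = p("annotation.gff3"), plus = p("coverage_plus.bedGraph"),
              minus = p("coverage_minus.bedGraph"), counts = p("counts.tsv"),
              samples = p("samples.tsv"), edges = p("network_edges.tsv"),
              targets = p("network_targets.txt"), ladder = p("ladder.tsv"),
              truth = p("truth.json")))
}
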