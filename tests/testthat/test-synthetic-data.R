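test_that("generated genomes respect planted sRNA geometry", {
  for (seed in 1:3) {
    g <- generate_genome(small_config(seed))
    genes <- g$annotation$genes
    tr <- g$truth$srnas
    expect_equal(sum(tr$mode == "cis"), 8L)
    expect_equal(sum(tr$mode == "trans"), 4L)
    expect_true(all(tr$size >= 101 & tr$size <= 562))
    expect_equal(tr$size, tr$end - tr$start)
    for (i in seq_len(nrow(tr))) {
      opp <- genes[genes$replicon == tr$replicon[i] &
                     genes$strand != tr$strand[i], ]
      same <- genes[genes$replicon == tr$replicon[i] &
                      genes$strand == tr$strand[i], ]
      ov_opp <- pmin(opp$end, tr$end[i]) - pmax(opp$start, tr$start[i])
      ov_same <- pmin(same$end, tr$end[i]) - pmax(same$start, tr$start[i])
      if (tr$mode[i] == "cis") {
        # strictly inside exactly one opposite-strand gene
        expect_equal(sum(ov_opp > 0), 1L)
        host <- opp[which(ov_opp > 0), ]
        expect_true(host$start < tr$start[i] && tr$end[i] < host$end)
        expect_equal(host$locus_tag, tr$antisense_locus[i])
      } else {
        # no overlap with any gene; margin from every gene boundary
        expect_true(all(c(ov_opp, ov_same) <= 0))
        all_g <- genes[genes$replicon == tr$replicon[i], ]
        dist <- pmax(all_g$start - tr$end[i], tr$start[i] - all_g$end)
        expect_true(all(dist >= 80))
      }
    }
  }
})

test_that("zero planted sRNAs give genes-only annotations", {
  g <- generate_genome(small_config(1, n_cis_srnas = 0, n_trans_srnas = 0))
  expect_equal(nrow(g$truth$srnas), 0L)
  expect_equal(nrow(g$annotation$genes), 60L)
})

test_that("simulated counts are reproducible and match NB moments", {
  cfg <- small_config(5)
  g <- generate_genome(cfg)
  cm1 <- simulate_counts(g$truth, cfg)
  cm2 <- simulate_counts(g$truth, cfg)
  expect_identical(cm1$counts, cm2$counts)

  # moment check with many replicates and no planted effects
  cfg2 <- simulation_config(seed = 9, n_replicates_per_condition = 2500,
                            libsize_factor_range = c(1, 1))
  truth <- list(features = tibble::tibble(
    feature = c("a", "b", "c"), type = "gene",
    mean = c(50, 200, 1000), dispersion = 0.2, log2fc = 0))
  cm <- simulate_counts(truth, cfg2)
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, var)
  expect_equal(m, c(a = 50, b = 200, c = 1000), tolerance = 0.05)
  expect_equal(v, m + 0.2 * m^2, tolerance = 0.08)
  # equal condition means in expectation when log2fc = 0
  m1 <- rowMeans(cm$counts[, cm$condition == "C"])
  m2 <- rowMeans(cm$counts[, cm$condition == "N"])
  expect_equal(m1 / m2, c(a = 1, b = 1, c = 1), tolerance = 0.05)

  # dispersion -> 0 limit behaves like Poisson
  truth0 <- truth
  truth0$features$dispersion <- 0
  cm0 <- simulate_counts(truth0, cfg2)
  v0 <- apply(cm0$counts, 1, var)
  expect_equal(v0 / rowMeans(cm0$counts), c(a = 1, b = 1, c = 1),
               tolerance = 0.1)

  truth_bad <- truth
  truth_bad$features$mean[1] <- Inf
  expect_error(simulate_counts(truth_bad, cfg2), "non-finite")
})

test_that("coverage conserves read mass and confines signal to features", {
  ann <- genome_annotation(
    c(chr = 5000),
    tibble::tibble(locus_tag = c("GA", "GB"), replicon = "chr",
                   start = c(1000L, 3000L), end = c(1200L, 3030L),
                   strand = c("+", "-"), product = NA, category = NA))
  truth <- list(srnas = tibble::tibble(
    id = character(), replicon = character(), start = integer(),
    end = integer(), strand = character(), size = integer(),
    mode = character(), antisense_locus = character()))
  y <- matrix(c(60L, 40L, 7L, 3L), 2, 2, byrow = TRUE,
              dimnames = list(c("GA", "GB"), c("C1", "N1")))
  cm <- count_matrix(y, c("C", "N"))
  cfg <- simulation_config(seed = 2, read_length = 50, background_rate = 0)
  cov <- simulate_coverage(truth, ann, cm, cfg)
  # GA: 100 reads x 50 nt inside [1000, 1200)
  expect_equal(sum(cov$chr[["+"]]), 100 * 50)
  expect_equal(sum(cov$chr[["+"]][1:1000]), 0)
  expect_equal(sum(cov$chr[["+"]][1201:5000]), 0)
  # GB is shorter than a read: reads truncate to the 30 nt feature
  expect_equal(sum(cov$chr[["-"]]), 10 * 30)
  expect_equal(sum(cov$chr[["-"]][3001:3030]), 300)

  # background rate bounds off-feature depth
  cfg_bg <- simulation_config(seed = 3, read_length = 50,
                              background_rate = 0.05)
  cov_bg <- simulate_coverage(truth, ann, cm, cfg_bg)
  off <- cov_bg$chr[["+"]][setdiff(1:5000, 1001:1200)]
  expect_lt(mean(off), 0.05 * 1.5)
  # reproducibility
  cov_bg2 <- simulate_coverage(truth, ann, cm, cfg_bg)
  expect_identical(cov_bg, cov_bg2)
})

test_that("network generator plants the requested connectivity deficit", {
  cfg <- simulation_config(seed = 1, n_genes = 200,
                           replicon_lengths = c(chr = 300000),
                           n_cis_srnas = 2, n_trans_srnas = 2,
                           network_fraction = 1, target_network_fraction = 1,
                           network_mean_degree = 10)
  g <- generate_genome(cfg)
  targets <- g$annotation$genes$locus_tag[1:40]

  ratios <- vapply(1:20, function(s) {
    cfg$seed <- 400 + s
    sim <- simulate_network(g$annotation, targets, cfg)
    d <- degree_summary(sim$network)
    d$mean_degree_target / d$mean_degree_nontarget
  }, numeric(1))
  # one target endpoint per cross dyad: mean degree ratio close to the
  # odds-scale deficit (exactly 0.8 only in the small-p limit)
  expect_equal(mean(ratios), 0.8, tolerance = 0.07)

  cfg$network_degree_deficit <- 0
  ratios0 <- vapply(1:10, function(s) {
    cfg$seed <- 500 + s
    sim <- simulate_network(g$annotation, targets, cfg)
    d <- degree_summary(sim$network)
    d$mean_degree_target / d$mean_degree_nontarget
  }, numeric(1))
  expect_equal(mean(ratios0), 1, tolerance = 0.05)

  sim <- simulate_network(g$annotation, targets, cfg)
  expect_false(any(sim$network$edges$source == sim$network$edges$target))
  expect_error(
    simulate_network(g$annotation, targets,
                     simulation_config(network_degree_deficit = 0.999999) |>
                       (\(x) { x$network_degree_deficit <- 1; x })()),
    "deficit")
})

test_that("ladder simulation sits on the inverse-link curve", {
  cfg <- simulation_config(seed = 4, ladder_shape = Inf)
  sim <- simulate_ladder(cfg)
  expect_equal(sim$ladder$size_nt,
               1 / (sim$b0 + sim$b1 * sim$ladder$distance))
  # noisy simulation is reproducible and recovers the curve
  cfg2 <- simulation_config(seed = 4)
  s1 <- simulate_ladder(cfg2)
  s2 <- simulate_ladder(cfg2)
  expect_identical(s1$ladder, s2$ladder)
  hits <- vapply(1:10, function(s) {
    cfg2$seed <- s
    sim <- simulate_ladder(cfg2)
    cal <- calibrate_ladder(sim$ladder)
    se <- sqrt(diag(cal$vcov))
    all(abs(c(cal$b0, cal$b1) - c(sim$b0, sim$b1)) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # infeasible curve rejected
  cfg3 <- simulation_config(ladder_b0 = 0.02)  # 1/size < b0 for all sizes
  expect_error(simulate_ladder(cfg3), "non-positive")
})

test_that("a written dataset can be read back through the io layer", {
  cfg <- small_config(6)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  ann <- read_gff3(paths[["gff3"]])
  expect_equal(ann$replicons, ds$annotation$replicons)
  expect_equal(as.data.frame(ann$genes), as.data.frame(ds$annotation$genes))
  cov <- read_bedgraph_pair(paths[["plus"]], paths[["minus"]], ann)
  expect_equal(cov$chr[["+"]], ds$coverage$chr[["+"]])
  cm <- read_count_matrix(paths[["counts"]], paths[["samples"]])
  expect_equal(cm$counts, ds$counts$counts)
  expect_equal(nrow(read_edge_list(paths[["edges"]])),
               nrow(ds$network$network$edges))
})
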