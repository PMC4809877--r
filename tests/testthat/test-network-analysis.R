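test_that("network construction yields a simple directed graph", {
  edges <- tibble::tibble(source = c("A", "B", "C"),
                          target = c("B", "C", "A"))
  net <- metabolic_network(edges, target_set = "A")
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$nodes$is_target, c(TRUE, FALSE, FALSE))

  dup <- dplyr::bind_rows(edges, edges[1, ])
  expect_message(net2 <- metabolic_network(dup), "1 duplicate")
  expect_equal(nrow(net2$edges), 3L)

  loops <- dplyr::bind_rows(edges, tibble::tibble(source = "A",
                                                  target = "A"))
  expect_warning(net3 <- metabolic_network(loops), "self-loop")
  expect_equal(nrow(net3$edges), 3L)

  # file-based construction with a targets file
  ef <- withr::local_tempfile(); tf <- withr::local_tempfile()
  write_edge_list(edges, ef)
  writeLines(c("A", "C"), tf)
  net4 <- build_network(ef, tf)
  expect_equal(sum(net4$nodes$is_target), 2L)
})

test_that("degree summary matches hand counts on a star graph", {
  star <- metabolic_network(
    tibble::tibble(source = "H", target = c("L1", "L2", "L3", "L4")),
    target_set = "L1")
  d <- degree_summary(star)
  expect_equal(d$mean_degree_target, 1)
  expect_equal(d$mean_degree_nontarget, (4 + 1 + 1 + 1) / 4)
  expect_equal(d$relative_deficit, 1 - 1 / 1.75)
  # identical degrees -> zero deficit
  cyc <- metabolic_network(tibble::tibble(source = c("A", "B", "C"),
                                          target = c("B", "C", "A")),
                           target_set = "B")
  expect_equal(degree_summary(cyc)$relative_deficit, 0)
  no_targets <- metabolic_network(tibble::tibble(source = "A", target = "B"))
  expect_error(degree_summary(no_targets), "no target nodes")
})

test_that("edge-model MLE equals direct likelihood maximization", {
  cfg <- simulation_config(seed = 1, n_genes = 20,
                           replicon_lengths = c(chr = 40000),
                           n_cis_srnas = 1, n_trans_srnas = 1,
                           network_fraction = 1, target_network_fraction = 1,
                           network_mean_degree = 6)
  g <- generate_genome(cfg)
  targets <- g$annotation$genes$locus_tag[1:5]
  for (s in 1:3) {
    cfg$seed <- 600 + s
    sim <- simulate_network(g$annotation, targets, cfg)
    fit <- fit_edge_model(sim$network)
    cen <- srnapipe:::dyad_census_by_covariate(sim$network)
    nll <- function(th) {
      p <- plogis(th[1] + th[2] * as.numeric(names(cen$dyads)))
      -sum(cen$ties * log(p) + (cen$dyads - cen$ties) * log1p(-p))
    }
    opt <- optim(c(-2, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(c(fit$theta_edges, fit$theta_target), opt$par,
                 tolerance = 1e-4)
    expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
    expect_gt(fit$se_edges, 0)
    expect_gt(fit$se_target, 0)
    expect_equal(fit$tie_prob_ratio,
                 plogis(fit$theta_edges + fit$theta_target) /
                   plogis(fit$theta_edges))
  }
})

test_that("a covariate independent of ties is estimated near zero", {
  set.seed(44)
  n <- 80
  nodes <- sprintf("N%02d", 1:n)
  ij <- expand.grid(i = 1:n, j = 1:n)
  ij <- ij[ij$i != ij$j, ]
  tie <- runif(nrow(ij)) < 0.05
  net <- metabolic_network(
    tibble::tibble(source = nodes[ij$i[tie]], target = nodes[ij$j[tie]]),
    target_set = sample(nodes, 20), nodes = nodes)
  fit <- fit_edge_model(net)
  expect_lte(abs(fit$theta_target), 2 * fit$se_target)
})

test_that("fitted quantities are invariant to node relabeling", {
  cfg <- simulation_config(seed = 2, n_genes = 40,
                           replicon_lengths = c(chr = 80000),
                           n_cis_srnas = 1, n_trans_srnas = 1,
                           network_fraction = 1, target_network_fraction = 1,
                           network_mean_degree = 6)
  g <- generate_genome(cfg)
  targets <- g$annotation$genes$locus_tag[1:10]
  sim <- simulate_network(g$annotation, targets, cfg)
  fit <- fit_edge_model(sim$network)
  relabel <- function(x) paste0("zz_", x)
  net2 <- metabolic_network(
    tibble::tibble(source = relabel(sim$network$edges$source),
                   target = relabel(sim$network$edges$target)),
    target_set = relabel(targets),
    nodes = relabel(sim$network$nodes$gene))
  fit2 <- fit_edge_model(net2)
  expect_equal(fit2$theta_edges, fit$theta_edges)
  expect_equal(fit2$theta_target, fit$theta_target)
  expect_equal(fit2$loglik, fit$loglik)
})

test_that("degenerate covariate strata are reported, not fitted", {
  # targets with zero incident ties
  edges <- tibble::tibble(source = c("A", "B", "C", "A"),
                          target = c("B", "C", "A", "C"))
  net <- metabolic_network(edges, target_set = "T1",
                           nodes = c("A", "B", "C", "T1"))
  expect_error(fit_edge_model(net), "degenerate target stratum")
})

test_that("Metropolis sampler agrees with the exact MLE", {
  cfg <- simulation_config(seed = 3, n_genes = 60,
                           replicon_lengths = c(chr = 120000),
                           n_cis_srnas = 1, n_trans_srnas = 1,
                           network_fraction = 1, target_network_fraction = 1,
                           network_mean_degree = 8)
  g <- generate_genome(cfg)
  sim <- simulate_network(g$annotation, g$annotation$genes$locus_tag[1:15],
                          cfg)
  fit <- fit_edge_model(sim$network)
  mc <- mcmc_edge_model(sim$network, n_samples = 4000, step = 0.15, seed = 5)
  expect_equal(mc$theta_edges, fit$theta_edges, tolerance = 0.1)
  expect_equal(mc$theta_target, fit$theta_target,
               tolerance = 3 * fit$se_target)
})

test_that("membership proportions match hand computation", {
  genes <- tibble::tibble(
    locus_tag = sprintf("G%02d", 1:10), replicon = "chr",
    start = seq(0L, 900L, by = 100L), end = seq(50L, 950L, by = 100L),
    strand = "+", product = NA, category = NA)
  ann <- genome_annotation(c(chr = 1000), genes)
  net <- metabolic_network(
    tibble::tibble(source = c("G01", "G02", "G03"),
                   target = c("G02", "G03", "G04")),
    target_set = c("G01", "G09"))
  res <- membership_proportions(ann, c("G01", "G09"), net)
  expect_equal(res$prop_targets_in_network, 0.5)
  expect_equal(res$prop_genes_in_network, 0.4)
  hand <- two_proportion_ztest(1, 2, 4, 10)
  expect_equal(res$z, hand$z)
  expect_equal(res$p, hand$p)
  # a network containing every gene
  full <- metabolic_network(
    tibble::tibble(source = genes$locus_tag,
                   target = genes$locus_tag[c(2:10, 1)]),
    target_set = "G01")
  res_full <- membership_proportions(ann, "G01", full)
  expect_equal(res_full$prop_targets_in_network, 1)
  expect_equal(res_full$prop_genes_in_network, 1)
  expect_equal(res_full$z, 0)
  expect_error(membership_proportions(ann, "NOPE", net), "absent")
})
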