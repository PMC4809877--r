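#' Construct a directed metabolic network with target flags
#'
#' Builds a simple directed graph: self-loop rows are dropped with a
#' warning and duplicate edges collapsed with a message. Nodes are flagged
#' `is_target` iff they belong to `target_set`.
#'
#' @param edges Data frame with character columns `source`, `target`.
#' @param target_set Character vector of sRNA-target gene ids.
#' @param nodes Optional full node set (to retain isolated nodes).
#' @return An object of class `metabolic_network`: list with `nodes`
#'   (tibble `gene`, `is_target`) and `edges`.
#' @export
metabolic_network <- function(edges, target_set = character(),
                              nodes = NULL) {
  edges <- tibble::as_tibble(edges)[, c("source", "target")]
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  dup <- duplicated(paste(edges$source, edges$target, sep = "\r"))
  if (any(dup)) {
    message(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  structure(list(nodes = tibble::tibble(gene = nodes,
                                        is_target = nodes %in% target_set),
                 edges = edges),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d nodes (%d targets), %d directed edges\n",
              nrow(x$nodes), sum(x$nodes$is_target), nrow(x$edges)))
  invisible(x)
}

#' Read a metabolic network from an edge-list TSV
#'
#' @param edge_path TSV with `source`, `target` columns.
#' @param target_set Character vector of target gene ids (or a path to a
#'   file with one id per line).
#' @return A [metabolic_network()].
#' @export
build_network <- function(edge_path, target_set = character()) {
  if (length(target_set) == 1 && file.exists(target_set))
    target_set <- readLines(target_set, warn = FALSE)
  metabolic_network(read_edge_list(edge_path), target_set = target_set)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes$gene)
}

#' Compare total degree of target vs non-target genes
#'
#' @param network A [metabolic_network()].
#' @return A list with `mean_degree_target`, `mean_degree_nontarget`, and
#'   `relative_deficit` (= 1 - target/non-target mean).
#' @export
degree_summary <- function(network) {
  abort_if(!any(network$nodes$is_target), "no target nodes in network")
  abort_if(all(network$nodes$is_target), "no non-target nodes in network")
  g <- as_igraph(network)
  deg <- igraph::degree(g, mode = "all")[network$nodes$gene]
  mt <- mean(deg[network$nodes$is_target])
  mn <- mean(deg[!network$nodes$is_target])
  list(mean_degree_target = mt, mean_degree_nontarget = mn,
       relative_deficit = 1 - mt / mn)
}

# dyad census by covariate sum s = is_target(i) + is_target(j):
# counts of ordered dyads and of observed ties in each stratum
dyad_census_by_covariate <- function(network) {
  t_flag <- network$nodes$is_target
  n <- nrow(network$nodes)
  nt <- sum(t_flag)
  nn <- n - nt
  dyads <- c(`0` = nn * (nn - 1), `1` = 2 * nt * nn, `2` = nt * (nt - 1))
  i <- match(network$edges$source, network$nodes$gene)
  j <- match(network$edges$target, network$nodes$gene)
  s_edge <- t_flag[i] + t_flag[j]
  ties <- vapply(0:2, function(s) sum(s_edge == s), numeric(1))
  names(ties) <- names(dyads)
  list(dyads = dyads, ties = ties)
}

#' Fit the node-covariate edge-probability model (dyadic-independent ERGM)
#'
#' Each ordered dyad (i, j), i != j, carries a tie independently with
#' log-odds `theta_edges + theta_target * (is_target(i) + is_target(j))`.
#' Because the model has only edge and node-covariate terms, dyads are
#' independent and the exact maximum-likelihood fit reduces to a logistic
#' regression over the dyad census, solved by IRLS.
#'
#' @param network A [metabolic_network()].
#' @return A list of class `ergm_fit`: `theta_edges`, `theta_target`,
#'   `se_edges`, `se_target`, `tie_prob_ratio` (fitted tie probability at
#'   one target endpoint over the baseline), `loglik`, `census`.
#' @export
fit_edge_model <- function(network) {
  cen <- dyad_census_by_covariate(network)
  present <- cen$dyads > 0
  abort_if(sum(present) < 2, "need dyads in at least two covariate strata")
  base_ok <- cen$ties[["0"]] > 0 && cen$ties[["0"]] < cen$dyads[["0"]]
  abort_if(!base_ok,
           "degenerate baseline stratum: non-target dyads are all-%s",
           if (cen$ties[["0"]] == 0) "empty" else "tied")
  t_ties <- sum(cen$ties[c("1", "2")])
  t_dyads <- sum(cen$dyads[c("1", "2")])
  abort_if(t_dyads > 0 && (t_ties == 0 || t_ties == t_dyads),
           "degenerate target stratum: target-incident dyads are all-%s",
           if (t_ties == 0) "empty" else "tied")
  s <- as.numeric(names(cen$dyads))[present]
  m <- cen$ties[present]
  n <- cen$dyads[present]
  fit <- glm(cbind(m, n - m) ~ s, family = binomial())
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  p <- plogis(co[1] + co[2] * s)
  ll <- sum(m * log(p) + (n - m) * log1p(-p))
  structure(list(theta_edges = unname(co[1]), theta_target = unname(co[2]),
                 se_edges = unname(se[1]), se_target = unname(se[2]),
                 tie_prob_ratio = unname(plogis(co[1] + co[2]) /
                                           plogis(co[1])),
                 loglik = ll, census = cen),
            class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf(paste0("<ergm_fit> theta_edges = %.3f (SE %.3f), ",
                     "theta_target = %.3f (SE %.3f)\n",
                     "  tie probability at one target endpoint / baseline ",
                     "= %.3f\n"),
              x$theta_edges, x$se_edges, x$theta_target, x$se_target,
              x$tie_prob_ratio))
  invisible(x)
}

#' Metropolis re-estimate of the edge-model coefficients
#'
#' Cross-validates the exact logistic MLE of [fit_edge_model()] with a
#' random-walk Metropolis sampler over the dyad-census log-likelihood.
#'
#' @param network A [metabolic_network()].
#' @param n_samples Number of kept posterior-mode samples (flat prior).
#' @param step Proposal SD.
#' @param seed RNG seed.
#' @return A list with posterior means `theta_edges`, `theta_target` and the
#'   chain matrix.
#' @export
mcmc_edge_model <- function(network, n_samples = 2000, step = 0.1,
                            seed = 1L) {
  set.seed(seed)
  cen <- dyad_census_by_covariate(network)
  present <- cen$dyads > 0
  s <- as.numeric(names(cen$dyads))[present]
  m <- cen$ties[present]; n <- cen$dyads[present]
  ll <- function(th) {
    p <- plogis(th[1] + th[2] * s)
    sum(m * log(p) + (n - m) * log1p(-p))
  }
  cur <- c(log(sum(m) / (sum(n) - sum(m))), 0)
  cur_ll <- ll(cur)
  chain <- matrix(NA_real_, n_samples, 2)
  for (k in seq_len(2 * n_samples)) {
    prop <- cur + rnorm(2, 0, step)
    prop_ll <- ll(prop)
    if (log(runif(1)) < prop_ll - cur_ll) {
      cur <- prop; cur_ll <- prop_ll
    }
    if (k > n_samples) chain[k - n_samples, ] <- cur
  }
  list(theta_edges = mean(chain[, 1]), theta_target = mean(chain[, 2]),
       chain = chain)
}

#' Network-membership proportions of target vs all genes
#'
#' Reports which fraction of sRNA-target genes and of all annotated genes
#' appear as nodes of the metabolic network, with a pooled two-proportion
#' Z-test of the difference.
#'
#' @param annotation A [genome_annotation()] (the gene universe).
#' @param target_set Character vector of target locus tags.
#' @param network A [metabolic_network()].
#' @return A list with `prop_targets_in_network`, `prop_genes_in_network`,
#'   counts, `z`, and `p`.
#' @export
membership_proportions <- function(annotation, target_set, network) {
  genes <- annotation$genes$locus_tag
  abort_if(length(genes) == 0, "empty annotation")
  abort_if(!all(target_set %in% genes),
           "target_set contains loci absent from the annotation")
  in_net <- genes %in% network$nodes$gene
  k_t <- sum(target_set %in% network$nodes$gene)
  n_t <- length(target_set)
  k_a <- sum(in_net)
  n_a <- length(genes)
  zt <- two_proportion_ztest(k_t, n_t, k_a, n_a)
  list(prop_targets_in_network = k_t / n_t,
       prop_genes_in_network = k_a / n_a,
       n_targets = n_t, n_genes = n_a,
       n_targets_in_network = k_t, n_genes_in_network = k_a,
       z = zt$z, p = zt$p)
}
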