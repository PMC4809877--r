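#' Match sRNA calls to truth/count features by interval overlap
#'
#' Links each called interval to the planted sRNA (or any located feature
#' table with `feature`/`id`, `replicon`, `start`, `end`, `strand`) it
#' overlaps most on the same strand, so calls can be joined to the count
#' matrix and truth set.
#'
#' @param calls Call tibble from [classify_calls()].
#' @param features Tibble with `id`, `replicon`, `start`, `end`, `strand`.
#' @return `calls` with an added `feature` column (NA where unmatched).
#' @export
match_calls_to_features <- function(calls, features) {
  calls$feature <- NA_character_
  for (i in seq_len(nrow(calls))) {
    sel <- features$replicon == calls$replicon[i] &
      features$strand == calls$strand[i]
    if (!any(sel)) next
    f <- features[sel, ]
    ov <- overlap_len(calls$start[i], calls$end[i], f$start, f$end)
    if (max(ov) > 0)
      calls$feature[i] <- f$id[which.max(ov)]
  }
  calls
}

#' Pipeline configuration
#'
#' @param seed Master seed, recorded in the manifest and reused by every
#'   stochastic stage.
#' @param outdir Output directory.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param detection A [detection_params()].
#' @param n_boot Random re-pairings for the fold-change regression null.
#' @param trim_m,trim_a,shrink,mean_floor Differential-expression settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("srnapipe"),
                            sim = simulation_config(seed = seed),
                            detection = detection_params(),
                            n_boot = 10000,
                            trim_m = 0.30, trim_a = 0.05, shrink = 0.8,
                            mean_floor = 0) {
  sim$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis on a simulated dataset
#'
#' Executes simulate -> detect -> differential expression -> cis target
#' assignment -> fold-change regression with random re-pairing null ->
#' network analysis -> ladder calibration, writing the sRNA report table
#' and a JSON summary plus manifest under `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return A list with every stage's result, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config$sim)
  write_dataset(ds, file.path(config$outdir, "inputs"))

  calls <- detect_srnas(ds$coverage, ds$annotation, config$detection)
  calls <- match_calls_to_features(calls, ds$truth$srnas)
  de <- run_diffexp(ds$counts, trim_m = config$trim_m,
                    trim_a = config$trim_a, shrink = config$shrink,
                    mean_floor = config$mean_floor)
  cis_targets <- assign_cis_targets(calls, ds$annotation)

  # DE rows for calls go through the matched count feature
  de_calls <- de[match(calls$feature, de$feature), ]
  de_calls$feature <- calls$id
  de_calls <- de_calls[!is.na(calls$feature), , drop = FALSE]
  report <- write_srna_table(calls, de_calls, cis_targets,
                             file.path(config$outdir, "srna_table.tsv"))

  pairs <- pair_fold_changes(calls, cis_targets,
                             dplyr::bind_rows(de_calls, de))
  regression <- fit_fc_regression(pairs)
  null <- bootstrap_f_null(pairs, n_iter = config$n_boot,
                           seed = config$seed)

  net <- ds$network$network
  ergm <- fit_edge_model(net)
  degrees <- degree_summary(net)
  membership <- membership_proportions(
    ds$annotation, unique(cis_targets$target_locus), net)

  calib <- calibrate_ladder(ds$ladder$ladder)
  sizes <- predict_size(calib, ds$ladder$ladder$distance,
                        compare_size = config$sim$ladder_sizes)

  summary <- list(
    n_calls = nrow(calls), n_cis = sum(calls$mode == "cis"),
    n_trans = sum(calls$mode == "trans"),
    n_de_q05 = sum(de_calls$q <= 0.05, na.rm = TRUE),
    regression = regression[c("n", "slope", "r2", "f")],
    null = list(median_f = null$median_f, p_emp = null$p_emp,
                n_iter = null$n_iter),
    ergm = ergm[c("theta_edges", "theta_target", "se_target",
                  "tie_prob_ratio")],
    degrees = degrees, membership = membership,
    ladder = list(b0 = calib$b0, b1 = calib$b1,
                  inside_interval = mean(sizes$inside_interval)))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "srnapipe",
    version = as.character(utils::packageVersion("srnapipe")),
    seed = config$seed, n_boot = config$n_boot,
    detection = unclass(config$detection),
    rows = list(calls = nrow(calls), de = nrow(de), pairs = nrow(pairs),
                network_nodes = nrow(net$nodes),
                network_edges = nrow(net$edges)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, calls = calls, de = de, report = report,
                 cis_targets = cis_targets, pairs = pairs,
                 regression = regression, null = null, ergm = ergm,
                 degrees = degrees, membership = membership,
                 calibration = calib, sizes = sizes, summary = summary))
}
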