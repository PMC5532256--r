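#' Run the full gene evaluation pipeline from a JSON config
#'
#' Orchestrates: literature metrics -> pathway enrichment (plus optional
#' disease gene-set enrichment) -> co-membership network and centrality ->
#' metric table; and, when expression data are configured, a ranked
#' classification sweep for each of the four metrics plus the all-genes
#' baseline, each followed by a permutation test. Every stage logs to
#' stderr; a JSON run manifest listing config, input digests and outputs
#' is written last (and also on failure, naming the failed stage).
#'
#' Config fields (JSON object): `relation_table`, `pathway_gmt`,
#' `universe_size`, `disease_id` (required); `disease_gmt`,
#' `expression_matrix`, `expression_labels`, `out_dir` (default
#' `"markeval_out"`), plus any [analysis_config()] field
#' (`current_date`, `alpha`, `pea_p_threshold`, `snea_p_threshold`,
#' `fdr_q`, `permutation_runs`, `rng_seed`, `zscore_features`).
#'
#' @param config_path Path to the JSON config file (or an equivalent
#'   named list).
#' @return Invisibly, the manifest (named list), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_full_pipeline <- function(config_path) {
  cfg <- if (is.character(config_path)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    config_path
  }
  for (field in c("relation_table", "pathway_gmt", "universe_size",
                  "disease_id")) {
    if (is.null(cfg[[field]])) stop("config missing required field: ", field)
  }
  out_dir <- if (is.null(cfg$out_dir)) "markeval_out" else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  acfg <- analysis_config(
    current_date = if (is.null(cfg$current_date)) Sys.Date() else cfg$current_date,
    alpha = if (is.null(cfg$alpha)) 0.5 else cfg$alpha,
    pea_p_threshold = if (is.null(cfg$pea_p_threshold)) 1e-10 else cfg$pea_p_threshold,
    snea_p_threshold = if (is.null(cfg$snea_p_threshold)) 1e-50 else cfg$snea_p_threshold,
    fdr_q = if (is.null(cfg$fdr_q)) 0.001 else cfg$fdr_q,
    permutation_runs = if (is.null(cfg$permutation_runs)) 5000 else cfg$permutation_runs,
    rng_seed = if (is.null(cfg$rng_seed)) 1L else cfg$rng_seed,
    zscore_features = if (is.null(cfg$zscore_features)) TRUE else cfg$zscore_features
  )

  inputs <- c(relation_table = cfg$relation_table,
              pathway_gmt = cfg$pathway_gmt)
  if (!is.null(cfg$disease_gmt)) inputs["disease_gmt"] <- cfg$disease_gmt
  if (!is.null(cfg$expression_matrix)) {
    inputs["expression_matrix"] <- cfg$expression_matrix
    inputs["expression_labels"] <- cfg$expression_labels
  }
  manifest <- list(command = "run_full_pipeline",
                   config = cfg,
                   input_md5 = as.list(tools::md5sum(inputs)),
                   seed = acfg$rng_seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = character(0), status = "running")
  fail <- function(stage, err) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(sprintf("pipeline stage %s failed: %s", dQuote(stage),
                 conditionMessage(err)), call. = FALSE)
  }
  run_stage <- function(stage, expr_) {
    ml_log(stage, "starting")
    tryCatch(expr_, error = function(e) fail(stage, e))
  }
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
  }

  relations <- run_stage("read", read_relation_table(cfg$relation_table))
  pathways <- run_stage("read", read_gmt(cfg$pathway_gmt, cfg$universe_size))
  disease_sets <- if (!is.null(cfg$disease_gmt)) {
    run_stage("read", read_gmt(cfg$disease_gmt, cfg$universe_size))
  }

  fit <- run_stage("metrics",
                   marker_metrics(relations, cfg$disease_id, pathways,
                                  disease_sets = disease_sets,
                                  config = acfg))
  run_stage("write", {
    write_metric_table(fit, file.path(out_dir, "metric_table.tsv"))
    add_output(file.path(out_dir, "metric_table.tsv"))
    utils::write.table(fit$pea, file.path(out_dir, "pea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "pea.tsv"))
    if (!is.null(fit$snea)) {
      utils::write.table(fit$snea, file.path(out_dir, "snea.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add_output(file.path(out_dir, "snea.tsv"))
    }
    export_network(fit$network, file.path(out_dir, "network_edges.tsv"))
    add_output(file.path(out_dir, "network_edges.tsv"))
    add_output(file.path(out_dir, "network_edges.tsv.nodes.tsv"))
    utils::write.table(fit$centrality,
                       file.path(out_dir, "node_centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "node_centrality.tsv"))
  })

  if (!is.null(cfg$expression_matrix)) {
    expr <- run_stage("expression",
                      read_expression(cfg$expression_matrix,
                                      cfg$expression_labels))
    run_stage("sweep", {
      rankings <- c(lapply(stats::setNames(nm = c("rscore", "ascore",
                                                  "pscore", "sscore")),
                           function(m) metric_ranking(fit, m)),
                    list(all_genes = sort(fit$table$gene)))
      for (nm in names(rankings)) {
        sw <- ranked_subset_sweep(expr, rankings[[nm]],
                                  zscore = acfg$zscore_features,
                                  metric_name = nm)
        pt <- permutation_test(expr, sw$argmax_n, sw$max_cr,
                               runs = acfg$permutation_runs,
                               seed = acfg$rng_seed,
                               zscore = acfg$zscore_features)
        write_sweep_result(sw, file.path(out_dir, paste0("sweep_", nm)),
                           permutation = pt, seed = acfg$rng_seed)
        add_output(file.path(out_dir, paste0("sweep_", nm, ".tsv")))
        add_output(file.path(out_dir, paste0("sweep_", nm, ".json")))
        ml_log("sweep", "%s: max CR %.2f%% at n=%d, permutation p=%g",
               nm, 100 * sw$max_cr, sw$argmax_n, pt$p_value)
      }
    })
  }

  run_stage("crossmetrics", {
    cm <- tryCatch(cross_metrics_overlap(fit), error = function(e) NULL)
    if (is.null(cm)) {
      ml_log("crossmetrics", "skipped: no genes below the novelty threshold")
    } else {
      jsonlite::write_json(
        list(k = cm$k, threshold_years = cm$threshold_years,
             top_sets = cm$top_sets,
             intersections = lapply(cm$intersections, function(it) {
               list(families = it$families, size = it$size,
                    members = it$members)
             })),
        file.path(out_dir, "crossmetrics.json"),
        auto_unbox = TRUE, digits = NA)
      add_output(file.path(out_dir, "crossmetrics.json"))
    }
  })

  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ml_log("pipeline", "complete: %d output file(s) in %s",
         length(manifest$outputs), out_dir)
  invisible(manifest)
}
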