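#' Score disease candidate genes with four literature and network metrics
#'
#' The central fitting function. For every gene with evidence for
#' `disease_id` in the relation table it computes:
#' \describe{
#'   \item{rscore}{number of distinct supporting references (publication
#'     frequency);}
#'   \item{ascore}{age in years of the earliest supporting publication
#'     (small = novel);}
#'   \item{pscore}{number of significantly enriched candidate pathways
#'     containing the gene;}
#'   \item{sscore}{generalized weighted-degree centrality of the gene in
#'     the pathway co-membership network, normalized to mean 1 over all
#'     scored genes.}
#' }
#' Pathway significance is decided by [enrich_collection()] on `pathways`
#' (raw p below `config$pea_p_threshold` and BH pass at `config$fdr_q`);
#' the same test is applied to the optional disease gene-set collection
#' at `config$snea_p_threshold` and reported alongside.
#'
#' @param relations A [read_relation_table()] result.
#' @param disease_id Disease identifier to score against.
#' @param pathways A [gene_set_collection()] of candidate pathways.
#' @param disease_sets Optional second collection of disease-associated
#'   gene sets (sub-network surrogates); enrichment against it is
#'   reported but does not enter any score.
#' @param config An [analysis_config()]; supplies `current_date`,
#'   `alpha` and the enrichment thresholds.
#' @return An object of class `"marker_metrics"`: list with `table` (the
#'   per-gene metric data.frame, ordered by descending sscore, ties by
#'   gene symbol), `pea`, `snea`, `network`, `centrality`, `disease_id`,
#'   `config`.
#' @examples
#' fx <- end_to_end_fixture(synthetic_spec(n_genes = 60, n_sets = 20,
#'                                         universe_size = 2000,
#'                                         set_size_range = c(20, 60),
#'                                         n_informative = 8, seed = 1))
#' fit <- marker_metrics(fx$relations, fx$disease_id, fx$pathways,
#'                       config = analysis_config(current_date = "2016-10-01"))
#' head(coef(fit))
#' @export
marker_metrics <- function(relations, disease_id, pathways,
                           disease_sets = NULL,
                           config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(pathways, "gene_set_collection"))
  rscore <- compute_rscore(relations, disease_id)
  ascore <- compute_ascore(relations, disease_id, config$current_date)
  genes <- names(rscore)
  ml_log("metrics", "scoring %d gene(s) for disease %s", length(genes),
         disease_id)

  pea <- enrich_collection(genes, pathways,
                           p_threshold = config$pea_p_threshold,
                           fdr_q = config$fdr_q)
  sig <- significant_sets(pea, pathways)
  ml_log("metrics", "%d of %d pathway set(s) significant", length(sig),
         nrow(pea))
  pscore <- compute_pscores(genes, sig)

  network <- build_ggi_network(genes, sig)
  centrality <- compute_sscores(network, alpha = config$alpha)
  sscore <- stats::setNames(centrality$sscore, centrality$gene)

  snea <- NULL
  if (!is.null(disease_sets)) {
    snea <- enrich_collection(genes, disease_sets,
                              p_threshold = config$snea_p_threshold,
                              fdr_q = config$fdr_q)
    ml_log("metrics", "%d of %d disease set(s) significant",
           sum(snea$significant), nrow(snea))
  }

  tab <- data.frame(gene = genes,
                    rscore = unname(rscore[genes]),
                    ascore = unname(ascore[genes]),
                    pscore = unname(pscore[genes]),
                    sscore = unname(sscore[genes]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$sscore, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(table = tab, pea = pea, snea = snea, network = network,
                 centrality = centrality, disease_id = disease_id,
                 config = config),
            class = "marker_metrics")
}

#' @export
print.marker_metrics <- function(x, ...) {
  cat(sprintf("Marker metrics for disease %s: %d genes scored\n",
              x$disease_id, nrow(x$table)))
  cat(sprintf("  significant pathways: %d of %d; network edges: %d (%d isolated genes)\n",
              sum(x$pea$significant), nrow(x$pea),
              sum(x$network$weights > 0) / 2,
              sum(rowSums(x$network$weights) == 0)))
  cat("  top genes by sscore:\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.marker_metrics <- function(object, ...) {
  tab <- object$table
  s <- rbind(rscore = summary(tab$rscore), ascore = summary(tab$ascore),
             pscore = summary(tab$pscore), sscore = summary(tab$sscore))
  out <- list(disease_id = object$disease_id, n_genes = nrow(tab),
              n_significant_pathways = sum(object$pea$significant),
              metric_summary = s,
              frac_single_reference = mean(tab$rscore == 1))
  class(out) <- "summary.marker_metrics"
  out
}

#' @export
print.summary.marker_metrics <- function(x, ...) {
  cat(sprintf("Marker metrics summary (disease %s)\n", x$disease_id))
  cat(sprintf("  genes scored: %d; significant pathways: %d\n",
              x$n_genes, x$n_significant_pathways))
  cat(sprintf("  genes with a single supporting reference: %.1f%%\n",
              100 * x$frac_single_reference))
  print(round(x$metric_summary, 3))
  invisible(x)
}

#' @export
coef.marker_metrics <- function(object, ...) {
  m <- as.matrix(object$table[c("rscore", "ascore", "pscore", "sscore")])
  rownames(m) <- object$table$gene
  m
}

#' @export
as.data.frame.marker_metrics <- function(x, ...) x$table

#' Distribution panels for the four metrics
#'
#' @param x A `marker_metrics` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.marker_metrics <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(rscore = "RScore (references)", ascore = "AScore (years)",
            pscore = "PScore (pathways)", sscore = "SScore (rel. centrality)")
  for (m in names(labs)) {
    graphics::hist(x$table[[m]], main = labs[[m]], xlab = m, col = "grey80",
                   border = "white", ...)
  }
  invisible(x)
}

#' Write a per-gene metric table
#'
#' Tab-separated, one row per gene, columns
#' `gene/rscore/ascore/pscore/sscore`, ordered by descending sscore with
#' ties broken by gene symbol.
#'
#' @param x A `marker_metrics` fit or its metric `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metric_table <- function(x, path) {
  if (inherits(x, "marker_metrics")) x <- x$table
  cols <- c("gene", "rscore", "ascore", "pscore", "sscore")
  stopifnot(all(cols %in% names(x)))
  if (!nrow(x)) stop("metric table is empty; nothing written")
  x <- x[order(-x$sscore, x$gene), cols, drop = FALSE]
  # full precision so a round trip is bit-exact
  fmt <- x
  fmt$ascore <- sprintf("%.17g", x$ascore)
  fmt$sscore <- sprintf("%.17g", x$sscore)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#'
#' @param path Input path.
#' @return A `data.frame` with columns gene/rscore/ascore/pscore/sscore.
#' @export
read_metric_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character"))
  cols <- c("gene", "rscore", "ascore", "pscore", "sscore")
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("metric table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab[cols]
}

#' Per-metric gene rankings from a metric table
#'
#' @param metrics A metric `data.frame` (or `marker_metrics`).
#' @param metric One of `"rscore"`, `"ascore"`, `"pscore"`, `"sscore"`.
#' @param decreasing Rank best-first by descending score (default); ties
#'   are always broken by gene symbol for determinism.
#' @return Character vector of gene symbols, best first.
#' @export
metric_ranking <- function(metrics, metric, decreasing = TRUE) {
  if (inherits(metrics, "marker_metrics")) metrics <- metrics$table
  metric <- match.arg(metric, c("rscore", "ascore", "pscore", "sscore"))
  s <- metrics[[metric]]
  ord <- order(if (decreasing) -s else s, metrics$gene)
  metrics$gene[ord]
}
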