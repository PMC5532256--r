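#' Build the pathway co-membership gene-gene interaction network
#'
#' Nodes are the supplied candidate genes; the weight of edge (i, j) is
#' the number of significant gene sets containing both genes. Genes that
#' share no set with any other gene remain isolated nodes with strength 0
#' (they keep their place in the node list and later receive score 0).
#'
#' @param genes Character vector of candidate gene symbols (no
#'   duplicates); all of them become nodes, connected or not.
#' @param sig_sets List of character vectors: member lists of the
#'   significant sets.
#' @return An object of class `"gene_network"`: list with `genes`,
#'   `weights` (symmetric integer matrix, zero diagonal) and `n_sets`.
#' @export
build_ggi_network <- function(genes, sig_sets) {
  genes <- toupper(trimws(genes))
  if (!length(genes)) stop("gene list is empty")
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  membership <- matrix(0, nrow = length(genes), ncol = length(sig_sets),
                       dimnames = list(genes, NULL))
  for (k in seq_along(sig_sets)) {
    membership[genes %in% sig_sets[[k]], k] <- 1
  }
  w <- tcrossprod(membership)
  diag(w) <- 0
  storage.mode(w) <- "integer"
  structure(list(genes = genes, weights = w,
                 n_sets = length(sig_sets)),
            class = "gene_network")
}

#' Generalized (alpha-) weighted degree centrality
#'
#' `degree * (strength / degree)^alpha`: interpolates between plain degree
#' centrality (`alpha = 0`) and node strength (`alpha = 1`); at the
#' default `alpha = 0.5` it equals `sqrt(degree * strength)`, weighing the
#' number of neighbours and the total tie weight equally. Isolated nodes
#' (degree 0, hence strength 0) score 0 by convention.
#'
#' @param degree Non-negative integer vector of neighbour counts.
#' @param strength Non-negative vector of summed edge weights; must be 0
#'   wherever degree is 0.
#' @param alpha Tuning parameter (> 0 favours strength, values above 1
#'   favour strong ties over many ties).
#' @return Numeric vector of centralities.
#' @examples
#' generalized_centrality(4, 16, 0.5)  # 8
#' @export
generalized_centrality <- function(degree, strength, alpha = 0.5) {
  if (any(degree < 0) || any(strength < 0)) stop("negative degree or strength")
  if (any(degree == 0 & strength > 0)) {
    stop("strength must be 0 where degree is 0")
  }
  out <- numeric(length(degree))
  pos <- degree > 0
  out[pos] <- degree[pos] * (strength[pos] / degree[pos])^alpha
  out
}

#' Network significance score (SScore) for every node
#'
#' SScore of node i is `N * C_i / sum_j C_j`, where C is the generalized
#' centrality and N counts *all* supplied nodes, isolated ones included;
#' the mean SScore over all nodes is therefore exactly 1, and a gene with
#' SScore 2 is twice as central as the network average.
#'
#' @param network A [build_ggi_network()] result.
#' @param alpha Centrality tuning parameter (default 0.5).
#' @return A `data.frame` of class `"centrality_table"` with columns
#'   `gene`, `degree`, `strength`, `generalized`, `sscore`, in the
#'   network's node order.
#' @export
compute_sscores <- function(network, alpha = 0.5) {
  stopifnot(inherits(network, "gene_network"))
  w <- network$weights
  degree <- as.integer(rowSums(w > 0))
  strength <- as.numeric(rowSums(w))
  centrality <- generalized_centrality(degree, strength, alpha)
  total <- sum(centrality)
  if (total == 0) {
    stop("all nodes are isolated: SScore normalization is undefined")
  }
  n <- length(network$genes)
  res <- data.frame(gene = network$genes, degree = degree,
                    strength = strength, generalized = centrality,
                    sscore = n * centrality / total,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("centrality_table", "data.frame")
  res
}

#' Export a network as a weighted edge list (plus node table)
#'
#' Writes a TSV edge list with columns `gene_a`, `gene_b`, `weight`
#' (`gene_a < gene_b` lexicographically, rows sorted), and a companion
#' `<path>.nodes.tsv` listing every node so that isolated genes survive a
#' round trip. With `graphml = TRUE` an additional GraphML file is written
#' via the igraph package.
#'
#' @param network A `gene_network`.
#' @param path Edge-list output path.
#' @param graphml Also write `<path>.graphml`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, graphml = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  w <- network$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  a <- network$genes[idx[, 1]]
  b <- network$genes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      weight = w[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = network$genes),
                     paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("GraphML export requires the igraph package")
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = network$genes))
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  }
  invisible(path)
}

#' Re-import a network written by [export_network()]
#'
#' @param path Edge-list path (its `.nodes.tsv` companion must exist).
#' @return A `gene_network` (with `n_sets` unknown, set to `NA`).
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                             stringsAsFactors = FALSE)$gene
  w <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$gene_a, nodes)
    ib <- match(edges$gene_b, nodes)
    if (anyNA(ia) || anyNA(ib)) stop("edge gene absent from node table")
    w[cbind(ia, ib)] <- as.integer(edges$weight)
    w[cbind(ib, ia)] <- as.integer(edges$weight)
  }
  structure(list(genes = nodes, weights = w, n_sets = NA_integer_),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  n_edges <- sum(x$weights > 0) / 2
  cat(sprintf("Gene-gene interaction network: %d nodes, %d edges (%d isolated)\n",
              length(x$genes), n_edges, sum(rowSums(x$weights) == 0)))
  invisible(x)
}
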