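#' Fisher-exact over-representation p-value
#'
#' One-sided (greater) hypergeometric tail: the probability that a
#' uniformly random query of `query_size` genes from a universe of
#' `universe_size` overlaps a fixed set of `set_size` genes in at least
#' `overlap` members, i.e. P(X >= overlap) with
#' X ~ Hypergeometric(universe_size, set_size, query_size). This is the
#' one-sided Fisher exact test of over-representation.
#'
#' @param query_size,set_size Sizes of the two gene sets.
#' @param overlap Observed intersection size.
#' @param universe_size Annotation background size.
#' @return p-value(s) in (0, 1]. Vectorized over all arguments.
#' @examples
#' fisher_enrichment_test(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
fisher_enrichment_test <- function(query_size, set_size, overlap,
                                   universe_size) {
  n <- max(length(query_size), length(set_size), length(overlap),
           length(universe_size))
  query_size <- rep_len(as.numeric(query_size), n)
  set_size <- rep_len(as.numeric(set_size), n)
  overlap <- rep_len(as.numeric(overlap), n)
  universe_size <- rep_len(as.numeric(universe_size), n)
  if (any(overlap < 0)) stop("overlap must be non-negative")
  if (any(overlap > pmin(query_size, set_size))) {
    stop("inconsistent counts: overlap exceeds a margin")
  }
  if (any(query_size > universe_size) || any(set_size > universe_size)) {
    stop("inconsistent counts: set larger than the universe")
  }
  stats::phyper(overlap - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Jaccard similarity of two sets from their margins
#'
#' `overlap / (query_size + set_size - overlap)`, the ratio of
#' intersection to union.
#'
#' @inheritParams fisher_enrichment_test
#' @return Similarity in `[0, 1]`. Vectorized; errors if any union is
#'   empty.
#' @examples
#' jaccard_similarity(535, 472, 112)  # ~0.125
#' @export
jaccard_similarity <- function(query_size, set_size, overlap) {
  n <- max(length(query_size), length(set_size), length(overlap))
  query_size <- rep_len(as.numeric(query_size), n)
  set_size <- rep_len(as.numeric(set_size), n)
  overlap <- rep_len(as.numeric(overlap), n)
  if (any(overlap < 0) || any(overlap > pmin(query_size, set_size))) {
    stop("inconsistent counts: overlap exceeds a margin")
  }
  union_ <- query_size + set_size - overlap
  if (any(union_ == 0)) stop("undefined Jaccard similarity: empty union")
  overlap / union_
}

#' Gene-set over-representation analysis of a query gene list
#'
#' Tests every set of the collection against the query with the one-sided
#' Fisher exact test, applies Benjamini-Hochberg false discovery control
#' across all tested sets, and reports Jaccard similarity. A set is called
#' significant only if its raw p-value is below `p_threshold` *and* it
#' survives BH at level `fdr_q` (the dual criterion keeps isolated small
#' p-values from slipping through when many sets are tested).
#'
#' @param query Character vector of gene symbols (uppercased internally).
#' @param collection A [gene_set_collection()] whose `universe_size`
#'   defines the Fisher background.
#' @param p_threshold Raw p-value cutoff (default 1e-10).
#' @param fdr_q BH false discovery level (default 0.001).
#' @return A `data.frame` of class `"enrichment_result"`, one row per set,
#'   sorted by ascending p-value (ties broken by set name), with columns
#'   `set_name`, `category`, `n_entities`, `overlap`, `p_value`,
#'   `q_value`, `q_pass`, `significant`, `jaccard`, `jaccard_2dp`.
#' @export
enrich_collection <- function(query, collection, p_threshold = 1e-10,
                              fdr_q = 0.001) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(trimws(query)))
  query <- query[nzchar(query)]
  if (!length(query)) stop("query gene list is empty")
  members <- collection$sets
  observed_union <- length(unique(c(query, unlist(members, use.names = FALSE))))
  if (collection$universe_size < observed_union) {
    stop(sprintf("universe_size (%d) smaller than the observed union (%d)",
                 collection$universe_size, observed_union))
  }
  n_entities <- lengths(members)
  overlap <- vapply(members, function(m) sum(m %in% query), integer(1))
  p <- fisher_enrichment_test(length(query), n_entities, overlap,
                              collection$universe_size)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    set_name = names(members),
    category = unname(collection$category[names(members)]),
    n_entities = unname(n_entities),
    overlap = unname(overlap),
    p_value = unname(p),
    q_value = unname(q),
    q_pass = unname(q <= fdr_q),
    significant = unname(p < p_threshold & q <= fdr_q),
    jaccard = jaccard_similarity(length(query), unname(n_entities),
                                 unname(overlap)),
    stringsAsFactors = FALSE
  )
  res$jaccard_2dp <- round(res$jaccard, 2)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "query_size") <- length(query)
  attr(res, "universe_size") <- collection$universe_size
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Extract the member lists of the significant sets
#'
#' @param result An [enrich_collection()] result.
#' @param collection The collection it was computed from.
#' @return Named list of character vectors, in the result's order.
#' @export
significant_sets <- function(result, collection) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(collection, "gene_set_collection"))
  collection$sets[result$set_name[result$significant]]
}

#' Pathway membership score (PScore)
#'
#' PScore of a gene is the number of significant gene sets (candidate
#' pathways) that contain it; genes present in no significant set score 0.
#'
#' @param genes Character vector of gene symbols to score.
#' @param sig_sets List of character vectors: the member lists of the
#'   significant sets (see [significant_sets()]).
#' @return Named integer vector over `genes`.
#' @export
compute_pscores <- function(genes, sig_sets) {
  genes <- toupper(trimws(genes))
  if (!length(genes)) stop("gene list is empty")
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  counts <- integer(length(genes))
  names(counts) <- genes
  for (m in sig_sets) {
    hit <- genes %in% m
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment result: %d sets tested, %d significant (query %d, universe %d)\n",
    nrow(x), sum(x$significant), attr(x, "query_size"),
    attr(x, "universe_size")))
  NextMethod()
}
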