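#' @title Leave-one-out nearest-centroid classification
#' @name loo-classification
#' @description
#' Expression-based validation of a gene ranking: a held-out sample is
#' assigned to the class (case/control) whose centroid — the per-gene mean
#' over the training samples, optionally after per-gene standardization
#' with training-fold statistics — is nearest in Euclidean distance. The
#' classification ratio (CR) is the fraction of samples assigned
#' correctly over all leave-one-out folds.
NULL

# Per-fold squared-distance contributions of every gene.
#
# Returns, for each class c, a genes x samples matrix D[[c]] where
# D[[c]][g, s] is the squared (optionally standardized) distance of
# held-out sample s to the class-c training centroid along gene g. The
# Euclidean distance of s to centroid c over any gene subset is then
# sqrt(colSums over the subset), so subsets, ranked sweeps (via cumsum)
# and permutation draws all reuse one pass over the folds.
loo_fold_contributions <- function(values, labels, zscore = TRUE) {
  x <- values
  n_samples <- ncol(x)
  labels <- factor(as.character(labels))
  class_levels <- sort(levels(labels))
  counts <- table(labels)[class_levels]
  if (any(counts < 2L)) {
    stop("each class needs at least 2 samples for leave-one-out folds")
  }
  rs <- rowSums(x)
  ss <- rowSums(x^2)
  class_sums <- vapply(class_levels,
                       function(cl) rowSums(x[, labels == cl, drop = FALSE]),
                       numeric(nrow(x)))
  if (is.null(dim(class_sums))) {   # single-gene subset
    class_sums <- matrix(class_sums, nrow = 1L,
                         dimnames = list(NULL, class_levels))
  }
  d2 <- lapply(class_levels, function(cl) {
    matrix(NA_real_, nrow(x), n_samples)
  })
  names(d2) <- class_levels
  n_tr <- n_samples - 1L
  for (s in seq_len(n_samples)) {
    xs <- x[, s]
    if (zscore) {
      t1 <- rs - xs
      t2 <- ss - xs^2
      v <- (t2 - t1^2 / n_tr) / (n_tr - 1L)
      sdv <- sqrt(pmax(v, 0))
      sdv[!is.finite(sdv) | sdv <= 0] <- 1  # constant gene: center only
    } else {
      sdv <- 1
    }
    cl_s <- as.character(labels[s])
    for (cl in class_levels) {
      cs <- class_sums[, cl]
      centroid <- if (cl == cl_s) {
        (cs - xs) / (counts[[cl]] - 1L)
      } else {
        cs / counts[[cl]]
      }
      d2[[cl]][, s] <- ((xs - centroid) / sdv)^2
    }
  }
  list(d2 = d2, labels = labels, class_levels = class_levels)
}

# classification ratio from per-class squared-distance matrices
# (rows already reduced to the chosen subset); ties go to the
# lexicographically first class
cr_from_dist <- function(dist_by_class, labels, class_levels) {
  dmat <- do.call(cbind, dist_by_class)
  pred <- class_levels[max.col(-dmat, ties.method = "first")]
  mean(pred == as.character(labels))
}

resolve_subset <- function(expr, genes) {
  genes <- unique(toupper(trimws(genes)))
  present <- genes[genes %in% expr$genes]
  incomplete <- present[expr$incomplete[present]]
  if (length(incomplete)) {
    ml_log("validation", "excluded %d incomplete gene(s) from the subset",
           length(incomplete))
  }
  usable <- setdiff(present, incomplete)
  if (!length(usable)) {
    stop("no usable genes: all requested genes are missing or incomplete")
  }
  usable
}

#' Leave-one-out nearest-centroid classification ratio
#'
#' @param expr A [labeled_expression()] object; each class must have at
#'   least 2 samples.
#' @param genes Gene subset used as classification features; genes absent
#'   from `expr` or flagged incomplete are dropped with a log entry.
#' @param zscore Standardize each gene with training-fold mean/sd before
#'   computing distances (default `TRUE`); genes constant in a training
#'   fold are centered only.
#' @return The classification ratio in `[0, 1]`.
#' @seealso [ranked_subset_sweep()], [permutation_test()]
#' @export
nearest_centroid_loo_cr <- function(expr, genes, zscore = TRUE) {
  stopifnot(inherits(expr, "labeled_expression"))
  usable <- resolve_subset(expr, genes)
  prep <- loo_fold_contributions(expr$values[usable, , drop = FALSE],
                                 expr$labels, zscore = zscore)
  dist_by_class <- lapply(prep$d2, colSums)
  cr_from_dist(dist_by_class, prep$labels, prep$class_levels)
}

#' Classification sweep over the top-n genes of a ranking
#'
#' Evaluates the LOO classification ratio using the `n` highest-ranked
#' genes present in the expression data, for every `n` in `n_grid`
#' (default: all of `1 ... length(ranking in expr)`), and records the
#' maximum CR together with the smallest subset size attaining it.
#'
#' @inheritParams nearest_centroid_loo_cr
#' @param ranking Ordered character vector of gene symbols, best first.
#' @param n_grid Optional integer vector of subset sizes; sizes exceeding
#'   the available genes are skipped with a log entry.
#' @param metric_name Label stored with the result.
#' @return An object of class `"sweep_result"`: list with `metric_name`,
#'   `n_values`, `cr_values`, `max_cr`, `argmax_n`.
#' @export
ranked_subset_sweep <- function(expr, ranking, n_grid = NULL, zscore = TRUE,
                                metric_name = "ranking") {
  stopifnot(inherits(expr, "labeled_expression"))
  if (!length(ranking)) stop("ranking is empty")
  ranking <- unique(toupper(trimws(ranking)))
  usable <- resolve_subset(expr, ranking)
  ranked <- ranking[ranking %in% usable]   # keep the ranking's order
  n_avail <- length(ranked)
  if (is.null(n_grid)) n_grid <- seq_len(n_avail)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 1L)) stop("subset sizes must be positive")
  skip <- n_grid > n_avail
  if (any(skip)) {
    ml_log("validation", "skipping %d subset size(s) beyond the %d available genes",
           sum(skip), n_avail)
    n_grid <- n_grid[!skip]
  }
  if (!length(n_grid)) stop("no usable subset sizes")
  prep <- loo_fold_contributions(expr$values[ranked, , drop = FALSE],
                                 expr$labels, zscore = zscore)
  cum <- lapply(prep$d2, function(m) {
    cm <- apply(m, 2L, cumsum)
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L)  # single-gene ranking
    cm
  })
  cr <- vapply(n_grid, function(n) {
    cr_from_dist(lapply(cum, function(m) m[n, ]),
                 prep$labels, prep$class_levels)
  }, numeric(1))
  max_cr <- max(cr)
  structure(list(metric_name = metric_name, n_values = n_grid,
                 cr_values = cr, max_cr = max_cr,
                 argmax_n = n_grid[which(cr == max_cr)[1L]]),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Ranked-subset sweep (%s): %d subset sizes\n",
              x$metric_name, length(x$n_values)))
  cat(sprintf("  max CR %.2f%% at n = %d genes\n", 100 * x$max_cr, x$argmax_n))
  invisible(x)
}

#' CR-versus-subset-size curve
#'
#' @param x A `sweep_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, ...) {
  graphics::plot(x$n_values, 100 * x$cr_values, type = "l",
                 xlab = "top-n genes", ylab = "classification ratio (%)",
                 main = x$metric_name, ...)
  graphics::points(x$argmax_n, 100 * x$max_cr, pch = 19)
  invisible(x)
}

#' Permutation test of a classification ratio
#'
#' Tests the null hypothesis that a randomly selected gene subset of the
#' same size classifies as well as the observed subset: each run draws
#' `n_genes` genes uniformly without replacement from the usable genes of
#' `expr`, computes the LOO CR, and the p-value is the fraction of runs
#' whose CR is greater than or equal to `observed_cr`. With
#' `smooth = TRUE` the (r+1)/(R+1) estimator is used instead, which
#' cannot return exactly 0.
#'
#' @inheritParams nearest_centroid_loo_cr
#' @param n_genes Subset size drawn in each run.
#' @param observed_cr Observed classification ratio in `[0, 1]`.
#' @param runs Number of permutation runs.
#' @param seed Optional integer seed; the result is deterministic given
#'   the seed.
#' @param smooth Use the add-one p-value estimator.
#' @return An object of class `"permutation_result"`: list with
#'   `observed_cr`, `runs`, `n_at_least`, `p_value`, `mean_permuted_cr`.
#' @export
permutation_test <- function(expr, n_genes, observed_cr, runs = 5000,
                             seed = NULL, zscore = TRUE, smooth = FALSE) {
  stopifnot(inherits(expr, "labeled_expression"))
  if (!is.numeric(observed_cr) || observed_cr < 0 || observed_cr > 1) {
    stop("observed_cr must lie in [0, 1]")
  }
  runs <- as.integer(runs)
  if (runs < 1L) stop("runs must be >= 1")
  pool <- expr$genes[!expr$incomplete]
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L || n_genes > length(pool)) {
    stop(sprintf("n_genes must lie in [1, %d] (usable genes)", length(pool)))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  prep <- loo_fold_contributions(expr$values[pool, , drop = FALSE],
                                 expr$labels, zscore = zscore)
  crs <- vapply(seq_len(runs), function(r) {
    sel <- sample.int(length(pool), n_genes)
    cr_from_dist(lapply(prep$d2, function(m) {
      colSums(m[sel, , drop = FALSE])
    }), prep$labels, prep$class_levels)
  }, numeric(1))
  n_at_least <- sum(crs >= observed_cr)
  p <- if (smooth) (n_at_least + 1) / (runs + 1) else n_at_least / runs
  structure(list(observed_cr = observed_cr, runs = runs,
                 n_at_least = n_at_least, p_value = p,
                 mean_permuted_cr = mean(crs)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed CR %.2f%%, mean permuted CR %.2f%% (%d runs)\n",
    100 * x$observed_cr, 100 * x$mean_permuted_cr, x$runs))
  cat(sprintf("  p-value = %g (%d run(s) with CR >= observed)\n",
              x$p_value, x$n_at_least))
  invisible(x)
}

#' Overlap of the top genes selected by different metrics
#'
#' Compares the recently reported genes (publication age at most
#' `ascore_threshold_years`; their count defines the subset size k) with
#' the k genes ranked highest by each of the other metrics, and reports
#' the requested intersections with per-metric score summaries
#' (mean and sd over each intersection).
#'
#' The `"ascore"` family denotes the novelty set itself (age ascending);
#' `"rscore"`, `"pscore"` and `"sscore"` take the top k by descending
#' score, ties broken by gene symbol.
#'
#' @param metrics A `marker_metrics` fit or its metric `data.frame`.
#' @param ascore_threshold_years Novelty cutoff in years (default 2).
#' @param combos List of character vectors naming the metric families to
#'   intersect; default: pscore/sscore, rscore/pscore/sscore and
#'   ascore/pscore/sscore.
#' @return An object of class `"cross_metrics"`: list with `k`,
#'   `threshold_years`, `top_sets` and `intersections` (each with
#'   `members`, `size` and `score_summary`).
#' @export
cross_metrics_overlap <- function(metrics, ascore_threshold_years = 2,
                                  combos = NULL) {
  if (inherits(metrics, "marker_metrics")) metrics <- metrics$table
  cols <- c("gene", "rscore", "ascore", "pscore", "sscore")
  stopifnot(all(cols %in% names(metrics)))
  if (anyNA(metrics[cols])) stop("metrics must be complete for all genes")
  novel <- metrics$gene[metrics$ascore <= ascore_threshold_years]
  k <- length(novel)
  if (k == 0L) {
    stop(sprintf("no novel genes at threshold %g years",
                 ascore_threshold_years))
  }
  top_sets <- list(
    rscore = metric_ranking(metrics, "rscore")[seq_len(k)],
    ascore = sort(novel),
    pscore = metric_ranking(metrics, "pscore")[seq_len(k)],
    sscore = metric_ranking(metrics, "sscore")[seq_len(k)]
  )
  if (is.null(combos)) {
    combos <- list(c("pscore", "sscore"),
                   c("rscore", "pscore", "sscore"),
                   c("ascore", "pscore", "sscore"))
  }
  score_summary <- function(genes) {
    sub <- metrics[metrics$gene %in% genes, , drop = FALSE]
    data.frame(metric = c("rscore", "ascore", "pscore", "sscore"),
               mean = vapply(c("rscore", "ascore", "pscore", "sscore"),
                             function(m) mean(sub[[m]]), numeric(1)),
               sd = vapply(c("rscore", "ascore", "pscore", "sscore"),
                           function(m) stats::sd(sub[[m]]), numeric(1)),
               row.names = NULL)
  }
  intersections <- lapply(combos, function(fam) {
    fam <- match.arg(fam, names(top_sets), several.ok = TRUE)
    members <- sort(Reduce(intersect, top_sets[fam]))
    list(families = fam, members = members, size = length(members),
         score_summary = if (length(members)) score_summary(members) else NULL)
  })
  names(intersections) <- vapply(combos, paste, character(1), collapse = "_")
  structure(list(k = k, threshold_years = ascore_threshold_years,
                 top_sets = top_sets, intersections = intersections),
            class = "cross_metrics")
}

#' @export
print.cross_metrics <- function(x, ...) {
  cat(sprintf("Cross-metrics overlap: k = %d (publication age <= %g years)\n",
              x$k, x$threshold_years))
  for (nm in names(x$intersections)) {
    cat(sprintf("  %s: %d gene(s)\n", nm, x$intersections[[nm]]$size))
  }
  invisible(x)
}

#' Write a sweep result as TSV curve plus JSON summary
#'
#' @param sweep A [ranked_subset_sweep()] result.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param permutation Optional [permutation_test()] result included in the
#'   JSON summary.
#' @param seed Optional seed recorded in the summary.
#' @return Invisibly, the JSON path.
#' @export
write_sweep_result <- function(sweep, path_prefix, permutation = NULL,
                               seed = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.table(data.frame(n = sweep$n_values, cr = sweep$cr_values),
                     paste0(path_prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_ <- list(metric = sweep$metric_name, max_cr = sweep$max_cr,
                   argmax_n = sweep$argmax_n)
  if (!is.null(permutation)) {
    summary_$permutation_p <- permutation$p_value
    summary_$runs <- permutation$runs
    summary_$mean_permuted_cr <- permutation$mean_permuted_cr
  }
  if (!is.null(seed)) summary_$seed <- seed
  jsonlite::write_json(summary_, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(path_prefix, ".json"))
}
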