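#' Analysis configuration
#'
#' Bundles the tunable parameters shared by the scoring and validation
#' stages. Defaults follow common practice for literature-curated gene
#' pools: equal weighting of degree and strength in the centrality
#' (`alpha = 0.5`), a stringent raw enrichment p cutoff combined with
#' Benjamini-Hochberg control, and 5000 permutation runs.
#'
#' @param current_date Reference date for publication-age computations
#'   (`Date` or ISO-8601 string). Ages are measured from this date.
#' @param alpha Centrality tuning parameter in (0, Inf). `alpha = 0`
#'   reduces the generalized centrality to node degree, `alpha = 1` to
#'   node strength; the default 0.5 weighs both equally.
#' @param pea_p_threshold Raw p-value cutoff for pathway enrichment.
#' @param snea_p_threshold Raw p-value cutoff for disease gene-set
#'   (sub-network surrogate) enrichment.
#' @param fdr_q Benjamini-Hochberg false discovery level applied on top of
#'   the raw cutoff.
#' @param permutation_runs Number of random gene subsets drawn by the
#'   permutation test.
#' @param rng_seed Integer seed controlling all randomized steps.
#' @param zscore_features Standardize each gene with training-fold mean and
#'   standard deviation before computing classification distances.
#' @return An object of class `"analysis_config"` (a named list).
#' @examples
#' cfg <- analysis_config(current_date = "2016-10-01", rng_seed = 7)
#' cfg$alpha
#' @export
analysis_config <- function(current_date = Sys.Date(),
                            alpha = 0.5,
                            pea_p_threshold = 1e-10,
                            snea_p_threshold = 1e-50,
                            fdr_q = 0.001,
                            permutation_runs = 5000,
                            rng_seed = 1L,
                            zscore_features = TRUE) {
  current_date <- as.Date(current_date)
  if (is.na(current_date)) stop("current_date is not a valid date")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  for (nm in c("pea_p_threshold", "snea_p_threshold", "fdr_q")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop(sprintf("%s must lie in (0, 1]", nm))
    }
  }
  permutation_runs <- as.integer(permutation_runs)
  if (is.na(permutation_runs) || permutation_runs < 1L) {
    stop("permutation_runs must be >= 1")
  }
  structure(
    list(
      current_date = current_date,
      alpha = alpha,
      pea_p_threshold = pea_p_threshold,
      snea_p_threshold = snea_p_threshold,
      fdr_q = fdr_q,
      permutation_runs = permutation_runs,
      rng_seed = as.integer(rng_seed),
      zscore_features = isTRUE(zscore_features)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  current_date      %s\n", format(x$current_date)))
  cat(sprintf("  alpha             %g\n", x$alpha))
  cat(sprintf("  pea_p_threshold   %g\n", x$pea_p_threshold))
  cat(sprintf("  snea_p_threshold  %g\n", x$snea_p_threshold))
  cat(sprintf("  fdr_q             %g\n", x$fdr_q))
  cat(sprintf("  permutation_runs  %d\n", x$permutation_runs))
  cat(sprintf("  rng_seed          %d\n", x$rng_seed))
  cat(sprintf("  zscore_features   %s\n", x$zscore_features))
  invisible(x)
}

# stage-tagged logging; all diagnostics go to stderr so stdout stays clean
# for piped tabular output
ml_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
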