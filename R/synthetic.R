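#' Specification for the synthetic data generators
#'
#' Collects the parameters of the download-free fixture generators. The
#' defaults emulate the statistical structure of a curated candidate-gene
#' pool for a complex psychiatric disorder: 535 candidate genes of which
#' about half carry a single supporting reference (long-tailed reference
#' counts), supporting publications spread over roughly a decade, gene
#' sets of 100-500 members drawn from a 20,044-gene annotation universe
#' with candidates over-represented, and a case/control expression matrix
#' (45 cases, 50 controls) with a planted standardized mean shift on a
#' core block of informative genes.
#'
#' @param n_genes Number of candidate genes.
#' @param ref_count_distribution Named numeric vector mapping a reference
#'   count to its proportion of genes; proportions must sum to 1.
#' @param date_window Length-2 `Date` (or string) vector: publication
#'   dates are uniform in `[start, end]`.
#' @param n_sets Number of gene sets in the pathway collection.
#' @param set_size_range Length-2 integer vector of set sizes (uniform).
#' @param universe_size Annotation background size; sets draw members
#'   from the whole universe, candidates at `candidate_enrichment`-fold
#'   elevated weight.
#' @param candidate_enrichment Sampling-weight ratio of candidate genes
#'   over background genes in set membership (makes sets genuinely
#'   enriched for the candidate pool).
#' @param co_membership_bias Additional weight multiplier `1 + bias` for
#'   the core (informative) genes, inflating their pathway co-membership
#'   and hence their network centrality. `0` removes the core effect.
#' @param n_cases,n_controls Expression sample sizes per class (each
#'   >= 2).
#' @param n_informative Number of core/informative genes (`<= n_genes`).
#' @param effect_size Standardized case-vs-control mean shift planted on
#'   informative genes (in units of `noise_sd`).
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param disease_id Disease identifier written into relation tables.
#' @param seed Integer master seed; each generator draws from its own
#'   substream (`seed` plus a fixed per-component offset), so changing
#'   one component's parameters does not perturb the others' draws.
#' @return An object of class `"synthetic_spec"` (a validated named
#'   list).
#' @export
synthetic_spec <- function(n_genes = 535,
                           ref_count_distribution = c(
                             "1" = 0.5140, "2" = 0.1645, "3" = 0.1103,
                             "4" = 0.0561, "5" = 0.0299,
                             "6" = 0.0600, "8" = 0.0300, "12" = 0.0200,
                             "20" = 0.0152),
                           date_window = as.Date(c("2004-01-01",
                                                   "2016-09-30")),
                           n_sets = 120,
                           set_size_range = c(100L, 500L),
                           universe_size = 20044,
                           candidate_enrichment = 8,
                           co_membership_bias = 4,
                           n_cases = 45, n_controls = 50,
                           n_informative = 25,
                           effect_size = 0.5,
                           noise_sd = 1,
                           disease_id = "D001",
                           seed = 101L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be positive")
  if (is.null(names(ref_count_distribution)) ||
      anyNA(suppressWarnings(as.integer(names(ref_count_distribution))))) {
    stop("ref_count_distribution must be named by integer reference counts")
  }
  if (abs(sum(ref_count_distribution) - 1) > 1e-9) {
    stop("ref_count_distribution proportions must sum to 1")
  }
  if (any(ref_count_distribution < 0)) stop("negative proportion")
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || anyNA(date_window)) {
    stop("date_window must be two valid dates")
  }
  set_size_range <- as.integer(set_size_range)
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1L) {
    stop("set_size_range must be increasing positive integers")
  }
  universe_size <- as.integer(universe_size)
  if (universe_size < n_genes) stop("universe_size must be >= n_genes")
  if (set_size_range[2] > universe_size) {
    stop("set_size_range max exceeds the universe")
  }
  if (co_membership_bias < 0) stop("co_membership_bias must be >= 0")
  if (candidate_enrichment < 1) stop("candidate_enrichment must be >= 1")
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases < 2L || n_controls < 2L) stop("each class needs >= 2 samples")
  n_informative <- as.integer(n_informative)
  if (n_informative < 0L || n_informative > n_genes) {
    stop("n_informative must lie in [0, n_genes]")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(
    n_genes = n_genes,
    ref_count_distribution = ref_count_distribution,
    date_window = date_window, n_sets = as.integer(n_sets),
    set_size_range = set_size_range, universe_size = universe_size,
    candidate_enrichment = candidate_enrichment,
    co_membership_bias = co_membership_bias,
    n_cases = n_cases, n_controls = n_controls,
    n_informative = n_informative, effect_size = effect_size,
    noise_sd = noise_sd, disease_id = disease_id,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

candidate_genes <- function(spec) sprintf("G%04d", seq_len(spec$n_genes))

core_genes <- function(spec) {
  candidate_genes(spec)[seq_len(spec$n_informative)]
}

universe_genes <- function(spec) {
  c(candidate_genes(spec),
    sprintf("U%05d", seq_len(spec$universe_size - spec$n_genes)))
}

# weighted sampling without replacement by the exponential-race
# construction: the k smallest rexp(n)/w indices form a weighted sample
weighted_sample <- function(n, k, w) {
  order(stats::rexp(n) / w)[seq_len(k)]
}

uniform_dates <- function(n, window) {
  ndays <- as.integer(window[2] - window[1]) + 1L
  window[1] + (sample.int(ndays, n, replace = TRUE) - 1L)
}

#' Simulate a gene-disease relation table
#'
#' Per-gene reference counts are drawn from
#' `spec$ref_count_distribution`; each reference gets a unique id and a
#' publication date uniform in `spec$date_window`. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `relation_table` data.frame.
#' @export
simulate_relation_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$date_window[2] < spec$date_window[1]) {
    stop("empty date window")
  }
  set.seed(spec$seed + 1L)
  counts <- sample(as.integer(names(spec$ref_count_distribution)),
                   spec$n_genes, replace = TRUE,
                   prob = spec$ref_count_distribution)
  genes <- candidate_genes(spec)
  total <- sum(counts)
  tab <- data.frame(
    gene = rep(genes, counts),
    disease_id = spec$disease_id,
    reference_id = sprintf("R%06d", seq_len(total)),
    pub_date = uniform_dates(total, spec$date_window),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("relation_table", "data.frame")
  tab
}

#' Simulate an overlapping gene-set collection
#'
#' Draws `spec$n_sets` sets with sizes uniform in `spec$set_size_range`
#' from the annotation universe. Candidate genes carry
#' `spec$candidate_enrichment`-fold sampling weight (so the candidate
#' pool is genuinely over-represented, as a disease pathway collection
#' would be), and the core genes an additional
#' `1 + spec$co_membership_bias` multiplier, which drives their pathway
#' co-membership — and hence PScore and network centrality — above the
#' non-core candidates. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param prefix Set-name prefix.
#' @param category Category string stored for every set.
#' @param seed_offset Substream offset added to `spec$seed`.
#' @return A [gene_set_collection()].
#' @export
simulate_geneset_collection <- function(spec, prefix = "S",
                                        category = "synthetic_pathway",
                                        seed_offset = 2L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + as.integer(seed_offset))
  pool <- universe_genes(spec)
  w <- rep(1, length(pool))
  w[seq_len(spec$n_genes)] <- spec$candidate_enrichment
  if (spec$n_informative > 0L) {
    w[seq_len(spec$n_informative)] <-
      spec$candidate_enrichment * (1 + spec$co_membership_bias)
  }
  size_choices <- seq(spec$set_size_range[1], spec$set_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), spec$n_sets,
                                   replace = TRUE)]
  sets <- lapply(sizes, function(k) pool[weighted_sample(length(pool), k, w)])
  names(sets) <- sprintf("%s%03d", prefix, seq_along(sets))
  gene_set_collection(sets, spec$universe_size,
                      category = stats::setNames(rep(category, length(sets)),
                                                 names(sets)))
}

#' Simulate a case/control expression matrix
#'
#' Background values are i.i.d. Gaussian with standard deviation
#' `spec$noise_sd`; informative genes receive an additional
#' `spec$effect_size * spec$noise_sd` in the case samples. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param informative_genes Genes carrying the planted shift; defaults to
#'   the spec's core genes. Must be a subset of the candidate genes.
#' @return A [labeled_expression()] object (classes `"case"` and
#'   `"control"`).
#' @export
simulate_expression <- function(spec, informative_genes = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  genes <- candidate_genes(spec)
  if (is.null(informative_genes)) informative_genes <- core_genes(spec)
  if (!all(informative_genes %in% genes)) {
    stop("informative_genes must be a subset of the candidate genes")
  }
  set.seed(spec$seed + 3L)
  n_samples <- spec$n_cases + spec$n_controls
  values <- matrix(stats::rnorm(spec$n_genes * n_samples, 0, spec$noise_sd),
                   nrow = spec$n_genes,
                   dimnames = list(genes,
                                   c(sprintf("case_%02d", seq_len(spec$n_cases)),
                                     sprintf("control_%02d",
                                             seq_len(spec$n_controls)))))
  case_cols <- seq_len(spec$n_cases)
  values[informative_genes, case_cols] <-
    values[informative_genes, case_cols] + spec$effect_size * spec$noise_sd
  labeled_expression(values,
                     rep(c("case", "control"),
                         c(spec$n_cases, spec$n_controls)))
}

#' Generate a coherent end-to-end fixture with known ground truth
#'
#' Produces a relation table, a pathway collection, a disease gene-set
#' collection and a labeled expression matrix in which the planted
#' (informative) genes should rank highly under all four metrics: they
#' are the core genes of the set generator (high co-membership, hence
#' high PScore and SScore), they carry inflated reference counts
#' (15 + Poisson(20), emulating long-studied genes, hence high RScore),
#' their earliest reference predates the generic date window by up to 12
#' years (hence high publication age, i.e. a top descending-AScore
#' rank), and they carry the planted case/control expression shift.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `relations`, `pathways`,
#'   `disease_sets`, `expression`, `disease_id`, `truth` (list with
#'   `planted`, the core gene symbols) and `spec`.
#' @export
end_to_end_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_informative < 1L) stop("end_to_end_fixture needs n_informative >= 1")
  core <- core_genes(spec)
  genes <- candidate_genes(spec)

  set.seed(spec$seed + 11L)
  counts <- sample(as.integer(names(spec$ref_count_distribution)),
                   spec$n_genes, replace = TRUE,
                   prob = spec$ref_count_distribution)
  names(counts) <- genes
  counts[core] <- 15L + stats::rpois(length(core), 20)
  total <- sum(counts)
  tab <- data.frame(
    gene = rep(genes, counts),
    disease_id = spec$disease_id,
    reference_id = sprintf("R%06d", seq_len(total)),
    pub_date = uniform_dates(total, spec$date_window),
    stringsAsFactors = FALSE
  )
  # plant one early reference per core gene: first report up to 12 years
  # before the generic window opens
  early_window <- c(spec$date_window[1] - 4383L, spec$date_window[1])
  first_rows <- match(core, tab$gene)
  tab$pub_date[first_rows] <- uniform_dates(length(core), early_window)
  class(tab) <- c("relation_table", "data.frame")

  pathways <- simulate_geneset_collection(spec)
  spec_d <- spec
  spec_d$n_sets <- max(10L, as.integer(round(spec$n_sets / 4)))
  disease_sets <- simulate_geneset_collection(spec_d, prefix = "DS",
                                              category = "synthetic_disease",
                                              seed_offset = 7L)
  expression <- simulate_expression(spec, core)
  list(relations = tab, pathways = pathways, disease_sets = disease_sets,
       expression = expression, disease_id = spec$disease_id,
       truth = list(planted = core), spec = spec)
}
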