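test_that("all generators are bit-reproducible given the spec seed", {
  spec <- small_spec(seed = 77)
  expect_identical(simulate_relation_table(spec),
                   simulate_relation_table(spec))
  expect_identical(simulate_geneset_collection(spec),
                   simulate_geneset_collection(spec))
  e1 <- simulate_expression(spec)
  e2 <- simulate_expression(spec)
  expect_identical(e1$values, e2$values)
  f1 <- end_to_end_fixture(spec)
  f2 <- end_to_end_fixture(spec)
  expect_identical(as.data.frame(f1$relations), as.data.frame(f2$relations))
  expect_identical(f1$pathways$sets, f2$pathways$sets)
  expect_identical(f1$expression$values, f2$expression$values)
})

test_that("a degenerate reference-count distribution is honored exactly", {
  spec <- small_spec(seed = 2)
  spec$ref_count_distribution <- c("1" = 1.0)
  tab <- simulate_relation_table(spec)
  rs <- compute_rscore(tab, spec$disease_id)
  expect_true(all(rs == 1L))
  expect_length(rs, spec$n_genes)
})

test_that("reference counts follow the long-tailed distribution at scale", {
  spec <- synthetic_spec(n_genes = 5000, seed = 33)
  rs <- compute_rscore(simulate_relation_table(spec), spec$disease_id)
  emp <- table(factor(pmin(rs, 6), levels = 1:6)) / length(rs)
  want <- spec$ref_count_distribution
  expect_equal(unname(emp[["1"]]), unname(want[["1"]]), tolerance = 0.05)
  expect_equal(unname(emp[["6"]]),
               sum(want[as.integer(names(want)) >= 6]), tolerance = 0.05)
})

test_that("generated tables round-trip through the readers silently", {
  spec <- small_spec(seed = 4)
  fx <- end_to_end_fixture(spec)
  rp <- tempfile(fileext = ".tsv")
  write_relation_table(fx$relations, rp)
  expect_no_message(rel <- read_relation_table(rp))
  expect_equal(as.data.frame(rel), as.data.frame(fx$relations))
  gp <- tempfile(fileext = ".gmt")
  write_gmt(fx$pathways, gp)
  expect_no_message(col <- read_gmt(gp, spec$universe_size))
  expect_equal(col$sets, fx$pathways$sets)
  mp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(fx$expression, mp, lp)
  expect_no_message(expr <- read_expression(mp, lp))
  expect_equal(expr$values, fx$expression$values, tolerance = 1e-12)
  expect_equal(as.character(expr$labels), as.character(fx$expression$labels))
})

test_that("unbiased set sampling matches the analytic co-membership rate", {
  # with uniform weights, P(two given genes share a size-k set) is
  # k(k-1) / (n(n-1)); compare the mean pairwise weight to expectation
  spec <- synthetic_spec(n_genes = 40, universe_size = 40, n_sets = 300,
                         set_size_range = c(10, 10),
                         candidate_enrichment = 1, co_membership_bias = 0,
                         n_informative = 5, seed = 21)
  col <- simulate_geneset_collection(spec)
  net <- build_ggi_network(sprintf("G%04d", 1:40), col$sets)
  expected <- spec$n_sets * 10 * 9 / (40 * 39)
  observed <- mean(net$weights[upper.tri(net$weights)])
  expect_equal(observed, expected, tolerance = 0.1)
})

test_that("core genes dominate the centrality score under strong bias", {
  hits <- 0L
  for (s in 1:10) {
    spec <- synthetic_spec(n_genes = 60, universe_size = 600, n_sets = 40,
                           set_size_range = c(15, 30), n_informative = 10,
                           co_membership_bias = 6, seed = 400 + s)
    col <- simulate_geneset_collection(spec)
    net <- build_ggi_network(sprintf("G%04d", 1:60), col$sets)
    ss <- compute_sscores(net, 0.5)
    core <- ss$gene %in% sprintf("G%04d", 1:10)
    if (mean(ss$sscore[core]) > 1 && mean(ss$sscore[!core]) < 1) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("planted expression signal drives classification power", {
  wins <- 0L
  for (s in 1:20) {
    spec <- synthetic_spec(n_genes = 200, n_cases = 50, n_controls = 50,
                           n_informative = 20, effect_size = 2,
                           seed = 900 + s)
    expr <- simulate_expression(spec)
    cr <- nearest_centroid_loo_cr(expr, sprintf("G%04d", 1:20))
    if (cr > 0.9) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("a null effect leaves classification at chance", {
  crs <- vapply(1:15, function(s) {
    spec <- synthetic_spec(n_genes = 100, n_cases = 30, n_controls = 30,
                           n_informative = 10, effect_size = 0,
                           seed = 700 + s)
    expr <- simulate_expression(spec)
    nearest_centroid_loo_cr(expr, sprintf("G%04d", 1:10))
  }, numeric(1))
  expect_lt(abs(mean(crs) - 0.5), 0.1)
})

test_that("every metric recovers the planted genes on the default design", {
  cfg <- analysis_config(current_date = "2016-10-01")
  recov <- matrix(NA_real_, 10, 4,
                  dimnames = list(NULL, c("rscore", "ascore", "pscore",
                                          "sscore")))
  for (s in 1:10) {
    fx <- end_to_end_fixture(synthetic_spec(seed = 1200 + s))
    fit <- suppressMessages(
      marker_metrics(fx$relations, fx$disease_id, fx$pathways, config = cfg))
    k <- length(fx$truth$planted)
    for (m in colnames(recov)) {
      top <- metric_ranking(fit, m)[seq_len(k)]
      recov[s, m] <- mean(fx$truth$planted %in% top)
    }
  }
  expect_true(all(colMeans(recov) > 0.8))
})

test_that("recovery is at chance without planted signal", {
  spec <- synthetic_spec(n_genes = 150, universe_size = 3000, n_sets = 30,
                         set_size_range = c(30, 80), n_informative = 15,
                         co_membership_bias = 0, effect_size = 0, seed = 55)
  fx <- end_to_end_fixture(spec)
  # neutralize the literature planting too: regenerate relations unbiased
  rel <- simulate_relation_table(spec)
  cfg <- analysis_config(current_date = "2016-10-01")
  fit <- suppressMessages(
    marker_metrics(rel, spec$disease_id, fx$pathways, config = cfg))
  top <- metric_ranking(fit, "sscore")[seq_len(15)]
  expect_lt(mean(fx$truth$planted %in% top), 0.5)
})

test_that("an empty date window is rejected", {
  spec <- small_spec(seed = 3)
  spec$date_window <- as.Date(c("2016-01-01", "2015-01-01"))
  expect_error(simulate_relation_table(spec), "empty date window")
})

test_that("spec validation guards its invariants", {
  expect_error(synthetic_spec(ref_count_distribution = c("1" = 0.6,
                                                         "2" = 0.3)),
               "sum to 1")
  expect_error(synthetic_spec(n_informative = 600), "n_informative")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(set_size_range = c(100, 50000)), "universe")
  expect_error(synthetic_spec(n_cases = 1), ">= 2")
})
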