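test_that("a hand-run 4-fold fixture classifies perfectly", {
  # one gene, values 0,1 (class a) and 10,11 (class b): every held-out
  # sample sits nearer its own class centroid
  expr <- make_expr(matrix(c(0, 1, 10, 11), 1, 4), c("a", "a", "b", "b"))
  expect_equal(nearest_centroid_loo_cr(expr, expr$genes), 1)
  expect_equal(nearest_centroid_loo_cr(expr, expr$genes, zscore = FALSE), 1)
})

test_that("widely shifted constant profiles separate perfectly", {
  set.seed(2)
  values <- matrix(rnorm(5 * 10, sd = 0.01), 5, 10)
  values[, 1:5] <- values[, 1:5] + 100
  expr <- make_expr(values, rep(c("a", "b"), each = 5))
  expect_equal(nearest_centroid_loo_cr(expr, expr$genes), 1)
})

test_that("the fold machinery agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    n_a <- sample.int(n - 3, 1) + 1L   # 2 .. n-2, so both classes have >= 2
    g <- sample(1:5, 1)
    values <- matrix(rnorm(g * n), g, n)
    labels <- sample(rep(c("a", "b"), c(n_a, n - n_a)))
    expr <- make_expr(values, labels)
    for (z in c(TRUE, FALSE)) {
      expect_equal(nearest_centroid_loo_cr(expr, expr$genes, zscore = z),
                   loo_cr_oracle(values, labels, zscore = z))
    }
  }
})

test_that("degenerate classification inputs are rejected", {
  expr <- make_expr(matrix(rnorm(12), 3, 4), c("a", "a", "b", "b"))
  expect_error(nearest_centroid_loo_cr(expr, c("NOPE")), "usable")
  one <- make_expr(matrix(rnorm(12), 3, 4), c("a", "b", "b", "b"))
  expect_error(nearest_centroid_loo_cr(one, one$genes), "at least 2")
})

test_that("the sweep at full size reproduces the all-genes ratio", {
  set.seed(5)
  expr <- make_expr(matrix(rnorm(8 * 12), 8, 12),
                    rep(c("a", "b"), each = 6))
  sw <- ranked_subset_sweep(expr, sample(expr$genes))
  expect_equal(sw$cr_values[length(sw$cr_values)],
               nearest_centroid_loo_cr(expr, expr$genes))
  expect_equal(sw$max_cr, max(sw$cr_values))
  expect_true(sw$argmax_n %in% sw$n_values)
  # smallest argmax rule
  expect_equal(sw$argmax_n, min(sw$n_values[sw$cr_values == sw$max_cr]))
})

test_that("a constant matrix gives the same ratio at every subset size", {
  expr <- make_expr(matrix(5, 6, 8), rep(c("a", "b"), each = 4))
  sw <- ranked_subset_sweep(expr, expr$genes)
  expect_equal(length(unique(sw$cr_values)), 1L)
  # ties go to the lexicographically first class -> all predicted "a"
  expect_equal(sw$cr_values[1], 0.5)
})

test_that("subset sizes beyond the available genes are skipped", {
  set.seed(6)
  expr <- make_expr(matrix(rnorm(4 * 8), 4, 8), rep(c("a", "b"), each = 4))
  expect_message(
    sw <- ranked_subset_sweep(expr, expr$genes, n_grid = c(2, 4, 9)),
    "skipping")
  expect_equal(sw$n_values, c(2L, 4L))
})

test_that("a sweep with planted informative genes peaks early", {
  # a modest signal on 10 of 300 genes: the all-genes panel dilutes it
  spec <- synthetic_spec(n_genes = 300, universe_size = 3000,
                         n_informative = 10, effect_size = 1.2,
                         n_cases = 15, n_controls = 15, seed = 8)
  expr <- simulate_expression(spec)
  planted <- sprintf("G%04d", seq_len(spec$n_informative))
  ranking <- c(planted, setdiff(expr$genes, planted))
  sw <- ranked_subset_sweep(expr, ranking)
  expect_gt(sw$max_cr, sw$cr_values[length(sw$cr_values)])
  expect_lte(sw$argmax_n, 5 * spec$n_informative)
})

test_that("the permutation test is deterministic and bounded", {
  set.seed(9)
  expr <- make_expr(matrix(rnorm(20 * 12), 20, 12),
                    rep(c("a", "b"), each = 6))
  p1 <- permutation_test(expr, 5, observed_cr = 0, runs = 50, seed = 3)
  expect_equal(p1$p_value, 1)  # every permuted CR >= 0
  p2 <- permutation_test(expr, 5, observed_cr = 0.9, runs = 50, seed = 3)
  p3 <- permutation_test(expr, 5, observed_cr = 0.9, runs = 50, seed = 3)
  expect_equal(p2$p_value, p3$p_value)
  expect_equal(p2$n_at_least / p2$runs, p2$p_value)
  psm <- permutation_test(expr, 5, observed_cr = 1, runs = 50, seed = 3,
                          smooth = TRUE)
  expect_gt(psm$p_value, 0)
  expect_error(permutation_test(expr, 5, observed_cr = 1.2, runs = 10),
               "0, 1")
})

test_that("a perfectly separating subset beats noise permutations", {
  # 10 strongly informative genes in a 500-gene pool: random same-size
  # subsets rarely pick up enough of them to match
  spec <- synthetic_spec(n_genes = 500, universe_size = 5000,
                         n_informative = 10, effect_size = 3,
                         n_cases = 12, n_controls = 12, seed = 12)
  expr <- simulate_expression(spec)
  planted <- sprintf("G%04d", seq_len(spec$n_informative))
  obs <- nearest_centroid_loo_cr(expr, planted)
  expect_equal(obs, 1)
  pt <- permutation_test(expr, length(planted), obs, runs = 200, seed = 4)
  expect_lt(pt$p_value, 0.05)
})

test_that("cross-metrics intersections follow set arithmetic", {
  genes <- sprintf("g%02d", 1:15)
  metrics <- data.frame(
    gene = genes,
    rscore = 15:1,
    ascore = c(rep(1, 10), rep(5, 5)),        # novelty set = g01..g10
    pscore = c(15:6, 5:1),                    # top 10 = g01..g10
    sscore = c(1:5, 15:6) / 15,               # top 10 = g06..g15
    stringsAsFactors = FALSE
  )
  cm <- cross_metrics_overlap(metrics, 2, combos = list(c("pscore", "sscore")))
  expect_equal(cm$k, 10L)
  expect_equal(cm$top_sets$pscore, sort(genes[1:10]))
  expect_equal(cm$intersections$pscore_sscore$size, 5L)
  expect_equal(cm$intersections$pscore_sscore$members, genes[6:10])
  summ <- cm$intersections$pscore_sscore$score_summary
  rs <- 15:1
  expect_equal(summ$mean[summ$metric == "rscore"], mean(rs[6:10]))
})

test_that("identical rankings intersect fully; no novel genes errors", {
  genes <- sprintf("g%02d", 1:8)
  metrics <- data.frame(gene = genes, rscore = 8:1, ascore = rep(1, 8),
                        pscore = 8:1, sscore = (8:1) / 4.5,
                        stringsAsFactors = FALSE)
  cm <- cross_metrics_overlap(metrics, 2)
  for (it in cm$intersections) expect_equal(it$size, cm$k)
  metrics$ascore <- 10
  expect_error(cross_metrics_overlap(metrics, 2), "no novel genes")
})

test_that("sweep results export as a TSV curve and JSON summary", {
  set.seed(13)
  expr <- make_expr(matrix(rnorm(6 * 10), 6, 10),
                    rep(c("a", "b"), each = 5))
  sw <- ranked_subset_sweep(expr, expr$genes, metric_name = "demo")
  pt <- permutation_test(expr, sw$argmax_n, sw$max_cr, runs = 20, seed = 1)
  prefix <- tempfile()
  write_sweep_result(sw, prefix, permutation = pt, seed = 1)
  curve <- utils::read.delim(paste0(prefix, ".tsv"))
  expect_equal(curve$n, sw$n_values)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$metric, "demo")
  expect_equal(js$max_cr, sw$max_cr)
  expect_equal(js$runs, 20L)
})
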