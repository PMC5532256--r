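test_that("edge weights count shared significant sets", {
  sets <- list(P1 = c("A", "B"), P2 = c("A", "B", "C"), P3 = c("A"))
  net <- build_ggi_network(c("A", "B", "C"), sets)
  expect_equal(net$weights["A", "B"], 2L)
  expect_equal(net$weights["B", "C"], 1L)
  expect_equal(diag(net$weights), c(A = 0L, B = 0L, C = 0L))
  # genes sharing no set stay unconnected
  net2 <- build_ggi_network(c("A", "Z"), sets)
  expect_equal(net2$weights["A", "Z"], 0L)
  expect_error(build_ggi_network(c("A", "A"), sets), "duplicate")
})

test_that("a 4x3 membership fixture reproduces the hand-computed matrix", {
  sets <- list(S1 = c("A", "B", "D"), S2 = c("A", "B", "C"), S3 = c("B", "D"))
  net <- build_ggi_network(c("A", "B", "C", "D"), sets)
  hand <- matrix(c(0, 2, 1, 1,
                   2, 0, 1, 2,
                   1, 1, 0, 0,
                   1, 2, 0, 0), 4, 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"),
                                 c("A", "B", "C", "D")))
  expect_equal(unname(net$weights), unname(hand))
})

test_that("edge weights equal brute-force pairwise intersection counts", {
  set.seed(7)
  for (i in 1:10) {
    genes <- sprintf("G%02d", seq_len(sample(4:10, 1)))
    sets <- lapply(seq_len(sample(2:6, 1)), function(k) {
      sample(genes, sample(2:length(genes), 1))
    })
    names(sets) <- paste0("s", seq_along(sets))
    net <- build_ggi_network(genes, sets)
    expect_equal(net$weights, co_membership_oracle(genes, sets))
  }
})

test_that("a single-member set changes no edge weight", {
  sets <- list(S1 = c("A", "B"), S2 = c("A", "C"))
  w1 <- build_ggi_network(c("A", "B", "C"), sets)$weights
  w2 <- build_ggi_network(c("A", "B", "C"), c(sets, list(S3 = "A")))$weights
  expect_equal(w2, w1)
})

test_that("generalized centrality interpolates degree and strength", {
  expect_equal(generalized_centrality(4, 16, 0.5), 8)
  expect_equal(generalized_centrality(3, 7, 0), 3)
  expect_equal(generalized_centrality(3, 7, 1), 7)
  expect_equal(generalized_centrality(3, 7, 0.5), sqrt(21))
  expect_equal(generalized_centrality(0, 0, 0.5), 0)
  expect_error(generalized_centrality(-1, 0, 0.5), "negative")
  expect_error(generalized_centrality(0, 2, 0.5), "strength")
})

test_that("the 3-node path yields the worked normalized scores", {
  sets <- list(P1 = c("A", "B"), P2 = c("B", "C"))
  net <- build_ggi_network(c("A", "B", "C"), sets)
  cs <- compute_sscores(net, alpha = 0.5)
  expect_equal(cs$degree, c(1L, 2L, 1L))
  expect_equal(cs$strength, c(1, 2, 1))
  expect_identical(cs$sscore, c(0.75, 1.5, 0.75))
  # appending an isolated node renormalizes over N = 4
  net4 <- build_ggi_network(c("A", "B", "C", "Z"), sets)
  cs4 <- compute_sscores(net4, alpha = 0.5)
  expect_identical(cs4$sscore, c(1, 2, 1, 0))
})

test_that("identical centralities normalize to 1 and isolation errors out", {
  net <- build_ggi_network(c("A", "B"), list(S = c("A", "B")))
  expect_equal(compute_sscores(net)$sscore, c(1, 1))
  lonely <- build_ggi_network(c("A", "B"), list(S = "A"))
  expect_error(compute_sscores(lonely), "isolated")
})

test_that("normalized scores sum to the node count on random networks", {
  set.seed(19)
  for (i in 1:40) {
    genes <- sprintf("G%02d", seq_len(sample(3:25, 1)))
    sets <- lapply(seq_len(sample(2:8, 1)), function(k) {
      sample(genes, sample(2:length(genes), 1))
    })
    net <- build_ggi_network(genes, sets)
    cs <- compute_sscores(net, alpha = runif(1, 0.1, 1.5))
    expect_equal(sum(cs$sscore), length(genes), tolerance = 1e-9)
  }
})

test_that("edge-list export round-trips, keeping isolated nodes", {
  sets <- list(S1 = c("A", "B"), S2 = c("B", "C"), S3 = c("A", "B"))
  net <- build_ggi_network(c("A", "B", "C", "Z"), sets)
  path <- tempfile(fileext = ".tsv")
  export_network(net, path)
  edges <- utils::read.delim(path)
  expect_equal(nrow(edges), 2L)
  expect_true(all(edges$gene_a < edges$gene_b))
  expect_false(is.unsorted(edges$gene_a))
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"))$gene
  expect_true("Z" %in% nodes)
  back <- read_network(path)
  expect_equal(back$weights[net$genes, net$genes], net$weights)
})
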