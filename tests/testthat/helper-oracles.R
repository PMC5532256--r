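# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (phyper, p.adjust, the vectorized fold machinery) so that
# agreement is a genuine cross-check.

# upper hypergeometric tail by direct PMF summation with choose()
hyper_tail_oracle <- function(query, set, overlap, universe) {
  ks <- seq(overlap, min(query, set))
  sum(choose(set, ks) * choose(universe - set, query - ks)) /
    choose(universe, query)
}

# Benjamini-Hochberg step-up by its textbook definition
bh_pass_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) / m * q)
  pass <- rep(FALSE, m)
  if (length(below)) pass[o[seq_len(max(below))]] <- TRUE
  pass
}

# leave-one-out nearest-centroid CR with explicit loops over folds and
# classes
loo_cr_oracle <- function(values, labels, zscore = TRUE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  n <- ncol(values)
  correct <- logical(n)
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    xtr <- values[, tr, drop = FALSE]
    if (zscore) {
      m <- apply(xtr, 1, mean)
      sdv <- apply(xtr, 1, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
    } else {
      m <- rep(0, nrow(values))
      sdv <- rep(1, nrow(values))
    }
    dists <- vapply(classes, function(cl) {
      cen <- apply(xtr[, labels[tr] == cl, drop = FALSE], 1, mean)
      sqrt(sum(((values[, s] - m) / sdv - (cen - m) / sdv)^2))
    }, numeric(1))
    pred <- classes[which(dists == min(dists))[1]]
    correct[s] <- pred == labels[s]
  }
  mean(correct)
}

# pairwise shared-set counts by explicit double loop
co_membership_oracle <- function(genes, sets) {
  n <- length(genes)
  w <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w[i, j] <- sum(vapply(sets, function(m) {
        genes[i] %in% m && genes[j] %in% m
      }, logical(1)))
    }
  }
  w
}
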