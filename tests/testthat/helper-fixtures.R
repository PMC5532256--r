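# small programmatic fixtures shared across test files

write_relation_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("gene", "disease_id", "reference_id", "pub_date")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_fixture <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

make_expr <- function(values, labels) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  labeled_expression(values, labels)
}

# a small, quick study design used where the full default would be
# needlessly slow
small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_genes = 60, n_sets = 20, universe_size = 2000,
                 set_size_range = c(20, 60), n_informative = 8,
                 n_cases = 12, n_controls = 12, seed = seed, ...)
}
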