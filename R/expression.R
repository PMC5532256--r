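#' Construct a labeled expression object
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols, made
#'   uppercase), samples in columns (colnames = sample ids).
#' @param labels Per-sample class labels (character or factor), aligned to
#'   the columns of `values`; two or more classes.
#' @return An object of class `"labeled_expression"` with components
#'   `genes`, `samples`, `values`, `labels` (factor) and `incomplete`
#'   (logical per gene: `TRUE` if the gene has any missing value).
#' @export
labeled_expression <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  rownames(values) <- toupper(trimws(rownames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (length(labels) != ncol(values)) {
    stop("labels length does not match the number of samples")
  }
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least two sample classes")
  incomplete <- apply(values, 1L, anyNA)
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, labels = labels, incomplete = incomplete),
            class = "labeled_expression")
}

#' Read a case/control expression matrix with sample labels
#'
#' The canonical dialect is a plain TSV: first column gene symbols, one
#' numeric column per sample, with a header of sample ids. A minimal GEO
#' series-matrix dialect (the table between `!series_matrix_table_begin`
#' and `!series_matrix_table_end`) is accepted behind
#' `geo_series_matrix = TRUE`.
#'
#' Genes containing any missing value are flagged `incomplete` and are
#' excluded from classification subsets downstream (with a log entry),
#' mirroring the usual treatment of probes that failed on part of a
#' platform.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to a two-column TSV (`sample`, `label`) mapping
#'   every matrix sample to its class.
#' @param geo_series_matrix Parse the matrix file as a GEO series matrix.
#' @return A [labeled_expression()] object.
#' @export
read_expression <- function(matrix_path, labels_path,
                            geo_series_matrix = FALSE) {
  if (!file.exists(matrix_path)) stop("file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("file not found: ", labels_path)
  if (geo_series_matrix) {
    lines <- readLines(matrix_path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
      stop("series-matrix table delimiters not found in ", matrix_path)
    }
    txt <- lines[(beg + 1L):(end - 1L)]
    raw <- utils::read.delim(text = txt, colClasses = "character",
                             check.names = FALSE)
  } else {
    raw <- utils::read.delim(matrix_path, colClasses = "character",
                             check.names = FALSE)
  }
  if (ncol(raw) < 2L) stop("expression matrix needs a gene column and >= 1 sample")
  genes <- toupper(trimws(raw[[1L]]))
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol(s) in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  cells <- as.matrix(raw[-1L])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells) &
                 !toupper(trimws(cells)) %in% c("NA", ""), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value %s at gene %s, sample %s",
                 dQuote(cells[bad[1, 1], bad[1, 2]]),
                 genes[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, colnames(raw)[-1L])

  lab <- utils::read.delim(labels_path, colClasses = "character",
                           check.names = FALSE)
  if (ncol(lab) < 2L) stop("labels file needs two columns: sample, label")
  key <- stats::setNames(trimws(lab[[2L]]), trimws(lab[[1L]]))
  missing <- setdiff(colnames(num), names(key))
  if (length(missing)) {
    stop("sample(s) absent from labels file: ", paste(missing, collapse = ", "))
  }
  obj <- labeled_expression(num, key[colnames(num)])
  if (any(obj$incomplete)) {
    ml_log("expression", "%d gene(s) flagged incomplete (missing values)",
           sum(obj$incomplete))
  }
  obj
}

#' Write an expression object back to the TSV dialect
#'
#' @param expr A `labeled_expression`.
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(expr, matrix_path, labels_path) {
  stopifnot(inherits(expr, "labeled_expression"))
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = expr$samples, label = as.character(expr$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("Labeled expression: %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  if (any(x$incomplete)) {
    cat(sprintf("  %d gene(s) incomplete\n", sum(x$incomplete)))
  }
  invisible(x)
}

#' @export
dim.labeled_expression <- function(x) dim(x$values)
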