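#' Read a gene-set collection in GMT format
#'
#' Each GMT line is `name <tab> description <tab> member1 <tab> member2 ...`.
#' Members are uppercased; duplicates within a line are collapsed. The
#' description field is stored as the set's category (e.g. a GO namespace).
#'
#' The annotation background size (`universe_size`) is a required, explicit
#' input: enrichment p-values are not reproducible without it, so no
#' default is supplied.
#'
#' @param path Path to the GMT file.
#' @param universe_size Total number of genes in the annotation background;
#'   must be at least the size of the union of all members.
#' @return An object of class `"gene_set_collection"`: a list with
#'   `sets` (named list of character vectors), `category` (named character),
#'   and `universe_size`.
#' @seealso [enrich_collection()], [write_gmt()]
#' @export
read_gmt <- function(path, universe_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT format error: file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT format error: fewer than 3 fields at line %d",
                 which(nf < 3L)[1]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("GMT format error: duplicate set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  category <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(toupper(trimws(f[-(1:2)]))))
  names(sets) <- names_
  names(category) <- names_
  gene_set_collection(sets, universe_size, category = category)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe_size Positive integer annotation background size.
#' @param category Optional named character vector of set categories.
#' @return A `"gene_set_collection"` object.
#' @export
gene_set_collection <- function(sets, universe_size, category = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate set name(s)")
  sets <- lapply(sets, function(m) unique(toupper(trimws(m))))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  universe_size <- as.integer(universe_size)
  n_union <- length(unique(unlist(sets, use.names = FALSE)))
  if (is.na(universe_size) || universe_size < 1L) {
    stop("universe_size must be a positive integer")
  }
  if (universe_size < n_union) {
    stop(sprintf("universe_size (%d) smaller than the union of all members (%d)",
                 universe_size, n_union))
  }
  if (is.null(category)) {
    category <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  }
  structure(list(sets = sets, category = category,
                 universe_size = universe_size),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  cat_ <- collection$category
  cat_[is.na(cat_)] <- "na"
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], cat_[i], collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("Gene-set collection: %d sets (sizes %d-%d), universe %d genes\n",
              length(x$sets), min(sz), max(sz), x$universe_size))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
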