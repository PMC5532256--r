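#' Read a gene-disease relation table
#'
#' Loads tab-separated literature evidence rows, one per supporting
#' reference of a gene-disease relationship. Gene symbols are trimmed and
#' uppercased; rows duplicated on (gene, disease_id, reference_id) are
#' dropped (a relationship asserted twice by the same article counts once).
#'
#' Publication dates are ISO-8601; month-only (`"2015-03"`) and year-only
#' (`"2015"`) dates resolve to the first day of the period, with a log
#' entry.
#'
#' @param path Path to a TSV file with header columns `gene`,
#'   `disease_id`, `reference_id`, `pub_date`.
#' @return A `data.frame` of class `"relation_table"` with those four
#'   columns (`pub_date` as `Date`).
#' @seealso [compute_rscore()], [compute_ascore()], [write_relation_table()]
#' @export
read_relation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "disease_id", "reference_id", "pub_date")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("relation table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[required]
  raw$gene <- toupper(trimws(raw$gene))
  raw$disease_id <- trimws(raw$disease_id)
  raw$reference_id <- trimws(raw$reference_id)
  dates <- parse_pub_date(raw$pub_date)
  bad <- which(is.na(dates))
  if (length(bad)) {
    # +1 for the header line
    stop(sprintf("relation table date error: cannot parse pub_date %s at line %d",
                 dQuote(raw$pub_date[bad[1]]), bad[1] + 1L))
  }
  raw$pub_date <- dates
  dup <- duplicated(raw[c("gene", "disease_id", "reference_id")])
  if (any(dup)) {
    ml_log("relation_table", "dropped %d duplicate evidence row(s)", sum(dup))
    raw <- raw[!dup, , drop = FALSE]
  }
  rownames(raw) <- NULL
  class(raw) <- c("relation_table", "data.frame")
  raw
}

#' Write a relation table
#'
#' @param x A `relation_table` (or compatible data.frame).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_relation_table <- function(x, path) {
  stopifnot(all(c("gene", "disease_id", "reference_id", "pub_date") %in% names(x)))
  out <- as.data.frame(x)[c("gene", "disease_id", "reference_id", "pub_date")]
  out$pub_date <- format(as.Date(out$pub_date), "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ISO dates with month-only / year-only fallback (first day of the period)
parse_pub_date <- function(x) {
  x <- trimws(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  ym <- !full & grepl("^\\d{4}-\\d{2}$", x)
  if (any(ym)) {
    out[ym] <- as.Date(paste0(x[ym], "-01"), format = "%Y-%m-%d")
    ml_log("relation_table", "%d month-only date(s) resolved to first of month",
           sum(ym & !is.na(out)))
  }
  yo <- !full & !ym & grepl("^\\d{4}$", x)
  if (any(yo)) {
    out[yo] <- as.Date(paste0(x[yo], "-01-01"), format = "%Y-%m-%d")
    ml_log("relation_table", "%d year-only date(s) resolved to January 1",
           sum(yo))
  }
  out
}

#' @export
print.relation_table <- function(x, ...) {
  cat(sprintf("Relation table: %d evidence rows, %d gene(s), %d disease id(s)\n",
              nrow(x), length(unique(x$gene)), length(unique(x$disease_id))))
  NextMethod()
}
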