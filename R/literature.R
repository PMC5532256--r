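#' Reference support score (RScore)
#'
#' RScore of a gene is the number of distinct literature references
#' supporting its relationship with the given disease. Genes with no
#' evidence for that disease are absent from the result.
#'
#' @param relations A [read_relation_table()] result.
#' @param disease_id Disease identifier present in the table.
#' @return Named integer vector, gene -> reference count (every value
#'   >= 1).
#' @examples
#' tab <- data.frame(gene = c("BDNF", "BDNF", "DRD2"),
#'                   disease_id = "D1",
#'                   reference_id = c("r1", "r2", "r1"),
#'                   pub_date = as.Date("2015-06-01"))
#' compute_rscore(tab, "D1")
#' @export
compute_rscore <- function(relations, disease_id) {
  rel <- subset_disease(relations, disease_id)
  counts <- tapply(rel$reference_id, rel$gene,
                   function(r) length(unique(r)))
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(names(out))]
}

#' Publication age score (AScore)
#'
#' AScore of a gene is the age, in years, of its earliest supporting
#' publication: the maximum over the gene's references of
#' `(current_date - pub_date) + 1` days, converted to years by dividing by
#' 365.25. Small values flag recently reported ("novel") genes; the +1 day
#' keeps every age strictly positive, so a reference published on
#' `current_date` itself scores 1/365.25 years.
#'
#' @inheritParams compute_rscore
#' @param current_date Reference date (`Date` or string); no publication
#'   may postdate it.
#' @return Named numeric vector, gene -> age in years (all > 0).
#' @export
compute_ascore <- function(relations, disease_id, current_date) {
  current_date <- as.Date(current_date)
  rel <- subset_disease(relations, disease_id)
  future <- rel$pub_date > current_date
  if (any(future)) {
    stop(sprintf("reference %s has pub_date %s after current_date %s",
                 rel$reference_id[future][1],
                 format(rel$pub_date[future][1]), format(current_date)))
  }
  age_days <- as.integer(current_date - rel$pub_date) + 1L
  ages <- tapply(age_days, rel$gene, max) / 365.25
  out <- stats::setNames(as.numeric(ages), names(ages))
  out[order(names(out))]
}

#' Age of a single publication
#'
#' @param pub_date Publication date(s).
#' @param current_date Reference date.
#' @return Data frame with `age_days` (integer, >= 1) and `age_years`.
#' @export
article_age <- function(pub_date, current_date) {
  pub_date <- as.Date(pub_date)
  current_date <- as.Date(current_date)
  if (any(pub_date > current_date)) stop("pub_date after current_date")
  days <- as.integer(current_date - pub_date) + 1L
  data.frame(age_days = days, age_years = days / 365.25)
}

#' Select recently reported genes by publication age
#'
#' Returns the genes whose AScore does not exceed the threshold (boundary
#' inclusive), i.e. genes first reported within the last
#' `threshold_years` years.
#'
#' @param ascores Named numeric vector from [compute_ascore()].
#' @param threshold_years Positive age cutoff in years (default 2).
#' @return Character vector of gene symbols (possibly empty).
#' @export
novelty_filter <- function(ascores, threshold_years = 2) {
  if (!length(ascores)) stop("ascores is empty")
  if (!is.numeric(threshold_years) || length(threshold_years) != 1L ||
      threshold_years <= 0) {
    stop("threshold_years must be a single positive number")
  }
  sort(names(ascores)[ascores <= threshold_years])
}

subset_disease <- function(relations, disease_id) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L)
  known <- unique(relations$disease_id)
  if (!disease_id %in% known) {
    stop(sprintf("unknown disease_id %s; known ids: %s", dQuote(disease_id),
                 paste(sort(known), collapse = ", ")))
  }
  relations[relations$disease_id == disease_id, , drop = FALSE]
}
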