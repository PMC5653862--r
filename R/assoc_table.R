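#' Canonical master-table columns
#'
#' The canonical dialect for the drug-AE master association table: UTF-8,
#' tab-separated, one (product, AE) pair per row. List-valued cells
#' (`ingredient_ids`, `moa_class_ids`) use `|` as the internal separator.
#' @keywords internal
#' @noRd
.assoc_columns <- c(
  "product_id", "product_name_cn", "product_name_en",
  "ingredient_ids", "moa_class_ids",
  "ae_term_cn", "ae_term_en", "ae_id"
)

.split_multi <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(v) unique(v[nzchar(v)]))
}

.join_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

.ae_key <- function(ae_id, ae_term_en) {
  has_id <- !is.na(ae_id) & nzchar(ae_id)
  ifelse(has_id, ae_id, paste0("term:", ae_term_en))
}

.load_error <- function(msg) {
  stop(errorCondition(msg, class = c("aeclass_load_error", "error")))
}

#' Construct a drug-AE association table
#'
#' Builds the in-memory image of the curated master file: one record per
#' (drug product, AE) pair, carrying the product's ingredient identifiers and
#' mechanism-of-action (MoA) class identifiers as list columns. Duplicate
#' (product, AE) rows collapse to one; rows are kept in a canonical sort
#' order so that loading is independent of input row order.
#'
#' @param records data.frame with columns `product_id` and `ae_term_en`
#'   (mandatory, non-empty) and optionally `product_name_cn`,
#'   `product_name_en`, `ingredient_ids`, `moa_class_ids`, `ae_term_cn`,
#'   `ae_id`. `ingredient_ids` and `moa_class_ids` may be `|`-separated
#'   character columns or list columns of character vectors.
#' @return An object of class `assoc_table`: a list with element `records`
#'   (the normalised data.frame) and attribute `report` (the load report,
#'   see [load_report()]).
#' @export
association_table <- function(records) {
  if (!is.data.frame(records)) .load_error("records must be a data.frame")
  for (col in c("product_id", "ae_term_en")) {
    if (!col %in% names(records)) {
      .load_error(sprintf("missing mandatory column '%s'", col))
    }
  }
  for (col in setdiff(.assoc_columns, names(records))) {
    records[[col]] <- rep(NA_character_, nrow(records))
  }
  records <- records[.assoc_columns]
  for (col in setdiff(.assoc_columns, c("ingredient_ids", "moa_class_ids"))) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in c("ingredient_ids", "moa_class_ids")) {
    if (!is.list(records[[col]])) {
      records[[col]] <- .split_multi(as.character(records[[col]]))
    } else {
      records[[col]] <- lapply(records[[col]], function(v) {
        v <- as.character(v)
        unique(v[nzchar(v) & !is.na(v)])
      })
    }
  }

  bad <- which(is.na(records$product_id) | !nzchar(records$product_id) |
                 is.na(records$ae_term_en) | !nzchar(records$ae_term_en))
  if (length(bad) > 0) {
    .load_error(sprintf(
      "malformed row %d: empty product_id or ae_term_en", bad[1]))
  }

  key <- paste(records$product_id, .ae_key(records$ae_id, records$ae_term_en),
               sep = "\r")
  ord <- order(records$product_id,
               .ae_key(records$ae_id, records$ae_term_en),
               records$ae_term_en, method = "radix")
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL

  x <- structure(list(records = records), class = "assoc_table")
  attr(x, "report") <- .make_load_report(x)
  x
}

.make_load_report <- function(x) {
  r <- x$records
  list(
    n_records = nrow(r),
    n_products = length(unique(r$product_id)),
    n_ingredients = length(ingredient_universe(x)),
    n_ae_terms_en = length(unique(r$ae_term_en)),
    n_ae_terms_cn = length(unique(r$ae_term_cn[!is.na(r$ae_term_cn) &
                                                 nzchar(r$ae_term_cn)])),
    n_missing_ae_id = sum(is.na(r$ae_id) | !nzchar(r$ae_id))
  )
}

#' @export
print.assoc_table <- function(x, ...) {
  rep <- load_report(x)
  cat(sprintf(
    "<assoc_table> %d records | %d products | %d ingredients | %d EN AE terms (%d CN) | %d records without AE id\n",
    rep$n_records, rep$n_products, rep$n_ingredients,
    rep$n_ae_terms_en, rep$n_ae_terms_cn, rep$n_missing_ae_id))
  invisible(x)
}

#' Load report of an association table
#'
#' Counts of records, distinct products, distinct ingredients, distinct
#' English and Chinese AE terms, and records lacking an AE ontology id
#' (retained for product/AE counting but excluded from hierarchy-propagated
#' analyses).
#'
#' @param x an `assoc_table`.
#' @return Named list of counts.
#' @export
load_report <- function(x) {
  stopifnot(inherits(x, "assoc_table"))
  attr(x, "report")
}

#' Product and ingredient universes of an association table
#'
#' `product_universe()` returns the distinct product ids;
#' `ingredient_universe()` the union of ingredient ids across records. Note
#' that an ingredient whose products report no AE cannot appear in the table
#' (records are (product, AE) pairs); analyses over a wider ingredient
#' universe pass it explicitly (see [detect_class_effects()]).
#'
#' @param x an `assoc_table`.
#' @return Character vector of ids, sorted.
#' @export
product_universe <- function(x) {
  stopifnot(inherits(x, "assoc_table"))
  sort(unique(x$records$product_id))
}

#' @rdname product_universe
#' @export
ingredient_universe <- function(x) {
  stopifnot(inherits(x, "assoc_table"))
  sort(unique(unlist(x$records$ingredient_ids, use.names = FALSE)))
}

#' Read a drug-AE master association table
#'
#' Reads the canonical tab-separated dialect (UTF-8; columns `product_id`,
#' `product_name_cn`, `product_name_en`, `ingredient_ids`, `moa_class_ids`,
#' `ae_term_cn`, `ae_term_en`, `ae_id`; `|` inside list-valued cells).
#' Duplicate (product, AE) rows collapse on load and a load-report summary is
#' emitted as a message.
#'
#' @param path path to the TSV file.
#' @param quiet suppress the load-report message.
#' @return An `assoc_table` (see [association_table()]).
#' @export
read_association_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) .load_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!all(validUTF8(lines))) {
    .load_error(sprintf("file is not valid UTF-8: %s", path))
  }
  df <- utils::read.delim(
    text = lines, sep = "\t", quote = "", stringsAsFactors = FALSE,
    colClasses = "character", na.strings = "", check.names = FALSE
  )
  missing <- setdiff(.assoc_columns, names(df))
  if (length(missing) > 0) {
    .load_error(sprintf("missing mandatory column '%s'", missing[1]))
  }
  x <- association_table(df)
  if (!quiet) {
    rep <- load_report(x)
    message(sprintf(
      "loaded %d records: %d products, %d ingredients, %d EN AE terms (%d CN), %d records without AE id",
      rep$n_records, rep$n_products, rep$n_ingredients,
      rep$n_ae_terms_en, rep$n_ae_terms_cn, rep$n_missing_ae_id))
  }
  x
}

#' Write an association table in the canonical dialect
#'
#' @param x an `assoc_table`.
#' @param path output path; written UTF-8, tab-separated, `|`-joined list
#'   cells, empty string for missing optional fields.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  stopifnot(inherits(x, "assoc_table"))
  r <- x$records
  out <- r
  out$ingredient_ids <- .join_multi(r$ingredient_ids)
  out$moa_class_ids <- .join_multi(r$moa_class_ids)
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.assoc_columns, collapse = "\t"), con, useBytes = TRUE)
  body <- do.call(paste, c(unname(out[.assoc_columns]), list(sep = "\t")))
  if (length(body) > 0) writeLines(enc2utf8(body), con, useBytes = TRUE)
  invisible(path)
}
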