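#' Read a hierarchy from an edge list or flat OBO subset
#'
#' Edge-list format: UTF-8 TSV with header `child	parent`, one is-a edge per
#' row. OBO-subset format: `[Term]` stanzas with `id:`, `name:` and `is_a:`
#' lines only (the flat style produced by ontology extraction tools); an
#' `is_a:` target that is not itself a term in the file is a dangling-parent
#' error.
#'
#' @param path path to the hierarchy file.
#' @param format `"edges"` or `"obo"`.
#' @param labels_path optional TSV with columns `id`, `label_en`
#'   (optionally `label_cn`); ignored for OBO input, where `name:` lines
#'   provide labels.
#' @return An [hierarchy()] object.
#' @export
read_hierarchy <- function(path, format = c("edges", "obo"),
                           labels_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .load_error(sprintf("file not found: %s", path))
  if (format == "obo") return(.read_obo_subset(path))
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  for (col in c("child", "parent")) {
    if (!col %in% names(df)) {
      .load_error(sprintf("missing mandatory column '%s'", col))
    }
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.delim(labels_path, sep = "\t", quote = "",
                                stringsAsFactors = FALSE,
                                colClasses = "character", check.names = FALSE)
  }
  hierarchy(df, labels = labels)
}

.read_obo_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!all(validUTF8(lines))) {
    .load_error(sprintf("file is not valid UTF-8: %s", path))
  }
  term_starts <- which(trimws(lines) == "[Term]")
  if (length(term_starts) == 0) .load_error("no [Term] stanza found")
  bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(0); names_en <- character(0)
  edge_child <- character(0); edge_parent <- character(0)
  for (i in seq_along(term_starts)) {
    block <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (length(id) != 1) {
      .load_error(sprintf("[Term] stanza %d lacks a single id line", i))
    }
    nm <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE))
    isa <- grep("^is_a:", block, value = TRUE)
    # strip optional "! label" comments after the target id
    targets <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", isa)))
    ids <- c(ids, id)
    names_en <- c(names_en, if (length(nm) >= 1) nm[1] else NA_character_)
    edge_child <- c(edge_child, rep(id, length(targets)))
    edge_parent <- c(edge_parent, targets)
  }
  dangling <- setdiff(edge_parent, ids)
  if (length(dangling) > 0) {
    .load_error(sprintf("dangling parent id '%s'", dangling[1]))
  }
  hierarchy(
    data.frame(child = edge_child, parent = edge_parent,
               stringsAsFactors = FALSE),
    labels = data.frame(id = ids, label_en = names_en,
                        stringsAsFactors = FALSE),
    nodes = ids)
}

#' Write a hierarchy edge list (and optional labels) as TSV
#'
#' @param h an `isa_hierarchy`.
#' @param path output edge-list path.
#' @param labels_path optional output path for the label table.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path, labels_path = NULL) {
  stopifnot(inherits(h, "isa_hierarchy"))
  e <- h$edges[order(h$edges$child, h$edges$parent, method = "radix"), ]
  con <- file(path, open = "wb")
  writeLines(c("child\tparent", paste(e$child, e$parent, sep = "\t")),
             con, useBytes = TRUE)
  close(con)
  if (!is.null(labels_path) && !is.null(h$labels)) {
    l <- h$labels[order(h$labels$id, method = "radix"), ]
    con <- file(labels_path, open = "wb")
    writeLines(c("id\tlabel_en\tlabel_cn",
                 paste(l$id, l$label_en,
                       ifelse(is.na(l$label_cn), "", l$label_cn),
                       sep = "\t")),
               con, useBytes = TRUE)
    close(con)
  }
  invisible(path)
}
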