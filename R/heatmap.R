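#' PCR matrix over drug classes and AE classes
#'
#' Builds the n x m grid whose cell (drug class, AE class) is the PCR —
#' the fraction of the drug class's ingredients associated with the AE
#' class after upward propagation through the AE hierarchy. Cells with
#' value 1 are class effects. Drug classes with no ingredient mapped into
#' the universe are dropped with a warning; if every class is empty the
#' call errors.
#'
#' @inheritParams detect_class_effects
#' @return Numeric matrix with `class_ids` rownames and `ae_ids` colnames,
#'   all cells in `[0, 1]`.
#' @export
pcr_matrix <- function(table, class_h, ae_h, class_ids, ae_ids,
                       universe = NULL) {
  stopifnot(inherits(table, "assoc_table"),
            inherits(class_h, "isa_hierarchy"),
            inherits(ae_h, "isa_hierarchy"))
  class_ids <- as.character(class_ids)
  ae_ids <- as.character(ae_ids)
  if (is.null(universe)) {
    universe <- intersect(ingredient_universe(table), class_h$nodes)
  }
  universe <- sort(unique(as.character(universe)))

  amap <- collapse_to_ingredients(table, quiet = TRUE)
  amap <- propagate_ae(amap[intersect(names(amap), universe)], ae_h)
  missing_ing <- setdiff(universe, names(amap))
  if (length(missing_ing) > 0) {
    amap <- c(amap, stats::setNames(
      replicate(length(missing_ing), character(0), simplify = FALSE),
      missing_ing))
  }

  members <- lapply(class_ids, function(cl) class_members(class_h, cl, universe))
  names(members) <- class_ids
  empty <- class_ids[lengths(members) == 0]
  if (length(empty) == length(class_ids)) {
    stop("all drug classes have zero mapped ingredients")
  }
  if (length(empty) > 0) {
    warning(sprintf("dropping %d class(es) with zero mapped ingredients: %s",
                    length(empty), paste(empty, collapse = ", ")))
    class_ids <- setdiff(class_ids, empty)
  }

  m <- matrix(NA_real_, nrow = length(class_ids), ncol = length(ae_ids),
              dimnames = list(class_ids, ae_ids))
  for (cl in class_ids) {
    mem <- members[[cl]]
    has <- amap[mem]
    for (ae in ae_ids) {
      pos <- mem[vapply(has, function(s) ae %in% s, logical(1))]
      m[cl, ae] <- pcr(mem, pos)
    }
  }
  m
}

#' Deterministic agglomerative clustering of a PCR matrix
#'
#' Hierarchically clusters the rows (drug classes) and columns (AE classes)
#' of the PCR matrix so that similarly behaving classes sit adjacent in the
#' heatmap. The leaf order is made canonical by weight-reordering the
#' dendrograms with the row/column means, so the same matrix always yields
#' the same order regardless of input row permutation.
#'
#' @param m numeric matrix (at least 2 x 2 for clustering; a degenerate
#'   single-row or single-column matrix returns identity orders with a
#'   warning).
#' @param metric distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `row_order` and `col_order` (character vectors of
#'   dimnames in clustered order) and `row_dendrogram` / `col_dendrogram`
#'   (reordered [stats::dendrogram] objects, `NULL` when degenerate).
#' @export
cluster_matrix <- function(m, metric = "euclidean", linkage = "average") {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  if (nrow(m) < 2 || ncol(m) < 2) {
    warning("degenerate matrix: returning identity ordering")
    return(list(row_order = rownames(m), col_order = colnames(m),
                row_dendrogram = NULL, col_dendrogram = NULL))
  }
  .axis <- function(x) {
    hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
    d <- stats::reorder(stats::as.dendrogram(hc), rowMeans(x),
                        agglo.FUN = mean)
    list(order = labels(d), dend = d)
  }
  ro <- .axis(m)
  co <- .axis(t(m))
  list(row_order = ro$order, col_order = co$order,
       row_dendrogram = ro$dend, col_dendrogram = co$dend)
}

#' Read/write a PCR matrix as TSV
#'
#' The export is the artifact's contract for the heatmap: row ids in the
#' first column (`class_id` header), AE class ids as the remaining headers,
#' cells printed with full precision so the round trip is bit-exact.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `write_pcr_matrix()` returns `path` invisibly;
#'   `read_pcr_matrix()` the matrix.
#' @export
write_pcr_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  header <- paste(c("class_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pcr_matrix
#' @export
read_pcr_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Render the clustered PCR heatmap
#'
#' Convenience wrapper around [pheatmap::pheatmap()] using the same metric
#' and linkage as [cluster_matrix()]. The rendering never alters cell
#' values; the exported matrix plus orderings are the reproducible
#' contract, the image is presentation only.
#'
#' @param m PCR matrix from [pcr_matrix()].
#' @param filename optional output image path (`.png` or `.pdf`); `NULL`
#'   draws on the current device.
#' @param metric,linkage as in [cluster_matrix()].
#' @param ... passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_pcr_heatmap <- function(m, filename = NULL, metric = "euclidean",
                             linkage = "average", ...) {
  cluster <- nrow(m) >= 2 && ncol(m) >= 2
  args <- list(mat = m,
               cluster_rows = cluster, cluster_cols = cluster,
               clustering_distance_rows = metric,
               clustering_distance_cols = metric,
               clustering_method = linkage,
               silent = !is.null(filename), ...)
  if (!is.null(filename)) args$filename <- filename
  invisible(do.call(pheatmap::pheatmap, args))
}

#' Write row/column orderings as JSON
#'
#' @param ord a [cluster_matrix()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ord, path) {
  jsonlite::write_json(list(row_order = ord$row_order,
                            col_order = ord$col_order),
                       path, pretty = TRUE)
  invisible(path)
}
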