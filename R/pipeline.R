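#' Run the full class-effect analysis pipeline
#'
#' Loads the association table and the two hierarchies, runs the
#' statistical class-effect scan, builds the clustered PCR matrix, renders
#' the heatmap, and writes the result files to `out_dir`:
#' `class_effects.tsv`, `pcr_matrix.tsv`, `ordering.json`, `heatmap.png`
#' (when the matrix supports clustering) and `run_report.json` (the
#' machine-readable audit trail: input counts, cutoffs, classes and AEs
#' analysed, number of significant pairs, seed). Identical config and
#' inputs produce identical output files.
#'
#' @param table path to the master association TSV, or an `assoc_table`.
#' @param class_hierarchy path to the drug classification edge-list TSV, or
#'   an `isa_hierarchy`.
#' @param ae_hierarchy path to the AE hierarchy edge-list TSV, or an
#'   `isa_hierarchy`.
#' @param class_ids drug class ids to analyse; default: children of the
#'   classification root(s) (the top-level classes).
#' @param ae_ids AE class ids to analyse; default: children of the AE
#'   root(s).
#' @param universe optional explicit ingredient universe.
#' @param cutoffs a [class_effect_cutoffs()] list.
#' @param out_dir output directory (created if needed).
#' @param heatmap also render `heatmap.png`.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic; the seed is consumed by synthetic inputs upstream).
#' @return Invisibly, a list with `results`, `matrix`, `ordering`,
#'   `report` and the output paths.
#' @export
run_pipeline <- function(table, class_hierarchy, ae_hierarchy,
                         class_ids = NULL, ae_ids = NULL, universe = NULL,
                         cutoffs = class_effect_cutoffs(),
                         out_dir = ".", heatmap = TRUE, seed = 1L) {
  if (is.character(table)) table <- read_association_table(table, quiet = TRUE)
  if (is.character(class_hierarchy)) {
    class_hierarchy <- read_hierarchy(class_hierarchy)
  }
  if (is.character(ae_hierarchy)) ae_hierarchy <- read_hierarchy(ae_hierarchy)
  stopifnot(inherits(table, "assoc_table"),
            inherits(class_hierarchy, "isa_hierarchy"),
            inherits(ae_hierarchy, "isa_hierarchy"))

  .children_of_roots <- function(h) {
    sort(unique(h$edges$child[h$edges$parent %in% h$roots]))
  }
  if (is.null(class_ids)) class_ids <- .children_of_roots(class_hierarchy)
  if (is.null(ae_ids)) ae_ids <- .children_of_roots(ae_hierarchy)
  if (length(class_ids) == 0) stop("no drug class ids to analyse")
  if (length(ae_ids) == 0) stop("no AE class ids to analyse")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  res <- detect_class_effects(table, class_hierarchy, ae_hierarchy,
                              class_ids, ae_ids, universe = universe,
                              cutoffs = cutoffs)
  m <- pcr_matrix(table, class_hierarchy, ae_hierarchy, class_ids, ae_ids,
                  universe = universe)
  ord <- suppressWarnings(cluster_matrix(m))

  paths <- list(
    results = file.path(out_dir, "class_effects.tsv"),
    matrix = file.path(out_dir, "pcr_matrix.tsv"),
    ordering = file.path(out_dir, "ordering.json"),
    heatmap = file.path(out_dir, "heatmap.png"),
    report = file.path(out_dir, "run_report.json"))
  write_class_effects(res, paths$results)
  write_pcr_matrix(m, paths$matrix)
  write_ordering(ord, paths$ordering)
  if (heatmap && nrow(m) >= 2 && ncol(m) >= 2) {
    plot_pcr_heatmap(m, filename = paths$heatmap)
  } else {
    paths$heatmap <- NULL
  }

  lr <- load_report(table)
  report <- list(
    n_records = lr$n_records,
    n_products = lr$n_products,
    n_ingredients = lr$n_ingredients,
    n_ae_terms_en = lr$n_ae_terms_en,
    n_ae_terms_cn = lr$n_ae_terms_cn,
    n_records_without_ae_id = lr$n_missing_ae_id,
    n_classes_analyzed = length(unique(res$class_id)),
    n_aes_analyzed = length(unique(res$ae_id)),
    n_pairs_tested = nrow(res),
    n_significant = sum(res$significant),
    cutoffs = cutoffs,
    seed = as.integer(seed))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(results = res, matrix = m, ordering = ord,
                 report = report, paths = paths))
}
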