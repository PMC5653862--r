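#' Construct a rooted is-a hierarchy
#'
#' A hierarchy is a rooted directed acyclic graph of is-a edges over term ids
#' (AE ontology terms, drug ingredient classes, MoA classes). Multi-parent
#' nodes are permitted; roots are the nodes with no parent. Cycles are
#' rejected with one witness cycle in the error message.
#'
#' @param edges data.frame with character columns `child`, `parent`.
#' @param labels optional data.frame with columns `id`, `label_en` and
#'   optionally `label_cn`.
#' @param nodes optional extra (possibly isolated) node ids to include
#'   beyond those appearing in `edges`.
#' @return Object of class `isa_hierarchy` with elements `nodes`, `edges`,
#'   `roots`, `labels`, and the internal igraph representation.
#' @export
hierarchy <- function(edges, labels = NULL, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("child", "parent") %in% names(edges))) {
    stop("edges must be a data.frame with columns child, parent")
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent)) ||
      anyNA(edges$child) || anyNA(edges$parent)) {
    stop("edge list contains empty or missing ids")
  }
  edges <- unique(edges)
  all_nodes <- sort(unique(c(edges$child, edges$parent, as.character(nodes))))

  cyc <- .find_cycle(edges)
  if (!is.null(cyc)) {
    stop(sprintf("hierarchy contains a cycle: %s",
                 paste(c(cyc, cyc[1]), collapse = " -> ")))
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
  roots <- sort(setdiff(all_nodes, unique(edges$child)))

  if (!is.null(labels)) {
    labels <- data.frame(
      id = as.character(labels$id),
      label_en = as.character(labels$label_en),
      label_cn = if ("label_cn" %in% names(labels))
        as.character(labels$label_cn) else NA_character_,
      stringsAsFactors = FALSE)
  }

  structure(
    list(nodes = all_nodes, edges = edges, roots = roots,
         labels = labels, graph = g),
    class = "isa_hierarchy")
}

# Depth-first search for one directed cycle along child -> parent edges.
.find_cycle <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[start] != 0L) next
    stack <- list(list(node = start, nxt = 1L))
    path <- character(0)
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      if (fr$nxt == 1L) {
        state[fr$node] <- 1L
        path <- c(path, fr$node)
      }
      nbrs <- adj[[fr$node]]
      if (is.null(nbrs) || fr$nxt > length(nbrs)) {
        state[fr$node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$nxt <- fr$nxt + 1L
      nb <- nbrs[fr$nxt]
      if (state[nb] == 1L) {
        return(path[seq(match(nb, path), length(path))])
      }
      if (state[nb] == 0L) {
        stack[[length(stack) + 1L]] <- list(node = nb, nxt = 1L)
      }
    }
  }
  NULL
}

#' @export
print.isa_hierarchy <- function(x, ...) {
  cat(sprintf("<isa_hierarchy> %d nodes, %d edges, %d root(s): %s\n",
              length(x$nodes), nrow(x$edges), length(x$roots),
              paste(utils::head(x$roots, 5), collapse = ", ")))
  invisible(x)
}

#' Human-readable label for hierarchy terms
#'
#' Falls back to the id when no label table was supplied.
#' @param h an `isa_hierarchy`.
#' @param ids character vector of term ids.
#' @return Character vector of labels.
#' @export
node_label <- function(h, ids) {
  stopifnot(inherits(h, "isa_hierarchy"))
  if (is.null(h$labels)) return(ids)
  m <- match(ids, h$labels$id)
  out <- h$labels$label_en[m]
  out[is.na(out)] <- ids[is.na(out)]
  out
}

.check_node <- function(h, node) {
  if (length(node) != 1 || !node %in% h$nodes) {
    stop(sprintf("unknown hierarchy node: '%s'", as.character(node)[1]))
  }
}

#' Descendants and ancestors of a hierarchy term
#'
#' `descendants()` returns the transitive closure downward (all terms whose
#' is-a chain reaches `node`); `ancestors()` the closure upward. Multi-parent
#' terms contribute along every path (union semantics).
#'
#' @param h an `isa_hierarchy`.
#' @param node a term id in `h`.
#' @param include_self include `node` itself.
#' @return Character vector of term ids (sorted).
#' @export
descendants <- function(h, node, include_self = FALSE) {
  stopifnot(inherits(h, "isa_hierarchy"))
  .check_node(h, node)
  out <- names(igraph::subcomponent(h$graph, node, mode = "in"))
  if (!include_self) out <- setdiff(out, node)
  sort(out)
}

#' @rdname descendants
#' @export
ancestors <- function(h, node, include_self = FALSE) {
  stopifnot(inherits(h, "isa_hierarchy"))
  .check_node(h, node)
  out <- names(igraph::subcomponent(h$graph, node, mode = "out"))
  if (!include_self) out <- setdiff(out, node)
  sort(out)
}

#' Ingredients belonging to a drug class
#'
#' All ingredients under the ontological hierarchy of a class count as
#' members of that class: membership is the intersection of the ingredient
#' universe with the class node's descendants (including the node itself, so
#' that an ingredient used directly as a class id is its own member). An
#' ingredient may belong to several classes.
#'
#' @param h the drug classification hierarchy (ingredient leaves placed
#'   under class nodes).
#' @param class_id a class term id in `h`.
#' @param universe character vector of ingredient ids under analysis.
#' @return Character vector: `universe` members of the class, sorted.
#' @export
class_members <- function(h, class_id, universe) {
  mem <- descendants(h, class_id, include_self = TRUE)
  sort(intersect(universe, mem))
}

#' Propagate AE associations up the AE hierarchy
#'
#' Closes each ingredient's AE set under ancestors in the AE hierarchy so
#' that an association with a specific AE (e.g. diarrhea) also counts as an
#' association with every AE class above it (e.g. digestive system AE). The
#' global AE root(s) are excluded from the propagated classes — a score
#' against the universal root is 1 for every drug with any AE and carries no
#' information. AE ids already present are never removed, so the operation
#' is monotone and idempotent.
#'
#' @param assoc named list: ingredient id -> character vector of AE ids.
#'   Every AE id must resolve in `ae_h` (filter beforehand; see
#'   [collapse_to_ingredients()]).
#' @param ae_h the AE `isa_hierarchy`.
#' @return Named list of the same shape with ancestor-closed AE sets.
#' @export
propagate_ae <- function(assoc, ae_h) {
  stopifnot(inherits(ae_h, "isa_hierarchy"))
  ae_all <- unique(unlist(assoc, use.names = FALSE))
  unknown <- setdiff(ae_all, ae_h$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("AE id not in hierarchy: '%s'", unknown[1]))
  }
  anc <- lapply(ae_all, function(a) setdiff(ancestors(ae_h, a), ae_h$roots))
  names(anc) <- ae_all
  lapply(assoc, function(aes) {
    sort(unique(c(aes, unlist(anc[aes], use.names = FALSE))))
  })
}
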