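# In-code fixtures and independent brute-force oracles shared across tests.

# Minimal association table: a data.frame in the canonical column set.
make_records <- function(product_id, ae_term_en, ingredient_ids = NULL,
                         moa_class_ids = NULL, ae_id = NA_character_,
                         ae_term_cn = NA_character_) {
  data.frame(
    product_id = product_id,
    product_name_cn = NA_character_,
    product_name_en = product_id,
    ingredient_ids = if (is.null(ingredient_ids)) "" else ingredient_ids,
    moa_class_ids = if (is.null(moa_class_ids)) "" else moa_class_ids,
    ae_term_cn = ae_term_cn,
    ae_term_en = ae_term_en,
    ae_id = ae_id,
    stringsAsFactors = FALSE)
}

# Small AE hierarchy: root -> {digestive, neuro} -> leaves.
toy_ae_hierarchy <- function() {
  hierarchy(data.frame(
    child = c("AE:dig", "AE:neuro", "AE:diarrhea", "AE:nausea",
              "AE:headache"),
    parent = c("AE:root", "AE:root", "AE:dig", "AE:dig", "AE:neuro"),
    stringsAsFactors = FALSE))
}

# Random DAG over n nodes: edges only from higher to lower index (acyclic).
random_dag <- function(n, p = 0.1) {
  nodes <- sprintf("N%02d", seq_len(n))
  edges <- expand.grid(ci = seq_len(n), pi = seq_len(n))
  edges <- edges[edges$ci > edges$pi, ]
  keep <- stats::runif(nrow(edges)) < p
  e <- edges[keep, ]
  if (nrow(e) == 0) e <- data.frame(ci = 2L, pi = 1L)
  data.frame(child = nodes[e$ci], parent = nodes[e$pi],
             stringsAsFactors = FALSE)
}

# Brute-force transitive closure downward by repeated edge expansion,
# independent of igraph.
brute_descendants <- function(edges, node) {
  desc <- character(0)
  frontier <- node
  repeat {
    nxt <- setdiff(edges$child[edges$parent %in% frontier], c(desc, node))
    if (length(nxt) == 0) break
    desc <- c(desc, nxt)
    frontier <- nxt
  }
  sort(desc)
}

brute_ancestors <- function(edges, node) {
  anc <- character(0)
  frontier <- node
  repeat {
    nxt <- setdiff(edges$parent[edges$child %in% frontier], c(anc, node))
    if (length(nxt) == 0) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}

# Random 2x2 contingency cells with nondegenerate marginals.
random_cells <- function() {
  repeat {
    z <- stats::rpois(4, lambda = sample(1:8, 1)) + c(0, 0, 0, 1)
    names(z) <- c("a", "b", "c", "d")
    if ((z["a"] + z["c"]) > 0 && (z["b"] + z["d"]) > 0) return(z)
  }
}

# Naive average-linkage agglomerative clustering; returns sorted merge
# heights. Independent of stats::hclust.
brute_average_linkage_heights <- function(m, metric = "euclidean") {
  d <- as.matrix(stats::dist(m, method = metric))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}
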