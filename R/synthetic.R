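#' Configuration for the synthetic association-table generator
#'
#' The generator emulates the statistical structure of a curated
#' package-insert master file: a universe of ingredients partitioned (with
#' optional overlap) into classification classes, an AE ontology of given
#' depth, independent background ingredient-AE associations at a fixed
#' probability, and a set of planted class effects in which every member of
#' a chosen class is associated with a chosen leaf AE. Defaults mirror the
#' scale of a real cardiovascular-drug curation: 180 ingredients in 36
#' classes of 5, 736 leaf AEs in a depth-3 ontology, and a background rate
#' of 0.03 (about 22 reported AEs per ingredient).
#'
#' @param n_ingredients number of ingredients in the universe.
#' @param n_products_per_ingredient a single count, or a `c(min, max)`
#'   range sampled per ingredient.
#' @param class_sizes integer vector of class sizes; their sum must cover
#'   `n_ingredients` (every ingredient belongs to at least one class), and
#'   the excess over `n_ingredients` — the overlapping memberships — may
#'   not exceed `overlap_fraction` of all membership slots.
#' @param overlap_fraction allowed fraction of duplicate membership slots,
#'   in `[0, 1)`.
#' @param ae_hierarchy_depth depth of the AE ontology (root = level 1),
#'   at least 2.
#' @param n_leaf_aes number of leaf AE terms.
#' @param p_bg per-(ingredient, leaf AE) background association
#'   probability in `[0, 1]`.
#' @param planted_effects list of `c(class index, leaf AE index)` pairs.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_ingredients = 180,
                             n_products_per_ingredient = c(1, 3),
                             class_sizes = rep(5L, 36),
                             overlap_fraction = 0,
                             ae_hierarchy_depth = 3,
                             n_leaf_aes = 736,
                             p_bg = 0.03,
                             planted_effects = list(),
                             seed = 1L) {
  stopifnot(n_ingredients >= 1, length(class_sizes) >= 1,
            all(class_sizes >= 1), ae_hierarchy_depth >= 2,
            n_leaf_aes >= 1, p_bg >= 0, p_bg <= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  total <- sum(class_sizes)
  if (total < n_ingredients) {
    stop("sum of class sizes must cover n_ingredients")
  }
  if (total - n_ingredients > overlap_fraction * total) {
    stop("class sizes imply more overlap than overlap_fraction allows")
  }
  if (any(class_sizes > n_ingredients)) {
    stop("a class cannot be larger than the ingredient universe")
  }
  for (pe in planted_effects) {
    if (length(pe) != 2 ||
        pe[1] < 1 || pe[1] > length(class_sizes) ||
        pe[2] < 1 || pe[2] > n_leaf_aes) {
      stop("planted class or AE index out of range")
    }
  }
  structure(list(
    n_ingredients = as.integer(n_ingredients),
    n_products_per_ingredient = as.integer(n_products_per_ingredient),
    class_sizes = as.integer(class_sizes),
    overlap_fraction = overlap_fraction,
    ae_hierarchy_depth = as.integer(ae_hierarchy_depth),
    n_leaf_aes = as.integer(n_leaf_aes),
    p_bg = p_bg,
    planted_effects = planted_effects,
    seed = as.integer(seed)), class = "synthetic_config")
}

# Balanced AE ontology: root at level 1, leaves at level `depth`,
# intermediate level widths interpolated geometrically.
.build_ae_hierarchy <- function(depth, n_leaf) {
  widths <- pmax(1L, pmin(
    as.integer(ceiling(n_leaf^((seq_len(depth) - 1) / (depth - 1)))), n_leaf))
  widths[1] <- 1L
  widths[depth] <- n_leaf
  ids <- lapply(seq_len(depth), function(lvl) {
    if (lvl == 1) "AE:root"
    else if (lvl == depth) sprintf("AE:leaf%04d", seq_len(widths[lvl]))
    else sprintf("AE:l%d_%03d", lvl, seq_len(widths[lvl]))
  })
  edges <- list()
  for (lvl in 2:depth) {
    child <- ids[[lvl]]
    parent_idx <- ceiling(seq_along(child) * widths[lvl - 1] / widths[lvl])
    edges[[lvl - 1]] <- data.frame(
      child = child, parent = ids[[lvl - 1]][parent_idx],
      stringsAsFactors = FALSE)
  }
  all_ids <- unlist(ids, use.names = FALSE)
  labels <- data.frame(
    id = all_ids,
    label_en = ifelse(all_ids == "AE:root", "adverse event",
                      gsub("AE:", "synthetic AE ", all_ids)),
    stringsAsFactors = FALSE)
  hierarchy(do.call(rbind, edges), labels = labels)
}

#' Generate a synthetic association table with planted class effects
#'
#' Construction (all randomness consumes `cfg$seed`): ingredients are dealt
#' into classes of the configured sizes (overlap slots drawn from
#' ingredients not already in the class); a balanced AE ontology of the
#' configured depth is built; each planted (class, leaf AE) pair marks
#' every class member associated with that AE; every remaining
#' (ingredient, leaf AE) pair is associated independently with probability
#' `p_bg`; each ingredient-level association is then assigned to one
#' randomly chosen product of the ingredient — the direction the
#' product-to-ingredient collapse rule undoes. Products carry their
#' ingredient's classes as MoA-style class ids so both classification
#' routes are exercised.
#'
#' Ingredients with no association cannot appear in the association table
#' (records are (product, AE) pairs), so the full universe is returned
#' separately and should be passed to [detect_class_effects()].
#'
#' @param cfg a [synthetic_config()].
#' @return List with `table` (`assoc_table`), `class_hierarchy`,
#'   `ae_hierarchy`, `planted` (data.frame `class_id`, `ae_id`),
#'   `ingredients`, `class_ids`, `leaf_ae_ids`, `config`.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, .generate_impl(cfg))
}

.generate_impl <- function(cfg) {
  n <- cfg$n_ingredients
  ings <- sprintf("ING%04d", seq_len(n))
  class_ids <- sprintf("CLS%03d", seq_along(cfg$class_sizes))

  # deal shuffled ingredients into classes; overlap slots sampled from
  # ingredients not already members of that class
  shuffled <- sample(ings)
  members <- vector("list", length(class_ids))
  pos <- 1L
  for (i in seq_along(class_ids)) {
    size <- cfg$class_sizes[i]
    take <- min(size, max(0L, n - pos + 1L))
    base <- if (take > 0) shuffled[seq(pos, pos + take - 1L)] else character(0)
    pos <- pos + take
    if (take < size) {
      base <- c(base, sample(setdiff(ings, base), size - take))
    }
    members[[i]] <- sort(base)
  }
  names(members) <- class_ids

  class_edges <- rbind(
    data.frame(child = unlist(members, use.names = FALSE),
               parent = rep(class_ids, lengths(members)),
               stringsAsFactors = FALSE),
    data.frame(child = class_ids, parent = "CLS:root",
               stringsAsFactors = FALSE))
  class_h <- hierarchy(unique(class_edges))

  ae_h <- .build_ae_hierarchy(cfg$ae_hierarchy_depth, cfg$n_leaf_aes)
  leaves <- sprintf("AE:leaf%04d", seq_len(cfg$n_leaf_aes))

  assoc <- matrix(stats::runif(n * cfg$n_leaf_aes) < cfg$p_bg,
                  nrow = n, dimnames = list(ings, leaves))
  planted <- data.frame(class_id = character(0), ae_id = character(0),
                        stringsAsFactors = FALSE)
  for (pe in cfg$planted_effects) {
    cl <- class_ids[pe[1]]
    ae <- leaves[pe[2]]
    assoc[members[[cl]], ae] <- TRUE
    planted <- rbind(planted, data.frame(class_id = cl, ae_id = ae,
                                         stringsAsFactors = FALSE))
  }
  planted <- unique(planted)

  npp <- cfg$n_products_per_ingredient
  n_prod <- if (length(npp) == 2) {
    npp[1] + floor(stats::runif(n) * (npp[2] - npp[1] + 1L))
  } else rep(npp[1], n)
  products <- lapply(seq_len(n), function(i) {
    sprintf("P-%s-%02d", ings[i], seq_len(n_prod[i]))
  })
  names(products) <- ings

  hits <- which(assoc, arr.ind = TRUE)
  recs <- if (nrow(hits) > 0) {
    ing_i <- rownames(assoc)[hits[, 1]]
    ae_i <- colnames(assoc)[hits[, 2]]
    prod_i <- vapply(ing_i, function(g) {
      p <- products[[g]]
      p[[sample.int(length(p), 1L)]]
    }, character(1))
    data.frame(
      product_id = prod_i,
      product_name_en = prod_i,
      ingredient_ids = I(as.list(ing_i)),
      moa_class_ids = I(lapply(ing_i, function(g) {
        class_ids[vapply(members, function(mm) g %in% mm, logical(1))]
      })),
      ae_term_en = node_label(ae_h, ae_i),
      ae_id = ae_i,
      stringsAsFactors = FALSE)
  } else {
    data.frame(product_id = character(0), ae_term_en = character(0),
               stringsAsFactors = FALSE)
  }

  list(table = association_table(recs),
       class_hierarchy = class_h,
       ae_hierarchy = ae_h,
       planted = planted,
       ingredients = ings,
       class_ids = class_ids,
       leaf_ae_ids = leaves,
       config = cfg)
}

#' Monte-Carlo operating characteristics of the class-effect filter
#'
#' Repeatedly generates synthetic data under `cfg` (replicate r uses seed
#' `cfg$seed + r`), runs [detect_class_effects()] over every
#' (class, leaf AE) pair with the full ingredient universe, and summarises
#' how often planted pairs are recovered (marked significant) and how often
#' non-planted pairs are falsely flagged.
#'
#' @param cfg a [synthetic_config()] (normally with `planted_effects`).
#' @param n_reps number of Monte-Carlo replicates (>= 1).
#' @param cutoffs a [class_effect_cutoffs()] list.
#' @return List: `recovery_rate` and `false_positive_rate` (means over
#'   replicates), their standard errors `recovery_se` / `fp_se`, `n_reps`,
#'   and `per_rep` (data.frame with per-replicate rates).
#' @export
estimate_operating_characteristics <- function(cfg, n_reps,
                                               cutoffs = class_effect_cutoffs()) {
  stopifnot(inherits(cfg, "synthetic_config"), n_reps >= 1)
  rec <- numeric(n_reps)
  fp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    g <- generate_synthetic(cfg_r)
    res <- detect_class_effects(
      g$table, g$class_hierarchy, g$ae_hierarchy,
      class_ids = g$class_ids, ae_ids = g$leaf_ae_ids,
      universe = g$ingredients, cutoffs = cutoffs)
    pair <- paste(res$class_id, res$ae_id)
    planted <- paste(g$planted$class_id, g$planted$ae_id)
    is_planted <- pair %in% planted
    rec[r] <- if (any(is_planted)) {
      mean(res$significant[is_planted])
    } else NA_real_
    fp[r] <- if (any(!is_planted)) {
      mean(res$significant[!is_planted])
    } else NA_real_
  }
  .se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  list(recovery_rate = mean(rec, na.rm = TRUE),
       recovery_se = .se(rec),
       false_positive_rate = mean(fp, na.rm = TRUE),
       fp_se = .se(fp),
       n_reps = n_reps,
       per_rep = data.frame(rep = seq_len(n_reps), recovery = rec,
                            false_positive = fp))
}
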