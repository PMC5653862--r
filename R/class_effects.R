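#' Collapse product-level AE records to the ingredient level
#'
#' Class-effect statistics are defined at the drug-ingredient level: an
#' ingredient is associated with an AE as soon as at least one drug product
#' containing that ingredient carries the AE (different dosage forms of one
#' ingredient may report different AEs; any one positive form makes the
#' ingredient positive). Products with several ingredients contribute each
#' AE to every ingredient. Records lacking an AE ontology id cannot take
#' part in hierarchy-propagated analyses and are dropped here with a
#' message giving the count.
#'
#' @param table an `assoc_table`.
#' @param quiet suppress the dropped-record message.
#' @return Named list: ingredient id -> sorted character vector of AE ids.
#'   Every ingredient of [ingredient_universe()] is present, possibly with
#'   an empty AE set.
#' @export
collapse_to_ingredients <- function(table, quiet = FALSE) {
  stopifnot(inherits(table, "assoc_table"))
  r <- table$records
  ings <- ingredient_universe(table)
  out <- stats::setNames(vector("list", length(ings)), ings)
  for (i in seq_along(out)) out[[i]] <- character(0)
  has_id <- !is.na(r$ae_id) & nzchar(r$ae_id)
  n_drop <- sum(!has_id)
  if (n_drop > 0 && !quiet) {
    message(sprintf(
      "%d record(s) without AE id excluded from ingredient-level AE map",
      n_drop))
  }
  r <- r[has_id, , drop = FALSE]
  if (nrow(r) > 0) {
    ing_per_rec <- r$ingredient_ids
    reps <- lengths(ing_per_rec)
    flat <- data.frame(
      ingredient = unlist(ing_per_rec, use.names = FALSE),
      ae_id = rep(r$ae_id, reps),
      stringsAsFactors = FALSE)
    sp <- split(flat$ae_id, flat$ingredient)
    for (ing in names(sp)) out[[ing]] <- sort(unique(sp[[ing]]))
  }
  out
}

#' Proportional class level ratio (PCR)
#'
#' The fraction of a drug class's members that are associated with a given
#' AE: number of class members with the AE divided by the class size. A
#' class effect is the condition PCR = 1 — every ingredient in the class
#' carries the AE.
#'
#' @param members character vector of class member ingredient ids
#'   (non-empty).
#' @param ae_positive character vector of the members associated with the
#'   AE; must be a subset of `members`.
#' @return The ratio in `[0, 1]`.
#' @export
pcr <- function(members, ae_positive) {
  members <- unique(members)
  ae_positive <- unique(ae_positive)
  if (length(members) == 0) stop("undefined class: empty member set")
  if (length(setdiff(ae_positive, members)) > 0) {
    stop("ae_positive must be a subset of members")
  }
  length(ae_positive) / length(members)
}

#' Ingredient-level 2x2 contingency table for a (class, AE) pair
#'
#' Cells over the classification universe: `a` in-class ingredients with
#' the AE, `b` out-of-class ingredients with the AE, `c` in-class without,
#' `d` neither. `a + c` is the class size; `a + b + c + d` the universe
#' size.
#'
#' @param members class member ingredient ids (subset of `universe`).
#' @param universe all ingredients mapped into the classification scheme
#'   under analysis.
#' @param ae_positive_universe universe ingredients associated with the AE.
#' @return Object of class `contingency_2x2`: list with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
contingency <- function(members, universe, ae_positive_universe) {
  members <- unique(members)
  universe <- unique(universe)
  ae_pos <- unique(ae_positive_universe)
  if (length(setdiff(members, universe)) > 0) {
    stop("members must be a subset of universe")
  }
  if (length(setdiff(ae_pos, universe)) > 0) {
    stop("ae_positive_universe must be a subset of universe")
  }
  a <- length(intersect(members, ae_pos))
  b <- length(setdiff(ae_pos, members))
  c_ <- length(setdiff(members, ae_pos))
  d <- length(universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> a=%d b=%d c=%d d=%d (class %d / universe %d)\n",
              x$a, x$b, x$c, x$d, x$a + x$c, x$a + x$b + x$c + x$d))
  invisible(x)
}

.as_cells <- function(t) {
  if (inherits(t, "contingency_2x2")) {
    c(a = t$a, b = t$b, c = t$c, d = t$d)
  } else if (is.numeric(t) && length(t) == 4) {
    stats::setNames(as.numeric(t), c("a", "b", "c", "d"))
  } else {
    stop("expected a contingency_2x2 or a numeric vector (a, b, c, d)")
  }
}

#' Class-level proportional reporting ratio (C-PRR)
#'
#' The proportional reporting ratio computed over drug-ingredient counts in
#' a classification universe rather than case-report counts:
#' `C-PRR = (a/(a+c)) / (b/(b+d))`. A large value means the class-AE
#' association is richly reported relative to the rest of the universe; the
#' conventional signal cutoff is 2.
#'
#' Degenerate cells: `a = 0` gives 0; `b = 0` with `a > 0` gives `Inf`
#' (disproportionality is maximal but there is no out-of-class background —
#' downstream results flag this as `zero_background`). An empty class
#' (`a + c = 0`) or empty background (`b + d = 0`) is an error.
#'
#' @param t a [contingency()] table (or numeric `c(a, b, c, d)`).
#' @return Nonnegative real, possibly `Inf`.
#' @export
c_prr <- function(t) {
  z <- .as_cells(t)
  if (any(z < 0)) stop("negative contingency cells")
  if (z["a"] + z["c"] == 0) stop("undefined background: a + c = 0")
  if (z["b"] + z["d"] == 0) stop("undefined background: b + d = 0")
  if (z[["a"]] == 0) return(0)
  if (z[["b"]] == 0) return(Inf)
  (z[["a"]] / (z[["a"]] + z[["c"]])) / (z[["b"]] / (z[["b"]] + z[["d"]]))
}

#' Class-level Pearson chi-squared statistic
#'
#' Pearson's chi-squared on the ingredient 2x2 table,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with the Yates
#' continuity correction (`N (|ad - bc| - N/2)^2` in the numerator, floored
#' at 0). The conventional signal cutoff is > 4 (approximately p < 0.05 on
#' 1 df). A table with any zero marginal carries no information and returns
#' 0 with attribute `degenerate = TRUE`.
#'
#' @param t a [contingency()] table (or numeric `c(a, b, c, d)`).
#' @param correction apply the Yates continuity correction.
#' @return Nonnegative real.
#' @export
c_chi2 <- function(t, correction = FALSE) {
  z <- .as_cells(t)
  if (any(z < 0)) stop("negative contingency cells")
  a <- z[["a"]]; b <- z[["b"]]; c_ <- z[["c"]]; d <- z[["d"]]
  n <- a + b + c_ + d
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) return(structure(0, degenerate = TRUE))
  num <- abs(a * d - b * c_)
  if (correction) num <- max(0, num - n / 2)
  n * num^2 / prod(marg)
}

#' Default significance cutoffs for class-effect detection
#'
#' The combined three-criterion filter on top of the class-effect condition
#' PCR = 1: C-PRR at least 2 (the conventional PRR signal cutoff),
#' chi-squared above 4 (approximately p < 0.05), and at least 3 drug
#' ingredients in the class (the analogue of minimal case-report
#' filtering).
#'
#' @param c_prr_min minimum C-PRR (default 2).
#' @param chi2_min chi-squared threshold, strict (default 4).
#' @param min_ingredients minimum class size (default 3).
#' @param chi2_correction use the Yates continuity correction
#'   (default `FALSE`: plain Pearson).
#' @return Named list of cutoffs.
#' @export
class_effect_cutoffs <- function(c_prr_min = 2, chi2_min = 4,
                                 min_ingredients = 3,
                                 chi2_correction = FALSE) {
  stopifnot(c_prr_min > 0, chi2_min > 0, min_ingredients >= 1)
  list(c_prr_min = c_prr_min, chi2_min = chi2_min,
       min_ingredients = min_ingredients,
       chi2_correction = isTRUE(chi2_correction))
}

#' Detect statistically significant drug class effects on AEs
#'
#' Scores every (drug class, AE) pair: collapses product records to the
#' ingredient level, propagates AE associations up the AE hierarchy,
#' resolves class membership through the drug classification hierarchy,
#' builds the 2x2 ingredient contingency table against the classification
#' universe, and applies the combined filter — PCR = 1 (the class effect),
#' C-PRR >= cutoff, chi-squared > cutoff, class size >= minimum. Pairs are
#' scored independently; no multiplicity adjustment is applied beyond the
#' three-criterion rule (the `n_pairs_tested` column lets users apply their
#' own).
#'
#' @param table an `assoc_table`.
#' @param class_h drug classification `isa_hierarchy` whose leaves include
#'   ingredient ids (see [build_moa_hierarchy()] for the MoA scheme).
#' @param ae_h AE `isa_hierarchy`.
#' @param class_ids drug class ids to score (must resolve in `class_h`).
#' @param ae_ids AE (class) ids to score (must resolve in `ae_h`).
#' @param universe classification universe of ingredient ids (cells b and d
#'   count over it). Defaults to the table's ingredients that resolve as
#'   nodes of `class_h`, i.e. the ingredients mapped into the scheme under
#'   analysis; pass explicitly to include ingredients with no reported AE.
#' @param cutoffs a [class_effect_cutoffs()] list.
#' @return data.frame of class `class_effect_result`, one row per
#'   (class, AE) pair sorted by (class_id, ae_id), with columns `class_id`,
#'   `class_label`, `ae_id`, `ae_label`, `class_size`, `n_with_ae`, `a`,
#'   `b`, `c`, `d`, `pcr`, `c_prr`, `chi2`, `zero_background`,
#'   `passes_pcr`, `passes_cprr`, `passes_chi2`, `passes_min_n`,
#'   `significant`, `n_pairs_tested`. `c_prr` is `NA` when a class spans
#'   the whole universe (no background).
#' @export
detect_class_effects <- function(table, class_h, ae_h, class_ids, ae_ids,
                                 universe = NULL,
                                 cutoffs = class_effect_cutoffs()) {
  stopifnot(inherits(table, "assoc_table"),
            inherits(class_h, "isa_hierarchy"),
            inherits(ae_h, "isa_hierarchy"))
  class_ids <- as.character(class_ids)
  ae_ids <- as.character(ae_ids)
  unknown <- setdiff(class_ids, class_h$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown class id: '%s'", unknown[1]))
  }
  unknown <- setdiff(ae_ids, ae_h$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown AE id: '%s'", unknown[1]))
  }
  if (is.null(universe)) {
    universe <- intersect(ingredient_universe(table), class_h$nodes)
  }
  universe <- sort(unique(as.character(universe)))
  if (length(universe) == 0) stop("empty classification universe")

  amap <- collapse_to_ingredients(table, quiet = TRUE)
  amap <- amap[intersect(names(amap), universe)]
  amap <- propagate_ae(amap, ae_h)
  missing_ing <- setdiff(universe, names(amap))
  if (length(missing_ing) > 0) {
    empty <- stats::setNames(
      replicate(length(missing_ing), character(0), simplify = FALSE),
      missing_ing)
    amap <- c(amap, empty)
  }

  ae_positive <- lapply(ae_ids, function(ae) {
    names(amap)[vapply(amap, function(s) ae %in% s, logical(1))]
  })
  names(ae_positive) <- ae_ids
  members_by_class <- lapply(class_ids, function(cl) {
    class_members(class_h, cl, universe)
  })
  names(members_by_class) <- class_ids

  rows <- vector("list", length(class_ids) * length(ae_ids))
  k <- 0L
  for (cl in class_ids) {
    mem <- members_by_class[[cl]]
    for (ae in ae_ids) {
      k <- k + 1L
      pos <- ae_positive[[ae]]
      ct <- contingency(mem, universe, pos)
      p <- if (length(mem) > 0) pcr(mem, intersect(pos, mem)) else NA_real_
      prr <- if (ct$a + ct$c == 0 || ct$b + ct$d == 0) NA_real_ else c_prr(ct)
      chi <- as.numeric(c_chi2(ct, correction = cutoffs$chi2_correction))
      rows[[k]] <- data.frame(
        class_id = cl, ae_id = ae,
        class_size = ct$a + ct$c, n_with_ae = ct$a,
        a = ct$a, b = ct$b, c = ct$c, d = ct$d,
        pcr = p, c_prr = prr, chi2 = chi,
        zero_background = ct$b == 0 & ct$a > 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(class_id = character(0), ae_id = character(0),
                      class_size = integer(0), n_with_ae = integer(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), pcr = numeric(0), c_prr = numeric(0),
                      chi2 = numeric(0), zero_background = logical(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$class_id, res$ae_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$class_label <- node_label(class_h, res$class_id)
  res$ae_label <- node_label(ae_h, res$ae_id)
  res$passes_pcr <- !is.na(res$pcr) & res$pcr == 1
  res$passes_cprr <- !is.na(res$c_prr) & res$c_prr >= cutoffs$c_prr_min
  res$passes_chi2 <- res$chi2 > cutoffs$chi2_min
  res$passes_min_n <- res$class_size >= cutoffs$min_ingredients
  res$significant <- res$passes_pcr & res$passes_cprr &
    res$passes_chi2 & res$passes_min_n
  res$n_pairs_tested <- nrow(res)
  res <- res[, c("class_id", "class_label", "ae_id", "ae_label",
                 "class_size", "n_with_ae", "a", "b", "c", "d",
                 "pcr", "c_prr", "chi2", "zero_background",
                 "passes_pcr", "passes_cprr", "passes_chi2",
                 "passes_min_n", "significant", "n_pairs_tested")]
  class(res) <- c("class_effect_result", "data.frame")
  res
}

#' Write class-effect results as TSV
#'
#' @param res a [detect_class_effects()] result.
#' @param path output path; `Inf` C-PRR is written as `Inf`, `NA` as empty.
#' @return `path`, invisibly.
#' @export
write_class_effects <- function(res, path) {
  stopifnot(inherits(res, "class_effect_result"))
  out <- as.data.frame(res)
  for (col in c("pcr", "c_prr", "chi2")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a MoA classification hierarchy from the association table
#'
#' The master table maps each product to mechanism-of-action (MoA) class
#' ids. This helper turns that mapping into a classification hierarchy for
#' [detect_class_effects()]: each ingredient is placed under every MoA
#' class carried by a product containing it, and all MoA classes are placed
#' under a single root.
#'
#' @param table an `assoc_table`.
#' @param root_id id for the synthetic root node.
#' @return An [hierarchy()] with MoA classes and ingredient leaves.
#' @export
build_moa_hierarchy <- function(table, root_id = "MOA:root") {
  stopifnot(inherits(table, "assoc_table"))
  r <- table$records
  rows <- list()
  for (i in seq_len(nrow(r))) {
    ings <- r$ingredient_ids[[i]]
    moas <- r$moa_class_ids[[i]]
    if (length(ings) == 0 || length(moas) == 0) next
    rows[[length(rows) + 1L]] <- expand.grid(
      child = ings, parent = moas, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no product carries both ingredient and MoA ids")
  e <- unique(do.call(rbind, rows))
  moa_ids <- sort(unique(e$parent))
  e <- rbind(e, data.frame(child = moa_ids, parent = root_id,
                           stringsAsFactors = FALSE))
  hierarchy(e)
}

#' Rank the most frequently reported AEs
#'
#' AEs ordered by the number of distinct drugs associated with them, at the
#' product or the ingredient level; ties break lexicographically by AE key.
#' The AE key is the ontology id where present, else `term:<english term>`,
#' so records without an id still count here.
#'
#' @param table an `assoc_table`.
#' @param k number of top AEs to return (truncated to the number of
#'   distinct AEs).
#' @param level `"ingredient"` or `"product"`: what to count as a drug.
#' @return data.frame with columns `ae_key`, `ae_term_en`, `n_drugs`,
#'   sorted descending.
#' @export
rank_top_aes <- function(table, k, level = c("ingredient", "product")) {
  stopifnot(inherits(table, "assoc_table"), k >= 1)
  level <- match.arg(level)
  r <- table$records
  key <- .ae_key(r$ae_id, r$ae_term_en)
  if (level == "product") {
    flat <- data.frame(ae_key = key, drug = r$product_id,
                       ae_term_en = r$ae_term_en, stringsAsFactors = FALSE)
  } else {
    reps <- lengths(r$ingredient_ids)
    flat <- data.frame(
      ae_key = rep(key, reps),
      drug = unlist(r$ingredient_ids, use.names = FALSE),
      ae_term_en = rep(r$ae_term_en, reps),
      stringsAsFactors = FALSE)
  }
  flat <- unique(flat[, c("ae_key", "drug", "ae_term_en")])
  counts <- stats::aggregate(drug ~ ae_key + ae_term_en, data = flat,
                             FUN = function(v) length(unique(v)))
  names(counts)[names(counts) == "drug"] <- "n_drugs"
  counts <- counts[order(-counts$n_drugs, counts$ae_key, method = "radix"), ]
  rownames(counts) <- NULL
  utils::head(counts[, c("ae_key", "ae_term_en", "n_drugs")], k)
}
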