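test_that("product records collapse to ingredient-level AE sets", {
  recs <- rbind(
    make_records("P1", "nausea", "ING1", ae_id = "AE:nausea"),
    make_records("P2", "rash", "ING1", ae_id = "AE:rash"),
    make_records("P3", "cough", "ING2|ING3", ae_id = "AE:cough"))
  amap <- collapse_to_ingredients(association_table(recs))
  # union over an ingredient's products
  expect_equal(amap$ING1, c("AE:nausea", "AE:rash"))
  # multi-ingredient product fans the AE out to every ingredient
  expect_equal(amap$ING2, "AE:cough")
  expect_equal(amap$ING3, "AE:cough")
})

test_that("records without an AE id are excluded from the AE map with a message", {
  recs <- rbind(
    make_records("P1", "nausea", "ING1", ae_id = "AE:nausea"),
    make_records("P2", "mystery", "ING1", ae_id = NA_character_))
  tab <- association_table(recs)
  expect_message(amap <- collapse_to_ingredients(tab), "1 record")
  expect_equal(amap$ING1, "AE:nausea")
})

test_that("pcr is the exact member ratio with subset and emptiness contracts", {
  expect_equal(pcr(paste0("i", 1:4), paste0("i", 1:4)), 1)
  expect_equal(pcr(paste0("i", 1:5), character(0)), 0)
  expect_equal(pcr(paste0("i", 1:4), c("i1", "i2")), 0.5)
  expect_error(pcr(character(0), character(0)), "empty member set")
  expect_error(pcr(c("i1"), c("i2")), "subset")
})

test_that("contingency counts the four cells by definition", {
  uni <- paste0("i", 1:10)
  ct <- contingency(c("i1", "i2", "i3"), uni, c("i1", "i2", "i3", "i5"))
  expect_equal(unclass(ct)[c("a", "b", "c", "d")],
               list(a = 3L, b = 1L, c = 0L, d = 6L))
  # members = universe -> b = d = 0
  ct2 <- contingency(uni, uni, c("i1"))
  expect_equal(c(ct2$b, ct2$d), c(0L, 0L))
  expect_error(contingency(c("zz"), uni, character(0)), "subset of universe")
})

test_that("contingency matches brute-force per-element classification on random sets", {
  set.seed(11)
  uni <- sprintf("i%02d", 1:30)
  for (rep in 1:20) {
    mem <- sample(uni, sample(1:20, 1))
    pos <- sample(uni, sample(0:25, 1))
    ct <- contingency(mem, uni, pos)
    cells <- table(factor(uni %in% mem, c(TRUE, FALSE)),
                   factor(uni %in% pos, c(TRUE, FALSE)))
    expect_equal(c(ct$a, ct$b, ct$c, ct$d),
                 as.integer(c(cells[1, 1], cells[2, 1],
                              cells[1, 2], cells[2, 2])))
  }
})

test_that("c_prr substitutes the 2x2 cells with degenerate-cell contracts", {
  expect_equal(c_prr(c(3, 1, 0, 6)), 7)
  expect_equal(c_prr(c(1, 1, 1, 1)), 1)
  expect_equal(c_prr(c(0, 3, 2, 5)), 0)
  expect_identical(c_prr(c(3, 0, 0, 7)), Inf)
  expect_error(c_prr(c(0, 1, 0, 1)), "a \\+ c = 0")
  expect_error(c_prr(c(1, 0, 1, 0)), "b \\+ d = 0")
})

test_that("c_chi2 equals the independent Pearson oracle, with and without Yates", {
  expect_equal(c_chi2(c(2, 2, 2, 2)), 0)
  # verified value from stats::chisq.test on matrix(c(3,0,1,6))
  expect_equal(c_chi2(c(3, 1, 0, 6)), 6.4285714285714, tolerance = 1e-10)
  expect_lt(c_chi2(c(3, 1, 0, 6), correction = TRUE), c_chi2(c(3, 1, 0, 6)))
  set.seed(5150)
  for (rep in 1:50) {
    z <- random_cells()
    mt <- matrix(c(z["a"], z["b"], z["c"], z["d"]), 2, 2, byrow = TRUE)
    if (any(rowSums(mt) == 0) || any(colSums(mt) == 0)) {
      expect_equal(as.numeric(c_chi2(z)), 0)
      next
    }
    for (corr in c(FALSE, TRUE)) {
      oracle <- suppressWarnings(
        stats::chisq.test(mt, correct = corr)$statistic)
      expect_equal(as.numeric(c_chi2(z, correction = corr)),
                   as.numeric(oracle), tolerance = 1e-10)
    }
  }
  expect_error(c_chi2(c(-1, 1, 1, 1)), "negative")
  expect_true(isTRUE(attr(c_chi2(c(0, 0, 3, 4)), "degenerate")))
})

test_that("statistic invariances hold on random contingency tables", {
  set.seed(2024)
  for (rep in 1:200) {
    z <- random_cells()
    # chi-squared invariant under swapping rows and under swapping columns
    expect_equal(c_chi2(z), c_chi2(z[c("c", "d", "a", "b")]))
    expect_equal(c_chi2(z), c_chi2(z[c("b", "a", "d", "c")]))
    # complement equivariance: swapping class and complement inverts C-PRR
    if (z["a"] > 0 && z["b"] > 0) {
      expect_equal(c_prr(z[c("b", "a", "d", "c")]), 1 / c_prr(z),
                   tolerance = 1e-12)
    }
    # PCR bounds and the PCR = 1 <=> c = 0 equivalence
    p <- z[["a"]] / (z[["a"]] + z[["c"]])
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p == 1, z[["c"]] == 0)
  }
})

test_that("detect_class_effects flags exactly the planted pair on noiseless synthetic data", {
  cfg <- synthetic_config(n_ingredients = 20, class_sizes = rep(4L, 5),
                          n_leaf_aes = 10, p_bg = 0,
                          planted_effects = list(c(2L, 3L)), seed = 31)
  g <- generate_synthetic(cfg)
  res <- detect_class_effects(g$table, g$class_hierarchy, g$ae_hierarchy,
                              g$class_ids, g$leaf_ae_ids,
                              universe = g$ingredients)
  sig <- res[res$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$class_id, g$planted$class_id)
  expect_equal(sig$ae_id, g$planted$ae_id)
  expect_equal(sig$pcr, 1)
  expect_true(sig$zero_background)
  expect_identical(sig$c_prr, Inf)
  # results sorted by (class_id, ae_id), conjunction flag consistent
  expect_equal(order(res$class_id, res$ae_id), seq_len(nrow(res)))
  expect_equal(res$significant,
               res$passes_pcr & res$passes_cprr & res$passes_chi2 &
                 res$passes_min_n)
  expect_equal(unique(res$n_pairs_tested), nrow(res))
})

test_that("a planted class of size 2 fails the minimum-ingredient filter despite PCR = 1", {
  cfg <- synthetic_config(n_ingredients = 12,
                          class_sizes = c(2L, rep(5L, 2)),
                          n_leaf_aes = 8, p_bg = 0,
                          planted_effects = list(c(1L, 1L)), seed = 5)
  g <- generate_synthetic(cfg)
  res <- detect_class_effects(g$table, g$class_hierarchy, g$ae_hierarchy,
                              g$class_ids, g$leaf_ae_ids,
                              universe = g$ingredients)
  row <- res[res$class_id == g$planted$class_id &
               res$ae_id == g$planted$ae_id, ]
  expect_equal(row$pcr, 1)
  expect_false(row$passes_min_n)
  expect_false(row$significant)
  expect_equal(sum(res$significant), 0)
})

test_that("detection works at propagated AE-class level and via the MoA route", {
  # two products of two ingredients, each with a distinct digestive leaf AE:
  # at the digestive-class level both ingredients are positive
  recs <- rbind(
    make_records("P1", "diarrhea", "ING1", "MOA:x", ae_id = "AE:diarrhea"),
    make_records("P2", "nausea", "ING2", "MOA:x", ae_id = "AE:nausea"),
    make_records("P3", "headache", "ING3", "MOA:y", ae_id = "AE:headache"))
  tab <- association_table(recs)
  ae_h <- toy_ae_hierarchy()
  moa_h <- build_moa_hierarchy(tab)
  res <- detect_class_effects(tab, moa_h, ae_h,
                              class_ids = c("MOA:x", "MOA:y"),
                              ae_ids = c("AE:dig", "AE:neuro"))
  x_dig <- res[res$class_id == "MOA:x" & res$ae_id == "AE:dig", ]
  expect_equal(x_dig$pcr, 1)
  expect_equal(c(x_dig$a, x_dig$b, x_dig$c, x_dig$d), c(2, 0, 0, 1))
  expect_equal(res[res$class_id == "MOA:y" & res$ae_id == "AE:dig", "pcr"], 0)
  expect_error(
    detect_class_effects(tab, moa_h, ae_h, "MOA:nope", "AE:dig"),
    "unknown class id")
})

test_that("rank_top_aes counts distinct drugs per AE and matches a brute-force oracle", {
  recs <- rbind(
    make_records(sprintf("P%d", 1:5), "nausea", sprintf("ING%d", c(1, 1, 2, 3, 4)),
                 ae_id = "AE:n"),
    make_records(sprintf("P%d", 6:7), "rash", sprintf("ING%d", 5:6),
                 ae_id = "AE:r"))
  tab <- association_table(recs)
  top <- rank_top_aes(tab, k = 10, level = "product")
  expect_equal(top$ae_key[1], "AE:n")
  expect_equal(top$n_drugs, c(5, 2))
  top_ing <- rank_top_aes(tab, k = 1, level = "ingredient")
  expect_equal(top_ing$n_drugs, 4)

  set.seed(77)
  n <- 40
  recs <- make_records(sprintf("P%02d", sample(12, n, TRUE)),
                       "term", sprintf("ING%d", sample(6, n, TRUE)),
                       ae_id = sprintf("AE:%d", sample(5, n, TRUE)))
  recs$ae_term_en <- recs$ae_id
  tab <- association_table(recs)
  top <- rank_top_aes(tab, k = 100, level = "product")
  r <- tab$records
  oracle <- sort(tapply(r$product_id, r$ae_id,
                        function(v) length(unique(v))), decreasing = TRUE)
  expect_equal(sort(top$n_drugs, decreasing = TRUE), as.vector(oracle))
  expect_true(all(diff(top$n_drugs) <= 0))
})
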