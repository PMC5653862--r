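test_that("association table counts products and AE terms and collapses duplicates", {
  recs <- rbind(
    make_records("P1", "nausea", "ING1", ae_id = "AE:nausea"),
    make_records("P1", "rash", "ING1", ae_id = "AE:rash"),
    make_records("P2", "nausea", "ING2", ae_id = "AE:nausea"))
  tab <- association_table(recs)
  expect_s3_class(tab, "assoc_table")
  rep <- load_report(tab)
  expect_equal(rep$n_records, 3)
  expect_equal(length(product_universe(tab)), 2)
  expect_equal(rep$n_ae_terms_en, 2)

  # same (product, AE) on two rows -> one record after collapse
  dup <- rbind(recs, make_records("P1", "nausea", "ING1", ae_id = "AE:nausea"))
  expect_equal(load_report(association_table(dup))$n_records, 3)
})

test_that("ingredient universe is the union over records and multi-ingredient cells split on |", {
  recs <- rbind(
    make_records("P1", "cough", "ING1|ING2", ae_id = "AE:c"),
    make_records("P2", "rash", "ING2", ae_id = "AE:r"))
  tab <- association_table(recs)
  expect_equal(ingredient_universe(tab), c("ING1", "ING2"))
})

test_that("loading errors are structured: missing column, malformed row, bad encoding", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("product_id\tae_term_en", "P1\tnausea"), path)
  expect_error(read_association_table(path), "missing mandatory column",
               class = "aeclass_load_error")

  tab <- association_table(make_records("P1", "nausea"))
  ok <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab, ok)
  expect_s3_class(read_association_table(ok, quiet = TRUE), "assoc_table")

  expect_error(association_table(make_records(c("P1", ""), c("n", "r"))),
               "malformed row 2")

  bad <- withr::local_tempfile(fileext = ".tsv")
  con <- file(bad, "wb")
  writeBin(c(charToRaw(paste(c(paste(
    c("product_id", "product_name_cn", "product_name_en", "ingredient_ids",
      "moa_class_ids", "ae_term_cn", "ae_term_en", "ae_id"),
    collapse = "\t"), "P1\t"), collapse = "\n")), as.raw(c(0xff, 0xfe)),
    charToRaw("\tx\t\t\tnausea\t\n")), con)
  close(con)
  expect_error(read_association_table(bad), "not valid UTF-8",
               class = "aeclass_load_error")
})

test_that("write/load round-trips record-identically and load is order-independent", {
  recs <- rbind(
    make_records("P2", "rash", "ING2|ING3", "MOA1", ae_id = "AE:r",
                 ae_term_cn = "皮疹"),
    make_records("P1", "nausea", "ING1", "MOA1|MOA2", ae_id = "AE:n"),
    make_records("P3", "cough", "", ae_id = NA_character_))
  tab <- association_table(recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab, path)
  tab2 <- read_association_table(path, quiet = TRUE)
  expect_equal(tab2$records, tab$records)
  # permuted input rows give the same table
  perm <- association_table(recs[c(3, 1, 2), ])
  expect_equal(perm$records, tab$records)
  # and a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab2, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("hierarchy loads from edge lists, finds roots, and rejects cycles", {
  h <- hierarchy(data.frame(child = c("B", "C", "D"),
                            parent = c("A", "A", "B")))
  expect_equal(h$roots, "A")
  expect_equal(descendants(h, "A"), c("B", "C", "D"))
  expect_error(hierarchy(data.frame(child = c("A", "B"),
                                    parent = c("B", "A"))),
               "cycle")
})

test_that("OBO-subset fixture parses to the same DAG as the equivalent edge list", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: AE:0001", "name: adverse event", "",
    "[Term]", "id: AE:0002", "name: digestive system AE",
    "is_a: AE:0001 ! adverse event", "",
    "[Term]", "id: AE:0003", "name: nervous system AE",
    "is_a: AE:0001 ! adverse event", "",
    "[Term]", "id: AE:0004", "name: diarrhea AE",
    "is_a: AE:0002 ! digestive system AE", "",
    "[Term]", "id: AE:0005", "name: nausea AE",
    "is_a: AE:0002"), obo)
  h_obo <- read_hierarchy(obo, format = "obo")
  h_edge <- hierarchy(data.frame(
    child = c("AE:0002", "AE:0003", "AE:0004", "AE:0005"),
    parent = c("AE:0001", "AE:0001", "AE:0002", "AE:0002")))
  expect_equal(h_obo$edges[order(h_obo$edges$child), c("child", "parent")],
               h_edge$edges[order(h_edge$edges$child), c("child", "parent")],
               ignore_attr = TRUE)
  expect_equal(h_obo$roots, h_edge$roots)
  expect_equal(node_label(h_obo, "AE:0004"), "diarrhea AE")

  # dangling is_a target is named in the error
  writeLines(c("[Term]", "id: X:1", "is_a: X:9"), obo)
  expect_error(read_hierarchy(obo, format = "obo"), "dangling parent id 'X:9'")
})

test_that("hierarchy TSV round-trips through write_hierarchy", {
  h <- toy_ae_hierarchy()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hierarchy(h, path)
  h2 <- read_hierarchy(path)
  expect_equal(h2$nodes, h$nodes)
  expect_equal(h2$roots, h$roots)
  expect_setequal(paste(h2$edges$child, h2$edges$parent),
                  paste(h$edges$child, h$edges$parent))
})
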