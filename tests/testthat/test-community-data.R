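test_that("feature table TSV round-trips in both orientations", {
  p <- write_fixture(c("feature_id\ts1\ts2", "f1\t5\t0", "f2\t1\t2",
                       "f3\t0\t7"), "ft.tsv")
  ft <- read_feature_table(p)
  expect_equal(unname(library_sizes(ft)), c(6, 9))
  expect_equal(ft$feature_ids, c("f1", "f2", "f3"))
  expect_identical(ft$counts["f1", "s2"], 0L)

  pt <- write_fixture(c("sample_id\tf1\tf2\tf3", "s1\t5\t1\t0",
                        "s2\t0\t2\t7"), "ft_t.tsv")
  ft2 <- read_feature_table(pt, dialect = "samples_by_features")
  expect_identical(ft2$counts, ft$counts)
  expect_identical(read_feature_table(pt, "tsv_samples_by_features")$counts,
                   ft$counts)

  out <- file.path(tempdir(), "ft_out.tsv")
  write_feature_table(ft, out)
  expect_identical(readLines(out), readLines(p))
})

test_that("malformed feature tables fail with the offending cell named", {
  bad <- write_fixture(c("feature_id\ts1", "f1\t-3"), "neg.tsv")
  expect_error(read_feature_table(bad), "f1.*s1|s1.*f1")
  nonint <- write_fixture(c("feature_id\ts1", "f1\t2.5"), "frac.tsv")
  expect_error(read_feature_table(nonint), "f1")
  txt <- write_fixture(c("feature_id\ts1", "f1\tabc"), "txt.tsv")
  expect_error(read_feature_table(txt), "abc")
  dup <- write_fixture(c("feature_id\ts1", "f1\t1", "f1\t2"), "dup.tsv")
  expect_error(read_feature_table(dup), "duplicate")
  expect_error(feature_table(matrix(0, 1, 1)), "library size")
})

test_that("lineage parsing enforces prefixes and prefix closure", {
  tx <- taxonomy(c(
    a = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__;g__;s__",
    b = "k__Archaea;p__Euryarchaeota",
    c = "k__Bacteria;p__Chloroflexi;c__Anaerolineae;o__;f__Oops;g__;s__"))
  m <- unclass(tx)
  expect_equal(unname(m["a", "order"]), "Clostridiales")
  expect_true(is.na(m["a", "family"]))
  expect_equal(unname(m["b", "phylum"]), "Euryarchaeota")
  expect_true(all(is.na(m["b", c("class", "order", "family")])))
  # prefix closure truncates names below the first unassigned rank
  expect_true(is.na(m["c", "family"]))
  expect_error(taxonomy("k__Bacteria;x__Foo"), "prefix")
  expect_error(taxonomy("p__Firmicutes;k__Bacteria"), "prefix")
})

test_that("taxonomy TSV round-trips through the canonical form", {
  tx <- taxonomy(c(f1 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__;s__",
                   f2 = "k__Archaea;p__;c__;o__;f__;g__;s__"))
  p <- file.path(tempdir(), "tax.tsv")
  write_taxonomy(tx, p)
  expect_identical(unclass(read_taxonomy(p)), unclass(tx))
})

test_that("rank collapse sums shared labels and applies fallback labels", {
  md <- sample_metadata(c("h1_cecum", "h1_feces"), c("h1", "h1"),
                        c("cecum", "feces"))
  ft <- feature_table(matrix(c(3, 4, 5, 2, 1, 1, 1, 1), 4, 2,
                             dimnames = list(paste0("f", 1:4),
                                             c("h1_cecum", "h1_feces"))))
  tx <- taxonomy(c(
    f1 = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae",
    f2 = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae",
    f3 = "k__Bacteria;p__Synergistetes;c__Synergistia;o__Synergistales",
    f4 = "k__Archaea;p__Euryarchaeota"))
  fam <- collapse_to_rank(ft, tx, md, "family")
  expect_setequal(fam$taxa, c("Prevotellaceae", "Synergistales (o)",
                              "Euryarchaeota (p)"))
  expect_equal(fam$abund["Prevotellaceae", "h1_cecum"], 7)
  expect_equal(sum(fam$abund), sum(ft$counts))

  # order-independence of feature ordering
  perm <- c(3, 1, 4, 2)
  ft2 <- feature_table(ft$counts[perm, ])
  fam2 <- collapse_to_rank(ft2, tx, md, "family")
  expect_identical(fam2$abund, fam$abund)

  # class-rank fallback
  tx2 <- taxonomy(c(f1 = "k__Bacteria;p__Chloroflexi;c__Anaerolineae"))
  ft3 <- feature_table(matrix(c(2, 3), 1, 2,
                              dimnames = list("f1",
                                              c("h1_cecum", "h1_feces"))))
  expect_equal(collapse_to_rank(ft3, tx2, md, "family")$taxa,
               "Anaerolineae (c)")
})

test_that("collapse validates metadata coverage and design uniqueness", {
  ft <- feature_table(matrix(c(1, 2), 1, 2,
                             dimnames = list("f1", c("sA", "sB"))))
  tx <- taxonomy(c(f1 = "k__Bacteria;p__Firmicutes"))
  md_missing <- sample_metadata("sA", "h1", "cecum")
  expect_error(collapse_to_rank(ft, tx, md_missing), "sB")
  expect_error(sample_metadata(c("sA", "sB"), c("h1", "h1"),
                               c("cecum", "cecum")), "duplicated")
  expect_error(collapse_to_rank(
    feature_table(matrix(1, 1, 1, dimnames = list("f2", "sA"))),
    tx, md_missing), "absent from taxonomy")
})

test_that("classification rate is count-weighted and monotone in rank depth", {
  md <- sample_metadata("s1", "h1", "cecum")
  ft <- feature_table(matrix(c(10, 10), 2, 1,
                             dimnames = list(c("f1", "f2"), "s1")))
  tx <- taxonomy(c(
    f1 = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia;s__",
    f2 = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales"))
  expect_equal(classification_rate(ft, tx, "family"), 0.5)
  expect_equal(classification_rate(ft, tx, "kingdom"), 1.0)
  rates <- vapply(c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species"),
                  function(r) classification_rate(ft, tx, r), numeric(1))
  expect_true(all(diff(rates) <= 0))
  # weighting by counts, not features
  ft2 <- feature_table(matrix(c(30, 10), 2, 1,
                              dimnames = list(c("f1", "f2"), "s1")))
  expect_equal(classification_rate(ft2, tx, "family"), 0.75)
})

test_that("family table round-trips with metadata and validates design", {
  md <- sample_metadata(c("a", "b"), c("h1", "h1"), c("cecum", "feces"))
  fam <- family_table(matrix(c(1, 2, 3, 4), 2, 2,
                             dimnames = list(c("t1", "t2"), c("a", "b"))),
                      md$body_site, md$horse_id)
  p <- file.path(tempdir(), "fam.tsv")
  write_family_table(fam, p)
  fam2 <- read_family_table(p, md)
  expect_equal(fam2$abund, fam$abund)
  expect_equal(as.character(fam2$site), as.character(fam$site))
  expect_error(family_table(matrix(1, 1, 2), c("cecum", "cecum"),
                            c("h1", "h1")), "duplicated")
  expect_error(family_table(matrix(-1, 1, 1), "cecum", "h1"),
               "non-negative")
})
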