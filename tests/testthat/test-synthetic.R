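test_that("a fixed seed reproduces the study byte-for-byte", {
  d <- synthetic_design(n_horses = 3, n_families = 12, seed = 11,
                        library_size_mean = 2000)
  s1 <- generate_study(d)
  s2 <- generate_study(d)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$family_table$abund, s2$family_table$abund)
  expect_identical(unclass(s1$taxonomy), unclass(s2$taxonomy))
  # a different seed changes the draw
  d3 <- synthetic_design(n_horses = 3, n_families = 12, seed = 12,
                         library_size_mean = 2000)
  expect_false(identical(generate_study(d3)$table$counts, s1$table$counts))
})

test_that("generated counts are consistent: integer, complete, conserved", {
  d <- synthetic_design(n_horses = 4, n_families = 20, seed = 3,
                        library_size_mean = 5000,
                        features_per_family = c(2, 1))
  s <- generate_study(d)
  expect_true(all(s$table$counts >= 0))
  expect_equal(ncol(s$table$counts), 4 * 4)
  # feature counts sum to the family bookkeeping
  expect_equal(sum(s$table$counts), sum(s$family_table$abund))
  expect_equal(unname(colSums(s$family_table$abund)),
               unname(s$truth$library_sizes))
  # collapse of the emitted table reproduces the generator's bookkeeping
  fam <- collapse_to_rank(s$table, s$taxonomy, s$metadata)
  expect_equal(fam$abund, s$family_table$abund)
  # classification_rate recomputes the generator's read-fraction bookkeeping
  expect_equal(classification_rate(s$table, s$taxonomy, "family"),
               s$truth$family_read_fraction, tolerance = 1e-12)
})

test_that("planted indicators hit their faithfulness and exclusiveness targets", {
  pl <- planted_indicator("Family005", "cecum", exclusiveness = 0.9,
                          faithfulness = 1, mean_abundance = 0.08)
  d <- synthetic_design(n_horses = 24, n_families = 30, seed = 5,
                        library_size_mean = 1e5, library_size_cv = 0.1,
                        horse_effect_sd = 0.3, planted_indicators = pl)
  s <- generate_study(d)
  fam <- s$family_table
  lab <- "Family005"
  f_hat <- faithfulness(fam, "cecum", lab)
  e_hat <- exclusiveness(fam, "cecum", lab)
  expect_equal(f_hat, 1)
  expect_equal(e_hat, 0.9, tolerance = 0.05)

  # partial faithfulness is realised exactly as k carriers out of n horses
  pl2 <- planted_indicator("Family003", "feces", exclusiveness = 1,
                           faithfulness = 0.5, mean_abundance = 0.05)
  d2 <- synthetic_design(n_horses = 24, n_families = 10, seed = 6,
                         library_size_mean = 1e5, planted_indicators = pl2)
  s2 <- generate_study(d2)
  expect_equal(faithfulness(s2$family_table, "feces", "Family003"), 0.5)
  expect_equal(exclusiveness(s2$family_table, "feces", "Family003"), 1)
})

test_that("a written study round-trips through the community readers", {
  pl <- planted_indicator("Family002", "cecum", exclusiveness = 0.8,
                          faithfulness = 1, mean_abundance = 0.05)
  s <- generate_study(synthetic_design(n_horses = 3, n_families = 8,
                                       library_size_mean = 1500, seed = 4,
                                       planted_indicators = pl))
  dir <- file.path(tempdir(), "study_out")
  write_study(s, dir)
  tab <- read_feature_table(file.path(dir, "feature_table.tsv"))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(tab$counts, s$table$counts)
  expect_identical(unclass(tax), unclass(s$taxonomy))
  fam <- collapse_to_rank(tab, tax, md)
  expect_equal(fam$abund, s$family_table$abund)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$taxon, "Family002")
  expect_equal(truth$exclusiveness, 0.8)
})

test_that("infeasible planting is rejected before sampling", {
  expect_error(synthetic_design(planted_indicators = planted_indicator(
    "Family001", c("cecum", "ventral_colon", "dorsal_colon", "feces"),
    exclusiveness = 0.8)), "off-target")
  expect_error(synthetic_design(planted_indicators = planted_indicator(
    "Family001", "cecum", exclusiveness = 0.9, mean_abundance = 0)),
    "positive mean abundance")
  expect_error(synthetic_design(planted_indicators = planted_indicator(
    "Family001", "cecum", faithfulness = 0.4)), "multiple of 1/n_horses")
  expect_error(synthetic_design(planted_indicators = planted_indicator(
    "Family001", "cecum", exclusiveness = 1.2)), "exclusiveness")
})

test_that("null design is exchangeable: between-site distances match within-site", {
  d <- synthetic_design(n_horses = 6, n_families = 30, seed = 21,
                        horse_effect_sd = 0, overdispersion = Inf,
                        library_size_mean = 20000, library_size_cv = 0)
  s <- generate_study(d)
  dm <- unclass(bray_curtis(s$family_table))
  site <- s$family_table$site
  same <- outer(site, site, "==")
  ut <- upper.tri(dm)
  within <- mean(dm[ut & same])
  between <- mean(dm[ut & !same])
  expect_equal(within, between, tolerance = 0.02)
})

test_that("the hindgut preset encodes the proximal/distal community shift", {
  d <- pelvic_flexure_preset(seed = 1)
  expect_equal(d$n_families, 87)
  expect_equal(d$n_horses, 6)
  phyla <- vapply(d$lineages, function(l) parse_lineage(l)[2] %||% NA_character_,
                  character(1), USE.NAMES = FALSE)
  bact <- phyla == "Bacteroidetes" & !is.na(phyla)
  agg <- rowSums(d$base_composition[, bact])
  expect_equal(unname(agg[c("cecum", "ventral_colon")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(unname(agg[c("dorsal_colon", "feces")]), c(0.3, 0.3),
               tolerance = 1e-6)
  eury <- phyla == "Euryarchaeota" & !is.na(phyla)
  expect_true(all(diff(rowSums(d$base_composition[, eury])) > 0))
  # roughly 60% of expected reads family-assigned
  assigned <- vapply(d$lineages, function(l) !is.na(parse_lineage(l)[5]),
                     logical(1), USE.NAMES = FALSE)
  expect_equal(mean(colMeans(d$base_composition)[assigned] |> sum()), 0.6,
               tolerance = 0.05)
})

test_that("preset studies cluster at the pelvic flexure on PCoA axis 1", {
  s <- generate_study(pelvic_flexure_preset(seed = 42))
  rare <- rarefy(s$table, 30000, seed = 1)
  fam <- collapse_to_rank(rare, s$taxonomy, s$metadata)
  dm <- bray_curtis(sqrt_transform(fam))
  ord <- pcoa(dm)
  split <- ifelse(fam$site %in% c("cecum", "ventral_colon"), "prox", "dist")
  # axis-1 clusters and a positive silhouette for the 2-cluster split
  expect_true(max(ord$coordinates[split == "prox", 1]) <
                min(ord$coordinates[split == "dist", 1]) ||
              min(ord$coordinates[split == "prox", 1]) >
                max(ord$coordinates[split == "dist", 1]))
  expect_gt(mean_silhouette(dm, split), 0)
})
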