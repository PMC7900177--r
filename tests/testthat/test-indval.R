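test_that("faithfulness and exclusiveness follow their definitions", {
  # 2 sites x 3 horses, one taxon, hand-built presence pattern
  ab <- matrix(c(5, 0, 3, 0, 2, 0), 1, 6)  # present in horses 1..3 at site A
  fam <- family_table(ab, site = rep(c("A", "B"), 3),
                      horse = rep(c("h1", "h2", "h3"), each = 2),
                      taxa = "t")
  expect_equal(faithfulness(fam, "A", "t"), 1)
  expect_equal(faithfulness(fam, "B", "t"), 0)
  expect_equal(exclusiveness(fam, "A", "t"), 1)

  # means (2, 1, 1, 0) across four sites give E = 0.5 at site 1
  ab4 <- matrix(rep(c(2, 1, 1, 0), 2), 1, 8)
  fam4 <- family_table(ab4, site = rep(c("s1", "s2", "s3", "s4"), 2),
                       horse = rep(c("h1", "h2"), each = 4), taxa = "t")
  expect_equal(exclusiveness(fam4, "s1", "t"), 0.5)
  expect_equal(faithfulness(fam4, "s4", "t"), 0)
  # present in 3 of 6 horses -> 0.5
  ab6 <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6)
  fam6 <- family_table(ab6, site = rep("A", 6), horse = paste0("h", 1:6),
                       taxa = "t")
  expect_equal(faithfulness(fam6, "A", "t"), 0.5)
})

test_that("IndVal equals the naive triple-loop oracle to 1e-12", {
  cmb <- list(c(1, 2), c(2, 3), c(1, 3))
  for (k in 1:100) {
    fam <- random_family_table(ns = 3, nh = 4, nt = 10, seed = k)
    arr <- family_array(fam)
    fit <- indval(fam, n_perm = 1, seed = 1)
    oracle <- oracle_indval(arr)
    expect_equal(unname(fit$E), oracle$E, tolerance = 1e-12)
    expect_equal(unname(fit$F), oracle$F, tolerance = 1e-12)
    expect_equal(unname(fit$IV), oracle$IV, tolerance = 1e-12)
    fitc <- indval(fam, combinations = cmb, n_perm = 1, seed = 1)
    oc <- oracle_indval(arr, cmb)
    expect_equal(unname(fitc$IV), oc$IV, tolerance = 1e-12)
    expect_equal(unname(fitc$E), oc$E, tolerance = 1e-12)
  }
})

test_that("IndVal invariants: IV = sqrt(EF), E sums to one, bounds", {
  fam <- random_family_table(ns = 4, nh = 6, nt = 25, seed = 7)
  fit <- indval(fam, n_perm = 19, seed = 2)
  expect_equal(fit$IV, sqrt(fit$E * fit$F), tolerance = 1e-12)
  expect_true(all(fit$IV >= 0 & fit$IV <= 1 + 1e-12))
  sums <- colSums(fit$E)
  expect_true(all(abs(sums - 1) < 1e-12 | sums == 0))
  # combination with |C| = 1 reduces exactly to the single-site formula
  fit1 <- indval(fam, combinations = list(1, 2, 3, 4), n_perm = 1, seed = 1)
  expect_equal(unname(fit1$IV), unname(fit$IV), tolerance = 1e-12)
})

test_that("perfect and degenerate indicators take their limit values", {
  # taxon only in site A, present in every horse: E = F = IV = 1
  ab <- rbind(t1 = c(4, 0, 6, 0, 5, 0, 9, 0),
              t2 = c(1, 1, 1, 1, 1, 1, 1, 1))
  fam <- family_table(ab, site = rep(c("A", "B"), 4),
                      horse = rep(paste0("h", 1:4), each = 2))
  fit <- indval(fam, n_perm = 99, seed = 1)
  expect_equal(fit$stats$IV[1], 1)
  expect_equal(fit$stats$group[1], "A")
  # uniform taxon: E = 1/2 at each of 2 sites, F = 1
  expect_equal(unname(fit$E[, "t2"]), c(0.5, 0.5))
  # absent taxon is kept with IV 0 and p 1
  fam0 <- family_table(rbind(ab, t3 = 0 * ab[1, ]),
                       site = rep(c("A", "B"), 4),
                       horse = rep(paste0("h", 1:4), each = 2))
  fit0 <- indval(fam0, n_perm = 99, seed = 1)
  expect_equal(fit0$stats$IV[fit0$stats$taxon == "t3"], 0)
  expect_equal(fit0$stats$p_raw[fit0$stats$taxon == "t3"], 1)
})

test_that("combined-site groups use the merged-group formula", {
  # uniform taxon across 4 sites, C of size 2: F = 1, E = 1/3
  ab <- matrix(rep(c(2, 2, 2, 2), 3), 1, 12)
  fam <- family_table(ab, site = rep(c("s1", "s2", "s3", "s4"), 3),
                      horse = rep(paste0("h", 1:3), each = 4), taxa = "t")
  fit <- indval(fam, combinations = list(c("s1", "s2")), n_perm = 9,
                seed = 1)
  expect_equal(unname(fit$E[1, 1]), 1 / 3)
  expect_equal(unname(fit$F[1, 1]), 1)
  expect_equal(unname(fit$IV[1, 1]), sqrt(1 / 3))
  # taxon confined to C in every horse: IV = 1
  ab2 <- matrix(rep(c(3, 5, 0, 0), 3), 1, 12)
  fam2 <- family_table(ab2, site = rep(c("s1", "s2", "s3", "s4"), 3),
                       horse = rep(paste0("h", 1:3), each = 4), taxa = "t")
  fit2 <- indval(fam2, combinations = list(c("s1", "s2")), n_perm = 9,
                 seed = 1)
  expect_equal(unname(fit2$IV[1, 1]), 1)
  expect_error(indval(fam2, combinations = list(1:4), n_perm = 9),
               "all sites")
})

test_that("blocked randomization is deterministic, granular and degenerate-safe", {
  fam <- random_family_table(ns = 4, nh = 6, nt = 12, seed = 3)
  f1 <- indval(fam, n_perm = 199, seed = 5)
  f2 <- indval(fam, n_perm = 199, seed = 5)
  expect_identical(f1$stats$p_raw, f2$stats$p_raw)
  # add-one convention: p in {1/200, ..., 200/200}
  expect_true(all(abs(f1$stats$p_raw * 200 -
                        round(f1$stats$p_raw * 200)) < 1e-12))
  expect_true(all(f1$stats$p_raw >= 1 / 200))
  # a constant taxon has a permutation-invariant IV, so p = 1
  abc <- matrix(5, 1, 8)
  famc <- family_table(abc, site = rep(c("A", "B"), 4),
                       horse = rep(paste0("h", 1:4), each = 2), taxa = "t")
  fitc <- indval(famc, n_perm = 99, seed = 1)
  expect_equal(fitc$stats$p_raw, 1)
})

test_that("the generic blocked test agrees with the specialised indval path", {
  fam <- random_family_table(ns = 3, nh = 4, nt = 6, seed = 9)
  stat <- function(x) {
    arr <- family_array(x)
    apply(oracle_indval(arr)$IV, 2, max)
  }
  gen <- blocked_randomization_test(fam, stat, n_perm = 99, seed = 4)
  fit <- indval(fam, n_perm = 99, seed = 4)
  expect_equal(unname(gen$observed), fit$stats$IV, tolerance = 1e-12)
  expect_equal(unname(gen$p), fit$stats$p_raw)
})

test_that("results are invariant to a common rescaling of all samples", {
  fam <- random_family_table(ns = 4, nh = 6, nt = 15, seed = 13)
  fam2 <- fam
  fam2$abund <- fam$abund * 7.3
  f1 <- indval(fam, n_perm = 99, seed = 8)
  f2 <- indval(fam2, n_perm = 99, seed = 8)
  expect_equal(f1$IV, f2$IV, tolerance = 1e-12)
  expect_equal(f1$stats$p_raw, f2$stats$p_raw)
  # per-sample common factors (even depths) also leave E, F, IV unchanged
  fam3 <- fam
  fam3$abund <- sweep(fam$abund, 2, rep(2, ncol(fam$abund)), "*")
  expect_equal(indval(fam3, n_perm = 1, seed = 1)$IV, f1$IV,
               tolerance = 1e-12)
})

test_that("raising a taxon in its best site never lowers its IV there", {
  fam <- random_family_table(ns = 3, nh = 4, nt = 8, seed = 17)
  fit <- indval(fam, n_perm = 1, seed = 1)
  for (r in 1:8) {
    site_idx <- match(fit$stats$group[r], levels(fam$site))
    sel <- as.integer(fam$site) == site_idx
    fam_up <- fam
    fam_up$abund[r, sel] <- fam_up$abund[r, sel] * 2 + 1
    fit_up <- indval(fam_up, n_perm = 1, seed = 1)
    expect_gte(fit_up$IV[site_idx, r], fit$IV[site_idx, r] - 1e-12)
  }
})

test_that("BH step-up matches hand computation and selects correctly", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(out$selected, 1:3)
  expect_equal(bh_fdr(0.04)$q, 0.04)
  expect_equal(bh_fdr(0.04)$selected, 1L)
  expect_equal(bh_fdr(rep(0.001, 10))$selected, 1:10)
  expect_equal(bh_fdr(numeric(0))$q, numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("indicator tables format significant taxa in site-major order", {
  site <- rep(c("A", "B", "C", "D"), 6)
  horse <- rep(paste0("h", 1:6), each = 4)
  good <- ifelse(site == "A", 7, 0) + rep(0:5, each = 4) * (site == "A")
  set.seed(31)
  noise <- rpois(24, 5) + 1
  fam <- family_table(rbind(good = good, noise = noise), site, horse)
  fit <- indval(fam, n_perm = 999, seed = 3)
  tab <- indicator_table(fit)
  expect_equal(tab$taxon, "good")
  expect_equal(tab$IV, "1.0000")
  expect_match(tab$p_value, "^0\\.[0-9]{4}$")
  # with nothing significant the table is empty but keeps its columns
  famn <- family_table(matrix(noise, 1), site, horse, "noise")
  fitn <- indval(famn, n_perm = 99, seed = 2)
  tabn <- indicator_table(fitn)
  expect_equal(nrow(tabn), 0)
  expect_named(tabn, c("body_site", "taxon", "IV", "p_value", "q_value"))
})
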