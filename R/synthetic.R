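#' Describe a planted indicator taxon
#'
#' A planted indicator is a taxon whose site allocation is constructed so
#' that, in expectation, its exclusiveness equals `exclusiveness` and its
#' presence probability in each target site equals `faithfulness`.
#' Faithfulness is realised exactly: in every target site,
#' `round(faithfulness * n_horses)` horses carry the taxon (which horses is
#' randomized), so `faithfulness` must be a multiple of `1/n_horses`.
#'
#' @param taxon family name or index in the design.
#' @param sites character vector of target site names (or indices); must be
#'   a proper subset of the design's sites unless `exclusiveness = 1`.
#' @param exclusiveness target E* in (0, 1].
#' @param faithfulness target F* in (0, 1].
#' @param mean_abundance target mean relative abundance in target sites.
#' @return One-row data frame; rows can be `rbind`-ed into the
#'   `planted_indicators` argument of [synthetic_design()].
#' @export
planted_indicator <- function(taxon, sites, exclusiveness = 1,
                              faithfulness = 1, mean_abundance = 0.05) {
  data.frame(taxon = taxon, sites = paste(sites, collapse = ","),
             exclusiveness = exclusiveness, faithfulness = faithfulness,
             mean_abundance = mean_abundance, stringsAsFactors = FALSE)
}

#' Specify a synthetic blocked community study design
#'
#' Defines the generative model behind [generate_study()]: a blocked
#' (horse x body site) design in which each sample's composition is a
#' Dirichlet draw centred on the site's base composition perturbed by a
#' log-normal per-horse (block) random effect shared across that horse's
#' sites, and counts are multinomial at a log-normally drawn library size.
#' The shared block effect is what induces the within-horse correlation the
#' blocked permutation tests assume.
#'
#' @param n_horses number of blocks (default 6).
#' @param site_names body sites in proximal-to-distal order (default the
#'   four hindgut sites: cecum, ventral colon, dorsal colon, feces).
#' @param n_families number of taxa (default 87).
#' @param base_composition sites x families matrix of mean relative
#'   abundances, rows summing to 1. Default: one shared log-normal
#'   rank-abundance profile for all sites (a null design with no site
#'   effect).
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of the log-normal library sizes (defaults 90000 and 0.3).
#' @param horse_effect_sd SD of the per-horse log-scale random effect
#'   (default 0.5; 0 switches block effects off).
#' @param overdispersion total Dirichlet concentration (default 200;
#'   `Inf` gives plain multinomial sampling with no overdispersion).
#' @param planted_indicators `NULL` or a data frame of
#'   [planted_indicator()] rows.
#' @param family_names,lineages optional taxon names and GreenGenes-style
#'   lineage strings (one per family). The default auto-generated taxonomy
#'   mixes fully classified and order-/phylum-only lineages to exercise
#'   fallback labelling.
#' @param features_per_family integer (recycled): how many sequence
#'   features each family is split into in the emitted feature table.
#' @param seed integer seed; fully determines the generated study. Draws
#'   are taken from counter-based substreams per horse and per
#'   (horse, site) cell, so enlarging one part of the design does not
#'   reshuffle unrelated draws.
#' @return Object of class `synthetic_design`.
#' @seealso [generate_study()], [pelvic_flexure_preset()]
#' @export
synthetic_design <- function(n_horses = 6,
                             site_names = c("cecum", "ventral_colon",
                                            "dorsal_colon", "feces"),
                             n_families = 87,
                             base_composition = NULL,
                             library_size_mean = 90000,
                             library_size_cv = 0.3,
                             horse_effect_sd = 0.5,
                             overdispersion = 200,
                             planted_indicators = NULL,
                             family_names = NULL,
                             lineages = NULL,
                             features_per_family = 1,
                             seed = 1) {
  n_horses <- stop_scalar_count(n_horses, "n_horses")
  n_families <- stop_scalar_count(n_families, "n_families")
  ns <- length(site_names)
  if (ns < 2) stop("need at least 2 sites", call. = FALSE)
  if (anyDuplicated(site_names)) stop("duplicate site name", call. = FALSE)

  if (is.null(family_names))
    family_names <- sprintf("Family%03d", seq_len(n_families))
  if (length(family_names) != n_families || anyDuplicated(family_names))
    stop("family_names must be ", n_families, " unique names", call. = FALSE)
  if (is.null(lineages)) lineages <- default_lineages(family_names)
  if (length(lineages) != n_families)
    stop("need one lineage per family", call. = FALSE)

  if (is.null(base_composition)) {
    prof <- stats::qlnorm((n_families:1 - 0.5) / n_families, 0, 1.5)
    prof <- prof / sum(prof)
    base_composition <- matrix(prof, ns, n_families, byrow = TRUE)
  }
  base_composition <- as.matrix(base_composition)
  if (!all(dim(base_composition) == c(ns, n_families)))
    stop("base_composition must be n_sites x n_families", call. = FALSE)
  if (any(base_composition < 0))
    stop("negative base composition", call. = FALSE)
  rs <- rowSums(base_composition)
  if (any(abs(rs - 1) > 1e-6))
    stop("base composition rows must sum to 1", call. = FALSE)
  base_composition <- base_composition / rs
  dimnames(base_composition) <- list(site_names, family_names)

  planted <- validate_planted(planted_indicators, site_names, family_names,
                              n_horses)
  composition <- apply_planting(base_composition, planted)

  if (library_size_mean < 1 || library_size_cv < 0)
    stop("invalid library size parameters", call. = FALSE)
  if (horse_effect_sd < 0) stop("horse_effect_sd must be >= 0", call. = FALSE)
  if (!(is.infinite(overdispersion) || overdispersion > 0))
    stop("overdispersion must be positive or Inf", call. = FALSE)

  structure(list(
    n_horses = n_horses, site_names = site_names, n_families = n_families,
    family_names = family_names, lineages = lineages,
    base_composition = base_composition, composition = composition,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    horse_effect_sd = horse_effect_sd, overdispersion = overdispersion,
    planted_indicators = planted,
    features_per_family = rep_len(as.integer(features_per_family),
                                  n_families),
    seed = as.integer(seed)), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("synthetic_design: %d horses x %d sites, %d families, seed %d\n",
              x$n_horses, length(x$site_names), x$n_families, x$seed))
  if (nrow(x$planted_indicators))
    cat(sprintf("planted indicators: %s\n",
                paste(x$planted_indicators$taxon, collapse = ", ")))
  invisible(x)
}

validate_planted <- function(planted, site_names, family_names, n_horses) {
  empty <- data.frame(taxon = character(0), sites = character(0),
                      exclusiveness = numeric(0), faithfulness = numeric(0),
                      mean_abundance = numeric(0))
  if (is.null(planted) || !nrow(planted)) return(empty)
  planted <- as.data.frame(planted)
  planted$taxon <- ifelse(
    grepl("^[0-9]+$", as.character(planted$taxon)),
    family_names[as.integer(as.character(planted$taxon))],
    as.character(planted$taxon))
  if (!all(planted$taxon %in% family_names))
    stop("planted taxon not in family_names", call. = FALSE)
  if (anyDuplicated(planted$taxon))
    stop("a taxon may be planted only once", call. = FALSE)
  if (is.null(planted$mean_abundance)) planted$mean_abundance <- 0.05
  for (q in seq_len(nrow(planted))) {
    sites <- strsplit(planted$sites[q], "[,;]")[[1]]
    sites <- trimws(sites)
    if (!all(sites %in% site_names))
      stop("planted target site not in design", call. = FALSE)
    E <- planted$exclusiveness[q]; Fs <- planted$faithfulness[q]
    a <- planted$mean_abundance[q]
    if (!(E > 0 && E <= 1))
      stop("exclusiveness must lie in (0, 1]", call. = FALSE)
    if (a <= 0)
      stop("infeasible planting: exclusiveness > 0 requires a positive mean abundance in the target sites",
           call. = FALSE)
    if (!(Fs > 0 && Fs <= 1) ||
        abs(Fs * n_horses - round(Fs * n_horses)) > 1e-9)
      stop("faithfulness must be a multiple of 1/n_horses in (0, 1]",
           call. = FALSE)
    if (E < 1 && length(sites) >= length(site_names))
      stop("infeasible planting: exclusiveness < 1 needs at least one off-target site",
           call. = FALSE)
  }
  planted
}

# Bake planted site allocations into the composition matrix. Planted taxa
# get exact target means (a in target sites, a(1-E*)/(E* n_off) elsewhere);
# the remaining taxa are rescaled per site to absorb the rest, so rows
# still sum to 1 and the expected exclusiveness is exactly E*.
apply_planting <- function(base, planted) {
  comp <- base
  if (!nrow(planted)) return(comp)
  site_names <- rownames(base)
  p_idx <- match(planted$taxon, colnames(base))
  target <- matrix(0, nrow(base), length(p_idx))
  for (q in seq_along(p_idx)) {
    sites <- trimws(strsplit(planted$sites[q], "[,;]")[[1]])
    C <- match(sites, site_names)
    E <- planted$exclusiveness[q]
    a <- planted$mean_abundance[q]
    off <- setdiff(seq_len(nrow(base)), C)
    target[C, q] <- a
    if (length(off))
      target[off, q] <- a * (1 - E) / (E * length(off))
  }
  planted_total <- rowSums(target)
  if (any(planted_total >= 1))
    stop("planted abundances exceed the whole community in some site",
         call. = FALSE)
  other <- setdiff(seq_len(ncol(base)), p_idx)
  other_mass <- rowSums(base[, other, drop = FALSE])
  comp[, other] <- base[, other, drop = FALSE] *
    (1 - planted_total) / other_mass
  comp[, p_idx] <- target
  comp
}

# Auto-generated taxonomy: cycle five bacterial phyla; every 7th family is
# emitted order-only and every 11th phylum-only (with unique synthetic
# order/phylum names so collapsed labels stay distinct).
default_lineages <- function(family_names) {
  n <- length(family_names)
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Spirochaetes", "Verrucomicrobia")
  classes <- c("Bacteroidia", "Clostridia", "Gammaproteobacteria",
               "Spirochaetia", "Verrucomicrobiae")
  orders <- c("Bacteroidales", "Clostridiales", "Aeromonadales",
              "Spirochaetales", "Verrucomicrobiales")
  vapply(seq_len(n), function(r) {
    k <- (r - 1) %% 5 + 1
    if (r %% 11 == 0) {
      sprintf("k__Bacteria;p__SynPhy%03d", r)
    } else if (r %% 7 == 0) {
      sprintf("k__Bacteria;p__%s;c__%s;o__SynOrd%03d", phyla[k], classes[k], r)
    } else {
      sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s", phyla[k], classes[k],
              orders[k], family_names[r])
    }
  }, character(1))
}

# Collapsed label a family will receive at family rank, from its lineage.
lineage_family_label <- function(lineage, family_name) {
  parts <- parse_lineage(lineage)
  if (!is.na(parts[5])) return(parts[5])
  k <- which(!is.na(parts))
  if (!length(k)) return("Unassigned")
  k <- max(k)
  paste0(parts[k], " (", tax_prefixes[k], ")")
}

#' Generate a synthetic blocked community study
#'
#' Draws a full study from a [synthetic_design()]: for each (horse, site)
#' cell a composition is drawn from a Dirichlet centred on the site's base
#' composition perturbed by the horse's log-normal block effect, and counts
#' are drawn multinomially at a log-normal library size. Planted indicator
#' taxa are zeroed in the non-carrier horses of their target sites so that
#' faithfulness and exclusiveness match their targets in expectation. All
#' randomness flows from `design$seed` through per-horse and per-cell
#' substreams; a fixed seed gives byte-identical output.
#'
#' @param design a [synthetic_design()].
#' @return List with components `table` (a [feature_table()]), `taxonomy`,
#'   `metadata` (a [sample_metadata()]), `family_table` (the generator's
#'   own family-level bookkeeping as a [family_table()], labelled as
#'   [collapse_to_rank()] would label it) and `truth` (planted parameters,
#'   presence plan, per-family collapsed labels, family-assignment flags
#'   and the realised fraction of reads belonging to family-assigned
#'   features, horse effects, library sizes).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  ns <- length(d$site_names); nh <- d$n_horses; R <- d$n_families
  seed <- d$seed

  b <- matrix(0, nh, R)
  if (d$horse_effect_sd > 0) {
    for (j in seq_len(nh))
      b[j, ] <- with_seed(child_seed(seed, 100 + j),
                          stats::rnorm(R, 0, d$horse_effect_sd))
  }

  # presence plan for planted taxa: exactly round(F* nh) carrier horses per
  # target site
  present <- array(TRUE, c(ns, nh, R))
  planted <- d$planted_indicators
  for (q in seq_len(nrow(planted))) {
    r <- match(planted$taxon[q], d$family_names)
    sites <- trimws(strsplit(planted$sites[q], "[,;]")[[1]])
    k <- as.integer(round(planted$faithfulness[q] * nh))
    for (i in match(sites, d$site_names)) {
      carriers <- with_seed(child_seed(seed, 20000 + q * 64 + i),
                            sample.int(nh, k))
      present[i, setdiff(seq_len(nh), carriers), r] <- FALSE
    }
  }

  sdlog <- sqrt(log(1 + d$library_size_cv^2))
  meanlog <- log(d$library_size_mean) - sdlog^2 / 2

  fpf <- d$features_per_family
  n_feat <- sum(fpf)
  feat_family <- rep(seq_len(R), fpf)
  feature_ids <- unlist(lapply(seq_len(R), function(r) {
    if (fpf[r] == 1) sprintf("asv_%03d", r)
    else sprintf("asv_%03d.%d", r, seq_len(fpf[r]))
  }))

  n_samp <- ns * nh
  fam_counts <- matrix(0, R, n_samp)
  feat_counts <- matrix(0, n_feat, n_samp)
  sample_ids <- character(n_samp)
  site_vec <- integer(n_samp); horse_vec <- integer(n_samp)

  col <- 0
  for (j in seq_len(nh)) {
    for (i in seq_len(ns)) {
      col <- col + 1
      sample_ids[col] <- sprintf("horse%d_%s", j, d$site_names[i])
      site_vec[col] <- i; horse_vec[col] <- j
      cs <- child_seed(seed, 1000 + (j - 1) * ns + i)
      draws <- with_seed(cs, {
        N <- max(1, round(stats::rlnorm(1, meanlog, sdlog)))
        m <- d$composition[i, ] * exp(b[j, ])
        m[!present[i, j, ]] <- 0
        m <- m / sum(m)
        p <- if (is.finite(d$overdispersion)) {
          g <- stats::rgamma(R, shape = d$overdispersion * m)
          if (sum(g) == 0) m else g / sum(g)
        } else m
        cnt <- stats::rmultinom(1, N, p)[, 1]
        fc <- numeric(n_feat)
        pos <- 1
        for (r in seq_len(R)) {
          k <- fpf[r]
          if (k == 1) {
            fc[pos] <- cnt[r]
          } else if (cnt[r] > 0) {
            fc[pos:(pos + k - 1)] <-
              stats::rmultinom(1, cnt[r], rep(1 / k, k))[, 1]
          }
          pos <- pos + k
        }
        list(cnt = cnt, fc = fc)
      })
      fam_counts[, col] <- draws$cnt
      feat_counts[, col] <- draws$fc
    }
  }

  labels <- vapply(seq_len(R), function(r)
    lineage_family_label(d$lineages[r], d$family_names[r]), character(1))
  if (anyDuplicated(labels))
    stop("design lineages collapse two families to the same label: ",
         labels[duplicated(labels)][1], call. = FALSE)
  fam_assigned <- vapply(d$lineages, function(l) !is.na(parse_lineage(l)[5]),
                         logical(1), USE.NAMES = FALSE)

  md <- sample_metadata(sample_ids, paste0("horse", horse_vec),
                        d$site_names[site_vec], site_levels = d$site_names)
  tab <- feature_table(feat_counts, feature_ids, sample_ids)
  tax <- taxonomy(d$lineages[feat_family], feature_ids)
  ord <- order(labels)
  fam <- family_table(fam_counts[ord, , drop = FALSE],
                      md$body_site, md$horse_id, taxa = labels[ord])
  total <- sum(fam_counts)
  study <- list(table = tab, taxonomy = tax, metadata = md, family_table = fam,
       truth = list(design = d, planted = planted, presence_plan = present,
                    family_labels = labels, family_assigned = fam_assigned,
                    family_read_fraction =
                      sum(fam_counts[fam_assigned, ]) / total,
                    horse_effects = b,
                    library_sizes = stats::setNames(colSums(fam_counts),
                                                    sample_ids)))
  study
}

#' Write a generated study to disk in the package's TSV formats
#'
#' Emits the feature table, taxonomy and metadata in the formats the
#' corresponding readers consume, plus the planted-indicator truth record
#' (taxon, target sites, E*, F*, mean abundance) as `truth.tsv`.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(study$table, file.path(dir, "feature_table.tsv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(study$truth$planted, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
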