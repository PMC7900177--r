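#' Configuration for an end-to-end analysis run
#'
#' Collects every tunable of the pipeline into one serializable object. A
#' run is reproducible from the configuration, the inputs and the root seed
#' alone: every stage draws from a seed derived from `seed`, and each
#' output table carries the configuration hash and stage seeds in header
#' comments.
#'
#' @param feature_table,taxonomy,metadata input objects
#'   ([feature_table()], [taxonomy()], [sample_metadata()]) or paths to the
#'   corresponding TSVs. Alternatively supply `design`.
#' @param design a [synthetic_design()]; the study is then generated at run
#'   time instead of read from files.
#' @param depth rarefaction depth (default 59157).
#' @param rank collapse rank for the community table (default `"family"`).
#' @param seed root seed; all stage seeds derive from it.
#' @param shannon_base logarithm base for Shannon diversity (default 2).
#' @param permanova_scheme,permanova_n_perm overall PERMANOVA permutation
#'   scheme and count (defaults: `"free"`, 9999); pairwise site tests
#'   always use the exhaustive within-block scheme.
#' @param indicator_n_perm randomizations for the indicator analysis
#'   (default 9999).
#' @param fdr false discovery rate for indicator selection (default 0.05).
#' @param combinations site combinations for the combined-site indicator
#'   run; default: every contiguous (anatomically adjacent) run of 2 or 3
#'   sites.
#' @param top_n_families rows of the family relative-abundance table before
#'   the `Other` remainder (default 30).
#' @param out_dir `NULL` (no files) or a directory for the TSV outputs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(feature_table = NULL, taxonomy = NULL,
                       metadata = NULL, design = NULL, depth = 59157,
                       rank = "family", seed = 1, shannon_base = 2,
                       permanova_scheme = "free", permanova_n_perm = 9999,
                       indicator_n_perm = 9999, fdr = 0.05,
                       combinations = NULL, top_n_families = 30,
                       out_dir = NULL) {
  if (is.null(design) &&
      (is.null(feature_table) || is.null(taxonomy) || is.null(metadata)))
    stop("supply either a design or all of feature_table, taxonomy, metadata",
         call. = FALSE)
  structure(list(feature_table = feature_table, taxonomy = taxonomy,
                 metadata = metadata, design = design,
                 depth = stop_scalar_count(depth, "depth"),
                 rank = match.arg(rank, tax_ranks),
                 seed = as.integer(seed), shannon_base = shannon_base,
                 permanova_scheme = permanova_scheme,
                 permanova_n_perm = permanova_n_perm,
                 indicator_n_perm = indicator_n_perm, fdr = fdr,
                 combinations = combinations,
                 top_n_families = top_n_families, out_dir = out_dir),
            class = "run_config")
}

# All contiguous site index runs of the given lengths.
adjacent_site_combinations <- function(site_levels, sizes = c(2, 3)) {
  ns <- length(site_levels)
  out <- list()
  for (len in sizes) {
    if (len >= ns) next
    for (start in seq_len(ns - len + 1))
      out[[length(out) + 1]] <- seq(start, start + len - 1)
  }
  out
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  fnv1a(paste(utils::capture.output(utils::str(keep)), collapse = "\n"))
}

#' Run the full blocked community analysis pipeline
#'
#' Executes, in order: input loading (or synthetic generation), rarefaction
#' to even depth, per-sample Shannon diversity with pairwise Kruskal-Wallis
#' site tests, rank collapse, square-root transform, Bray-Curtis
#' dissimilarities, principal coordinates, overall PERMANOVA plus pairwise
#' exhaustive within-block PERMANOVA, dispersion testing, single-site and
#' combined-site indicator analyses with blocked randomization and BH
#' selection, and phylum/family relative-abundance summary tables. Any
#' stage failure aborts with the stage name. With `out_dir` set, every
#' result is written as a TSV whose header comments record the
#' configuration hash and stage seeds; two runs differing only in
#' `out_dir` produce content-identical files.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log messages.
#' @return Object of class `hindval_run` collecting every stage result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  logline <- function(stage, ...) {
    msg <- sprintf("stage=%s t=%.2fs %s", stage, proc.time()[3] - t0,
                   paste(..., collapse = " "))
    if (!quiet) message(msg)
    msg
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logs <- character(0)
  seed <- config$seed

  inputs <- run_stage("load", {
    if (!is.null(config$design)) {
      study <- generate_study(config$design)
      list(table = study$table, tax = study$taxonomy, md = study$metadata,
           truth = study$truth)
    } else {
      tab <- config$feature_table
      if (is.character(tab)) tab <- read_feature_table(tab)
      tax <- config$taxonomy
      if (is.character(tax)) tax <- read_taxonomy(tax)
      md <- config$metadata
      if (is.character(md)) md <- read_sample_metadata(md)
      list(table = tab, tax = tax, md = md, truth = NULL)
    }
  })
  logs <- c(logs, logline("load", sprintf("samples=%d features=%d",
                                          ncol(inputs$table$counts),
                                          nrow(inputs$table$counts))))

  pre_total <- sum(as.double(inputs$table$counts))
  rare_seed <- child_seed(seed, 1)
  rare <- run_stage("rarefy",
                    rarefy(inputs$table, config$depth, seed = rare_seed))
  if (ncol(rare$counts) == 0)
    stop("stage 'rarefy' failed: no sample reaches depth ", config$depth,
         call. = FALSE)
  retention <- retention_summary(pre_total, config$depth,
                                 ncol(rare$counts))
  logs <- c(logs, logline("rarefy",
                          sprintf("depth=%d retained=%d fraction=%.4f seed=%d",
                                  config$depth, ncol(rare$counts),
                                  retention$retained_fraction, rare_seed)))

  md <- inputs$md
  md_idx <- match(rare$sample_ids, md$sample_id)
  sites <- md$body_site[md_idx]
  horses <- md$horse_id[md_idx]

  alpha <- run_stage("alpha", {
    h <- shannon(rare, base = config$shannon_base)
    data.frame(sample_id = rare$sample_ids, horse_id = horses,
               body_site = sites, shannon = as.numeric(h))
  })
  alpha_pairwise <- run_stage("alpha",
                              pairwise_kruskal_wallis(alpha$shannon, sites))
  logs <- c(logs, logline("alpha",
                          sprintf("base=%g site_means=%s", config$shannon_base,
                                  paste(sprintf("%.2f",
                                                tapply(alpha$shannon, sites,
                                                       mean)),
                                        collapse = "/"))))

  fam <- run_stage("collapse",
                   collapse_to_rank(rare, inputs$tax, md, config$rank))
  class_rate <- run_stage("collapse",
                          classification_rate(rare, inputs$tax, config$rank))
  logs <- c(logs, logline("collapse",
                          sprintf("rank=%s taxa=%d classified=%.3f",
                                  config$rank, nrow(fam$abund), class_rate)))

  dm <- run_stage("beta", bray_curtis(sqrt_transform(fam)))
  ord <- run_stage("beta", pcoa(dm))
  logs <- c(logs, logline("beta", sprintf("pc1=%.3f pc2=%.3f",
                                          ord$proportion_explained[1],
                                          ord$proportion_explained[2])))

  perm_seed <- child_seed(seed, 2)
  overall <- run_stage("permanova",
    permanova(dm, sites, n_permutations = config$permanova_n_perm,
              scheme = config$permanova_scheme,
              blocks = if (config$permanova_scheme != "free") horses,
              seed = perm_seed))
  pairwise <- run_stage("permanova",
    pairwise_permanova(dm, sites, horses,
                       scheme = "exhaustive_within_block"))
  logs <- c(logs, logline("permanova",
                          sprintf("scheme=%s F=%.4f p=%g seed=%d",
                                  config$permanova_scheme, overall$pseudo_F,
                                  overall$p_value, perm_seed)))

  disp_seed <- child_seed(seed, 3)
  disp <- run_stage("permdisp", permdisp(dm, sites, seed = disp_seed))
  logs <- c(logs, logline("permdisp", sprintf("F=%.4f p=%g seed=%d",
                                              disp$F, disp$p_value,
                                              disp_seed)))

  iv_seed_1 <- child_seed(seed, 4)
  iv_single <- run_stage("indicator",
    indval(fam, n_perm = config$indicator_n_perm, seed = iv_seed_1,
           fdr = config$fdr))
  cmb <- config$combinations %||%
    adjacent_site_combinations(levels(fam$site))
  iv_seed_2 <- child_seed(seed, 5)
  iv_combined <- run_stage("indicator",
    indval(fam, combinations = cmb, n_perm = config$indicator_n_perm,
           seed = iv_seed_2, fdr = config$fdr))
  logs <- c(logs, logline("indicator",
                          sprintf("n_perm=%d fdr=%g significant=%d+%d seeds=%d,%d",
                                  config$indicator_n_perm, config$fdr,
                                  sum(iv_single$stats$significant),
                                  sum(iv_combined$stats$significant),
                                  iv_seed_1, iv_seed_2)))

  rel <- run_stage("report", {
    phylum <- relative_abundance_table(
      collapse_counts(rare, inputs$tax, "phylum"))
    fam_rel <- relative_abundance_table(fam$abund,
                                        top_n = config$top_n_families)
    list(phylum = phylum, family = fam_rel)
  })

  run <- structure(list(
    config = config, config_hash = config_hash(config),
    retention = retention, classification_rate = class_rate,
    alpha = alpha, alpha_pairwise = alpha_pairwise,
    family_table = fam, distance = dm, pcoa = ord,
    permanova_overall = overall, permanova_pairwise = pairwise,
    permdisp = disp, indval_single = iv_single,
    indval_combined = iv_combined,
    table_single = indicator_table(iv_single),
    table_combined = indicator_table(iv_combined),
    rel_phylum = rel$phylum, rel_family = rel$family,
    truth = inputs$truth, log = logs), class = "hindval_run")

  if (!is.null(config$out_dir))
    run_stage("report", write_run(run, config$out_dir))
  run
}

#' Per-sample relative abundances, optionally truncated to the top taxa
#'
#' Converts a taxa-by-samples abundance matrix to per-sample proportions.
#' With `top_n` set, only the `top_n` taxa with the highest mean relative
#' abundance are kept and the remainder is pooled into an `Other` row, so
#' every column still sums to 1.
#'
#' @param m taxa-by-samples numeric matrix (or [family_table()]).
#' @param top_n `NULL` for all taxa, or the number of rows to keep.
#' @return Matrix of proportions (taxa or `top_n + 1` rows, samples in
#'   columns).
#' @export
relative_abundance_table <- function(m, top_n = NULL) {
  if (inherits(m, "family_table")) m <- m$abund
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero-sum sample", call. = FALSE)
  rel <- sweep(m, 2, tot, "/")
  if (is.null(top_n) || nrow(rel) <= top_n) return(rel)
  keep <- order(rowMeans(rel), decreasing = TRUE)[seq_len(top_n)]
  top <- rel[keep, , drop = FALSE]
  rbind(top, Other = 1 - colSums(top))
}

#' @export
print.hindval_run <- function(x, ...) {
  cat("hindval pipeline run (config ", x$config_hash, ")\n", sep = "")
  cat(sprintf("retained %s sequences (%.2f%%) at depth %d\n",
              format(x$retention$retained_total),
              100 * x$retention$retained_fraction, x$config$depth))
  cat(sprintf("overall PERMANOVA: F = %.4f, p = %g (%s)\n",
              x$permanova_overall$pseudo_F, x$permanova_overall$p_value,
              x$permanova_overall$permutation_scheme))
  cat(sprintf("dispersion: F = %.4f, p = %g\n", x$permdisp$F,
              x$permdisp$p_value))
  cat(sprintf("indicator taxa: %d single-site, %d combined-site\n",
              nrow(x$table_single), nrow(x$table_combined)))
  invisible(x)
}

write_tsv_commented <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write every pipeline result as TSV under `dir`. Header comments carry the
# config hash and root seed but never the output path itself.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("config_hash: %s", run$config_hash),
           sprintf("seed: %d", run$config$seed))
  p <- function(f) file.path(dir, f)
  write_tsv_commented(
    data.frame(retained_total = run$retention$retained_total,
               retained_fraction = run$retention$retained_fraction,
               classification_rate = run$classification_rate),
    p("retention.tsv"), hdr)
  write_tsv_commented(run$alpha, p("alpha_diversity.tsv"), hdr)
  write_tsv_commented(run$alpha_pairwise, p("alpha_pairwise_kw.tsv"), hdr)
  write_family_table(run$family_table, p("family_table.tsv"))
  write_dist_matrix(run$distance, p("bray_curtis.tsv"))
  write_pcoa(run$pcoa, p("pcoa.tsv"))
  stats_rows <- rbind(
    data.frame(test = "permanova_overall",
               statistic = run$permanova_overall$pseudo_F,
               p = run$permanova_overall$p_value,
               scheme = run$permanova_overall$permutation_scheme,
               n_perm = run$permanova_overall$n_permutations),
    data.frame(test = paste0("permanova_", run$permanova_pairwise$group1,
                             "_vs_", run$permanova_pairwise$group2),
               statistic = run$permanova_pairwise$pseudo_F,
               p = run$permanova_pairwise$p,
               scheme = "exhaustive_within_block", n_perm = NA),
    data.frame(test = "permdisp", statistic = run$permdisp$F,
               p = run$permdisp$p_value, scheme = "free",
               n_perm = run$permdisp$n_permutations))
  write_tsv_commented(stats_rows, p("beta_tests.tsv"), hdr)
  write_tsv_commented(run$table_single, p("indicators_single.tsv"), hdr)
  write_tsv_commented(run$table_combined, p("indicators_combined.tsv"), hdr)
  write_tsv_commented(summary(run$indval_single), p("indval_single_full.tsv"),
                      hdr)
  write_tsv_commented(summary(run$indval_combined),
                      p("indval_combined_full.tsv"), hdr)
  write_tsv_commented(
    data.frame(taxon = rownames(run$rel_phylum), run$rel_phylum,
               check.names = FALSE),
    p("relative_abundance_phylum.tsv"), hdr)
  write_tsv_commented(
    data.frame(taxon = rownames(run$rel_family), run$rel_family,
               check.names = FALSE),
    p("relative_abundance_family.tsv"), hdr)
  writeLines(run$log, p("run_log.txt"))
  invisible(dir)
}
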