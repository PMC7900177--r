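# Rank collapse with unclassified-rank fallback labels.

# Label each feature at `rank`: its name there if assigned, otherwise the
# deepest assigned name suffixed with the parenthesized rank letter, e.g.
# "Synergistales (o)", "Spirochaetes (p)", "Anaerolineae (c)". Features with
# no assignment at all become "Unassigned". If a fallback label collides
# with a genuine name at the target rank it is suffixed with "*" until
# unique (never observed in real GreenGenes output, but guarded).
rank_labels <- function(tax, rank = "family") {
  rank <- match.arg(rank, tax_ranks)
  m <- unclass(tax)
  ri <- match(rank, tax_ranks)
  lab <- m[, ri]
  need_fallback <- is.na(lab)
  if (any(need_fallback)) {
    sub <- m[need_fallback, seq_len(ri), drop = FALSE]
    deep <- apply(sub, 1, function(r) {
      k <- which(!is.na(r))
      if (!length(k)) return("Unassigned")
      k <- max(k)
      paste0(r[k], " (", tax_prefixes[k], ")")
    })
    direct <- unique(lab[!need_fallback])
    clash <- deep %in% direct
    while (any(clash)) {
      deep[clash] <- paste0(deep[clash], "*")
      clash <- deep %in% direct
    }
    lab[need_fallback] <- deep
  }
  stats::setNames(lab, rownames(m))
}

# Collapsed abundance matrix (labels x samples) at a rank; counts are summed
# over features sharing a label. The taxon universe is the union over all
# samples; absences are 0.
collapse_counts <- function(x, tax, rank = "family") {
  stopifnot(inherits(x, "feature_table"), inherits(tax, "taxonomy"))
  missing_tax <- setdiff(x$feature_ids, rownames(unclass(tax)))
  if (length(missing_tax))
    stop("feature '", missing_tax[1], "' absent from taxonomy", call. = FALSE)
  lab <- rank_labels(tax, rank)[x$feature_ids]
  m <- rowsum(x$counts + 0, group = lab)  # + 0: accumulate in double
  m[order(rownames(m)), , drop = FALSE]
}

#' Collapse a feature table to an analysis rank over a blocked design
#'
#' Sums feature counts that share a taxonomic label at `rank`. Features
#' unassigned at that rank keep their deepest assigned name with a
#' parenthesized rank suffix -- `"Synergistales (o)"`, `"Spirochaetes (p)"`,
#' `"Anaerolineae (c)"` -- so that partially classified lineages remain
#' distinct, countable taxa rather than being discarded or pooled.
#'
#' @param x a [feature_table()].
#' @param tax a [taxonomy()] covering every feature in `x`.
#' @param metadata a [sample_metadata()] frame covering every sample in `x`.
#' @param rank target rank (default `"family"`).
#' @return A [family_table()] with taxa sorted alphabetically by label and
#'   the samples of `x` tagged by site and horse. Total counts are
#'   conserved: `sum(result$abund) == sum(x$counts)`.
#' @examples
#' ft <- feature_table(matrix(c(3, 4), 2, 1,
#'   dimnames = list(c("a", "b"), "h1_cecum")))
#' tx <- taxonomy(rep("k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae", 2),
#'                c("a", "b"))
#' md <- sample_metadata("h1_cecum", "h1", "cecum")
#' collapse_to_rank(ft, tx, md)$abund
#' @export
collapse_to_rank <- function(x, tax, metadata, rank = "family") {
  stopifnot(inherits(metadata, "sample_metadata"))
  idx <- match(x$sample_ids, metadata$sample_id)
  if (anyNA(idx))
    stop("sample '", x$sample_ids[which(is.na(idx))[1]],
         "' present in table but absent from metadata", call. = FALSE)
  m <- collapse_counts(x, tax, rank)
  family_table(m, metadata$body_site[idx], metadata$horse_id[idx])
}

#' Fraction of sequences classified at a rank
#'
#' Weighted by sequence counts, not by feature counts: a rare unassigned
#' feature barely moves the rate. Because assignment is prefix-closed, the
#' rate is monotonically non-increasing from kingdom to species.
#'
#' @inheritParams collapse_to_rank
#' @return A single number in \[0, 1\].
#' @export
classification_rate <- function(x, tax, rank = "family") {
  stopifnot(inherits(x, "feature_table"), inherits(tax, "taxonomy"))
  total <- sum(as.double(x$counts))
  if (nrow(x$counts) == 0 || ncol(x$counts) == 0 || total == 0)
    stop("empty feature table", call. = FALSE)
  missing_tax <- setdiff(x$feature_ids, rownames(unclass(tax)))
  if (length(missing_tax))
    stop("feature '", missing_tax[1], "' absent from taxonomy", call. = FALSE)
  ok <- assigned_at(tax, rank)[x$feature_ids]
  sum(as.double(x$counts[ok, , drop = FALSE])) / total
}
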