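#' Construct a rank-collapsed community table for a blocked design
#'
#' A `family_table` holds the y[i, j, r] abundances the indicator analysis
#' operates on: taxa (usually families) in rows, samples in columns, with
#' each sample tagged by its body site i and horse (block) j. Abundances are
#' numeric, not integer, so relative abundances can be analysed as well as
#' counts: faithfulness, exclusiveness and IndVal are invariant to a common
#' per-sample scale when sampling depths are even.
#'
#' @param abund non-negative numeric matrix, taxa in rows, samples in
#'   columns.
#' @param site,horse per-sample site and block labels (site level order is
#'   preserved and taken as the anatomical order).
#' @param taxa taxon labels; default rownames of `abund`.
#' @return An object of class `family_table`: list with elements `abund`,
#'   `site` (factor), `horse` (factor), `taxa`.
#' @seealso [collapse_to_rank()], [indval()], [family_array()]
#' @export
family_table <- function(abund, site, horse, taxa = rownames(abund)) {
  abund <- as.matrix(abund)
  if (!is.numeric(abund) || any(!is.finite(abund)) || any(abund < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(nrow(abund)))
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1], call. = FALSE)
  if (length(site) != ncol(abund) || length(horse) != ncol(abund))
    stop("site and horse must have one entry per sample", call. = FALSE)
  site <- if (is.factor(site)) droplevels(site)
          else factor(as.character(site), levels = unique(as.character(site)))
  horse <- factor(as.character(horse))
  key <- paste(horse, site, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicated (horse, site) pair: horse '%s', site '%s'",
                 horse[d], site[d]), call. = FALSE)
  }
  rownames(abund) <- taxa
  if (is.null(colnames(abund)))
    colnames(abund) <- paste(horse, site, sep = "_")
  structure(list(abund = abund, site = site, horse = horse, taxa = taxa),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("family_table: %d taxa x %d samples (%d sites x %d horses)\n",
              nrow(x$abund), ncol(x$abund), nlevels(x$site),
              nlevels(x$horse)))
  invisible(x)
}

# TRUE iff every (site, horse) combination is present exactly once.
is_complete_design <- function(x) {
  ncol(x$abund) == nlevels(x$site) * nlevels(x$horse)
}

#' Rearrange a family table as a (site, horse, taxon) array
#'
#' Requires a complete design (every site sampled in every horse).
#'
#' @param x a [family_table()].
#' @return Numeric array with dim (n_sites, n_horses, n_taxa) and dimnames.
#' @export
family_array <- function(x) {
  stopifnot(inherits(x, "family_table"))
  if (!is_complete_design(x))
    stop("incomplete design: every horse must have every site", call. = FALSE)
  ns <- nlevels(x$site); nh <- nlevels(x$horse); nt <- nrow(x$abund)
  a <- array(0, dim = c(ns, nh, nt),
             dimnames = list(levels(x$site), levels(x$horse), x$taxa))
  si <- as.integer(x$site); hi <- as.integer(x$horse)
  for (k in seq_len(ncol(x$abund))) a[si[k], hi[k], ] <- x$abund[, k]
  a
}

#' @export
as.matrix.family_table <- function(x, ...) t(x$abund)  # samples x taxa

#' Element-wise square-root transform of community abundances
#'
#' Applied before Bray-Curtis to damp the extreme dynamic range of
#' community count data. Not idempotent: applying it twice gives the fourth
#' root, not the square root.
#'
#' @param x a [family_table()], [feature_table()], matrix or numeric vector
#'   with non-negative entries.
#' @return Same shape and class as the input.
#' @export
sqrt_transform <- function(x) UseMethod("sqrt_transform")

#' @export
sqrt_transform.default <- function(x) {
  if (any(x < 0)) stop("negative entry in sqrt_transform input", call. = FALSE)
  sqrt(x)
}

#' @export
sqrt_transform.family_table <- function(x) {
  x$abund <- sqrt_transform.default(x$abund)
  x
}

#' @export
sqrt_transform.feature_table <- function(x) {
  m <- sqrt_transform.default(x$counts)
  storage.mode(m) <- "double"
  structure(list(counts = m, feature_ids = x$feature_ids,
                 sample_ids = x$sample_ids),
            class = "feature_table")
}

#' Read or write a family table abundance TSV
#'
#' The abundance matrix is written taxa-by-samples with a `taxon` id column;
#' the per-sample design (horse, site) lives in the companion metadata TSV
#' (see [read_sample_metadata()]).
#'
#' @param path file path.
#' @param metadata a [sample_metadata()] frame covering every sample column.
#' @return `read_family_table()` returns a [family_table()].
#' @export
read_family_table <- function(path, metadata) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  idx <- match(colnames(m), metadata$sample_id)
  if (anyNA(idx))
    stop("sample '", colnames(m)[which(is.na(idx))[1]],
         "' missing from metadata", call. = FALSE)
  family_table(m, metadata$body_site[idx], metadata$horse_id[idx])
}

#' @rdname read_family_table
#' @param x a [family_table()].
#' @export
write_family_table <- function(x, path) {
  stopifnot(inherits(x, "family_table"))
  out <- data.frame(taxon = x$taxa, x$abund, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
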