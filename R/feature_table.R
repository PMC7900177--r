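#' Construct a feature-by-sample count table
#'
#' A `feature_table` holds the post-denoising sequence variant counts: a
#' non-negative integer matrix with features (ASVs) in rows and samples in
#' columns, plus duplicate-free identifiers for both margins. Samples with a
#' library size of zero are rejected because no downstream quantity
#' (rarefaction depth, diversity, dissimilarity) is defined for them.
#'
#' @param counts non-negative integer matrix, features in rows.
#' @param feature_ids,sample_ids character identifiers; default to the
#'   dimnames of `counts`.
#' @return An object of class `feature_table` with elements `counts`
#'   (integer matrix carrying dimnames), `feature_ids` and `sample_ids`.
#' @examples
#' ft <- feature_table(matrix(c(5, 1, 0, 0, 2, 7), 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' library_sizes(ft)
#' @export
feature_table <- function(counts, feature_ids = rownames(counts),
                          sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("id lengths must match matrix dimensions", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1],
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1],
         call. = FALSE)
  bad <- which(!is_wholenumber(counts) | counts < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "invalid count %s at feature '%s', sample '%s' (must be a non-negative integer)",
      format(counts[bad[1]]), feature_ids[i[1]], sample_ids[i[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_ids, sample_ids)
  ls <- colSums(counts)
  if (ncol(counts) > 0 && any(ls == 0))
    stop("sample '", sample_ids[which(ls == 0)[1]],
         "' has a library size of 0", call. = FALSE)
  structure(list(counts = counts, feature_ids = feature_ids,
                 sample_ids = sample_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("total count %s; library sizes %s..%s\n",
              format(sum(as.double(x$counts))),
              format(min(library_sizes(x))), format(max(library_sizes(x)))))
  invisible(x)
}

#' Per-sample library sizes (column sums) of a feature table
#' @param x a [feature_table()].
#' @return Named integer vector of per-sample totals.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  colSums(x$counts)
}

normalize_dialect <- function(dialect) {
  dialect <- sub("^tsv_", "", dialect[1])
  match.arg(dialect, c("features_by_samples", "samples_by_features"))
}

#' Read or write a feature table as TSV
#'
#' The on-disk format is a plain BIOM-style TSV: a header row of ids and one
#' row per feature (dialect `"features_by_samples"`, first column the feature
#' id) or per sample (dialect `"samples_by_features"`). Orientation is an
#' explicit flag and never guessed: silently transposed community matrices
#' are a classic analysis bug, so both dialects return an identical,
#' features-in-rows `feature_table`. Writing mirrors reading bit-exactly.
#'
#' @param path file path.
#' @param dialect `"features_by_samples"` or `"samples_by_features"`
#'   (a `tsv_` prefix is accepted).
#' @return `read_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, dialect = "features_by_samples") {
  dialect <- normalize_dialect(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           comment.char = "#")
  if (ncol(raw) < 2) stop("malformed header in ", path,
                          ": need an id column plus at least one data column",
                          call. = FALSE)
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    i <- arrayInd(which(is.na(num))[1], dim(num))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 mat[i[1], i[2]], ids[i[1]], colnames(mat)[i[2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(mat))
  if (dialect == "samples_by_features") num <- t(num)
  feature_table(num)
}

#' @rdname read_feature_table
#' @param x a [feature_table()].
#' @export
write_feature_table <- function(x, path, dialect = "features_by_samples") {
  stopifnot(inherits(x, "feature_table"))
  dialect <- normalize_dialect(dialect)
  m <- x$counts
  if (dialect == "samples_by_features") {
    m <- t(m)
    id_col <- "sample_id"
  } else {
    id_col <- "feature_id"
  }
  out <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
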