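#' Construct a validated sample dissimilarity matrix
#'
#' @param values square numeric matrix, symmetric to within 1e-12, zero
#'   diagonal, non-negative.
#' @param sample_ids identifiers; default dimnames.
#' @return An object of class `dist_matrix` (a matrix with ids).
#' @export
dist_matrix <- function(values, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in distance matrix", call. = FALSE)
  if (any(values < 0)) stop("negative dissimilarity", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix not symmetric", call. = FALSE)
  if (any(diag(values) != 0))
    stop("distance matrix diagonal must be exactly 0", call. = FALSE)
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, range [%.4g, %.4g]\n", nrow(x),
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

#' Bray-Curtis dissimilarities among samples
#'
#' d(u, v) = sum |u - v| / sum (u + v), computed with [vegan::vegdist()].
#' Values lie in \[0, 1\]: 0 for identical profiles, 1 for disjoint
#' supports. Bray-Curtis is a semimetric -- the triangle inequality is not
#' guaranteed and is not asserted anywhere in this package.
#'
#' @param x a [family_table()], [feature_table()] or samples-by-taxa
#'   matrix with non-negative rows, each with a positive sum.
#' @return A [dist_matrix()].
#' @examples
#' bray_curtis(rbind(u = c(2, 0, 1), v = c(1, 1, 0)))  # 3/5
#' @export
bray_curtis <- function(x) {
  m <- community_matrix(x)
  if (any(m < 0)) stop("negative abundance", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("zero-sum sample: ", rownames(m)[zero][1] %||% which(zero)[1],
         call. = FALSE)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  dist_matrix(d, rownames(m) %||% paste0("S", seq_len(nrow(m))))
}

#' Read or write a distance matrix as square TSV with an id header
#' @param path file path.
#' @return `read_dist_matrix()` returns a [dist_matrix()].
#' @export
read_dist_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  dist_matrix(m)
}

#' @rdname read_dist_matrix
#' @param x a [dist_matrix()].
#' @export
write_dist_matrix <- function(x, path) {
  out <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: eigendecomposition of the Gower double-centered
#' -D^2/2 matrix (via [stats::cmdscale()]). All eigenvalues are reported,
#' negative ones included; coordinates are returned for positive axes only
#' and no additive correction is applied (recorded in `$correction`).
#' Proportions explained are taken against the sum of absolute eigenvalues,
#' so they sum to at most 1.
#'
#' @param dm a [dist_matrix()] (or square symmetric matrix / `dist`).
#' @return Object of class `pcoa`: `coordinates` (samples x axes, columns
#'   `PC1`, `PC2`, ...), `eigenvalues`, `proportion_explained`,
#'   `correction`.
#' @export
pcoa <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- dist_matrix(dm)  # validates symmetry etc.
  n <- nrow(dm)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(unclass(dm)), k = max(n - 1, 1),
                    eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(pos))
  rownames(coords) <- rownames(dm)
  denom <- sum(abs(eig))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = pmax(eig, 0) / denom,
                 correction = "none (negative eigenvalues reported, excluded from coordinates)"),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  k <- min(3, ncol(x$coordinates))
  cat(sprintf("pcoa: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("proportion explained:",
      paste(sprintf("%s %.1f%%", colnames(x$coordinates)[seq_len(k)],
                    100 * x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @param x a `pcoa` object.
#' @param axes which two axes to draw.
#' @param groups optional per-sample grouping used for plot colours.
#' @param ... passed to [graphics::plot()].
#' @rdname pcoa
#' @export
plot.pcoa <- function(x, axes = c(1, 2), groups = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < max(axes)) stop("not enough positive axes", call. = FALSE)
  col <- 1
  if (!is.null(groups)) col <- as.integer(factor(groups)) + 1L
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * x$proportion_explained[axes])
  graphics::plot(co[, axes[1]], co[, axes[2]], col = col, pch = 19,
                 xlab = lab[1], ylab = lab[2], ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1L, pch = 19,
                     bty = "n")
  invisible(x)
}

#' Write ordination coordinates plus an eigenvalue sidecar
#' @param x a `pcoa` object.
#' @param path coordinates TSV path; the sidecar gets `paste0(path, ".meta")`.
#' @export
write_pcoa <- function(x, path) {
  out <- data.frame(sample_id = rownames(x$coordinates), x$coordinates,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(axis = seq_along(x$eigenvalues),
                     eigenvalue = x$eigenvalues,
                     proportion_explained = x$proportion_explained)
  utils::write.table(meta, paste0(path, ".meta"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
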