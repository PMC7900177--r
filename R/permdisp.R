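#' Test of multivariate homogeneity of group dispersions (PERMDISP)
#'
#' The standard assumption check for PERMANOVA: samples are embedded by
#' principal coordinates, each sample's distance to its group centroid (or
#' spatial median) is computed, and a one-way ANOVA F on those distances is
#' tested by permuting the distances across samples. Negative PCoA
#' eigenvalues are handled the usual way: squared distances are the
#' positive-axis contribution minus the magnitude of the negative-axis
#' ("imaginary") contribution, clamped at zero.
#'
#' @param dm a [dist_matrix()] (or square symmetric matrix / `dist`).
#' @param groups group labels; at least two groups with >= 2 members each.
#' @param n_permutations number of permutations (add-one p-value).
#' @param seed integer seed.
#' @param type `"centroid"` (default) or `"median"` (spatial median on the
#'   positive axes, Weiszfeld iteration).
#' @return Object of class `permdisp`: `F`, `p_value`, `distances`
#'   (per-sample distance to its group centre), `group_means`, `type`,
#'   `n_permutations`, `seed`.
#' @export
permdisp <- function(dm, groups, n_permutations = 999, seed = NULL,
                     type = c("centroid", "median")) {
  type <- match.arg(type)
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- dist_matrix(dm)
  n <- nrow(dm)
  groups <- factor(groups)
  if (length(groups) != n)
    stop("groups must have one label per sample", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group '", names(sizes)[sizes < 2][1], "' has fewer than 2 members",
         call. = FALSE)

  # Gower-centred embedding retaining real and imaginary parts
  D2 <- unclass(dm)^2
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% D2 %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  Xp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  Xn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))

  dist_to_centre <- function(Xp, Xn, idx, type) {
    if (type == "centroid") {
      cp <- colMeans(Xp[idx, , drop = FALSE])
      cn <- if (ncol(Xn)) colMeans(Xn[idx, , drop = FALSE]) else numeric(0)
    } else {
      cp <- spatial_median(Xp[idx, , drop = FALSE])
      cn <- if (ncol(Xn)) colMeans(Xn[idx, , drop = FALSE]) else numeric(0)
    }
    d2 <- rowSums(sweep(Xp[idx, , drop = FALSE], 2, cp)^2)
    if (ncol(Xn))
      d2 <- d2 - rowSums(sweep(Xn[idx, , drop = FALSE], 2, cn)^2)
    sqrt(pmax(d2, 0))
  }

  z <- numeric(n)
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    z[idx] <- dist_to_centre(Xp, Xn, idx, type)
  }

  anova_f <- function(z, groups) {
    gm <- tapply(z, groups, mean)
    ng <- tabulate(groups)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(groups)])^2)
    a <- nlevels(groups)
    (ssb / (a - 1)) / (ssw / (length(z) - a))
  }

  f_obs <- anova_f(z, groups)
  n_permutations <- stop_scalar_count(n_permutations, "n_permutations")
  count <- with_seed(seed, {
    cnt <- 0L
    for (k in seq_len(n_permutations)) {
      if (anova_f(z[sample.int(n)], groups) >= f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(F = f_obs, p_value = (1 + count) / (1 + n_permutations),
                 distances = stats::setNames(z, rownames(dm)),
                 group_means = tapply(z, groups, mean), type = type,
                 n_permutations = n_permutations, seed = seed),
            class = "permdisp")
}

# Weiszfeld iteration for the geometric median of rows of X.
spatial_median <- function(X, tol = 1e-10, max_iter = 200) {
  m <- colMeans(X)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    if (any(d < tol)) return(m)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' @export
print.permdisp <- function(x, ...) {
  cat("PERMDISP (", x$type, ")\n", sep = "")
  cat(sprintf("F = %.4f;  p = %s  (%d permutations)\n", x$F,
              format(x$p_value), x$n_permutations))
  invisible(x)
}
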