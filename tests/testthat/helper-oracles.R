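# Independent brute-force oracles used across the suite. These deliberately
# use naive loops and first-principles formulas, never the package's own
# vectorized code paths.

# Naive triple-loop IndVal on a (site, horse, taxon) array; `cmb` NULL for
# single sites or a list of site-index vectors.
oracle_indval <- function(arr, cmb = NULL) {
  ns <- dim(arr)[1]; nh <- dim(arr)[2]; nt <- dim(arr)[3]
  groups <- if (is.null(cmb)) as.list(seq_len(ns)) else cmb
  E <- Fm <- IV <- matrix(0, length(groups), nt)
  for (r in seq_len(nt)) {
    ybar <- numeric(ns)
    for (i in seq_len(ns)) {
      s <- 0
      for (j in seq_len(nh)) s <- s + arr[i, j, r]
      ybar[i] <- s / nh
    }
    for (g in seq_along(groups)) {
      C <- groups[[g]]
      pres <- 0
      for (i in C) for (j in seq_len(nh)) pres <- pres + (arr[i, j, r] > 0)
      f <- pres / (nh * length(C))
      yC <- mean(ybar[C])
      denom <- yC + sum(ybar[setdiff(seq_len(ns), C)])
      e <- if (denom == 0) 0 else yC / denom
      E[g, r] <- e; Fm[g, r] <- f; IV[g, r] <- sqrt(e * f)
    }
  }
  list(E = E, F = Fm, IV = IV)
}

# PERMANOVA pseudo-F recomputed from group centroids in coordinate space
# (valid for Euclidean-embeddable dissimilarities).
oracle_f_from_coords <- function(X, groups) {
  groups <- factor(groups)
  ss_t <- sum(sweep(X, 2, colMeans(X))^2)
  ss_w <- 0
  for (lev in levels(groups)) {
    idx <- groups == lev
    Xi <- X[idx, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  a <- nlevels(groups); n <- nrow(X)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Mean silhouette width of a 2-cluster split given a distance matrix.
mean_silhouette <- function(dm, labels) {
  dm <- unclass(dm)
  labels <- as.integer(factor(labels))
  s <- numeric(length(labels))
  for (u in seq_along(labels)) {
    own <- labels == labels[u]; own[u] <- FALSE
    a <- mean(dm[u, own])
    b <- mean(dm[u, labels != labels[u]])
    s[u] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small random complete blocked count table with some structural zeros.
random_family_table <- function(ns = 3, nh = 4, nt = 10, seed = 1,
                                zero_prob = 0.3, lambda = 20) {
  set.seed(seed)
  n <- ns * nh
  m <- matrix(rpois(nt * n, lambda) *
                (runif(nt * n) > zero_prob), nt, n)
  m[, colSums(m) == 0] <- 1  # keep every sample non-empty
  family_table(m, site = rep(paste0("site", seq_len(ns)), nh),
               horse = rep(paste0("h", seq_len(nh)), each = ns))
}

# Write a small TSV fixture and return its path.
write_fixture <- function(lines, name) {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}
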