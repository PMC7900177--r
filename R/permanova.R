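#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squared dissimilarities among groups and tests the
#' pseudo-F statistic by permutation. The sums of squares are computed
#' directly from squared pairwise dissimilarities: the total is
#' `sum_{u<v} d²(u,v) / N` and the within-group term is the analogous sum
#' within each group divided by its size, so no embedding is needed and any
#' (semi)metric -- Bray-Curtis included -- is acceptable.
#'
#' Three permutation schemes are offered:
#' \describe{
#'   \item{`free`}{group labels permuted freely across all samples;
#'     `p = (1 + #\{F* >= F_obs\}) / (1 + n_permutations)`.}
#'   \item{`within_block`}{labels shuffled independently within each block
#'     (e.g. within each horse), preserving between-block structure; sampled,
#'     add-one p as above.}
#'   \item{`exhaustive_within_block`}{for exactly two groups with one sample
#'     per group in each of b blocks, all `2^b` within-block label swaps are
#'     enumerated and `p = #\{F* >= F_obs\} / 2^b`, counting the identity.
#'     Because swapping every block relabels but does not repartition the
#'     samples, statistics come in mirror pairs and achievable p-values are
#'     the even multiples of `1/2^b`; the smallest is `2/2^b` (0.03125 for
#'     six blocks).}
#' }
#'
#' @param dm a [dist_matrix()] (or square symmetric matrix / `dist`).
#' @param groups group labels, one per sample; at least two groups.
#' @param n_permutations number of sampled permutations (ignored for the
#'   exhaustive scheme).
#' @param scheme permutation scheme, see Details.
#' @param blocks block labels (required for the blocked schemes); every
#'   block must span more than one group.
#' @param seed integer seed for the sampled schemes.
#' @return Object of class `permanova`: `pseudo_F`, `p_value`, `df`,
#'   `ss` (between/within/total), `n_permutations`, `permutation_scheme`,
#'   `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 9999,
                      scheme = c("free", "within_block",
                                 "exhaustive_within_block"),
                      blocks = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- dist_matrix(dm)
  n <- nrow(dm)
  groups <- factor(groups)
  if (length(groups) != n)
    stop("groups must have one label per sample", call. = FALSE)
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  D2 <- unclass(dm)^2
  g_int <- as.integer(groups)

  if (scheme != "free") {
    if (is.null(blocks))
      stop("blocks are required for scheme '", scheme, "'", call. = FALSE)
    blocks <- factor(blocks)
    if (length(blocks) != n)
      stop("blocks must have one label per sample", call. = FALSE)
    span <- tapply(g_int, blocks, function(g) length(unique(g)))
    if (any(span < 2))
      stop("block '", names(span)[span < 2][1],
           "' spans only one group", call. = FALSE)
  }

  f_obs <- permanova_f(D2, g_int, a)

  if (scheme == "exhaustive_within_block") {
    if (a != 2)
      stop("exhaustive_within_block requires exactly 2 groups", call. = FALSE)
    per_block <- table(blocks, groups)
    if (any(per_block != 1))
      stop("exhaustive_within_block requires one sample per group in every block",
           call. = FALSE)
    b <- nlevels(blocks)
    if (b > 20) stop("too many blocks to enumerate (", b, ")", call. = FALSE)
    block_members <- split(seq_len(n), blocks)
    n_tot <- 2^b
    fs <- numeric(n_tot)
    for (code in 0:(n_tot - 1)) {
      g_perm <- g_int
      for (j in seq_len(b)) {
        if (bitwAnd(bitwShiftR(code, j - 1L), 1L) == 1L) {
          idx <- block_members[[j]]
          g_perm[idx] <- 3L - g_perm[idx]  # swap the two labels
        }
      }
      fs[code + 1] <- permanova_f(D2, g_perm, a)
    }
    # 1e-12 margin so exact ties survive floating-point noise
    p <- sum(fs >= fs[1] - 1e-12) / n_tot  # code 0 is the identity
    n_perm_out <- n_tot
  } else {
    n_permutations <- stop_scalar_count(n_permutations, "n_permutations")
    count <- with_seed(seed, {
      cnt <- 0L
      if (scheme == "free") {
        for (k in seq_len(n_permutations)) {
          if (permanova_f(D2, g_int[sample.int(n)], a) >= f_obs - 1e-12)
            cnt <- cnt + 1L
        }
      } else {
        block_members <- split(seq_len(n), blocks)
        for (k in seq_len(n_permutations)) {
          g_perm <- g_int
          for (idx in block_members)
            g_perm[idx] <- g_perm[idx][sample.int(length(idx))]
          if (permanova_f(D2, g_perm, a) >= f_obs - 1e-12) cnt <- cnt + 1L
        }
      }
      cnt
    })
    p <- (1 + count) / (1 + n_permutations)
    n_perm_out <- n_permutations
  }

  ss_t <- sum(D2) / (2 * n)
  ss_w <- permanova_ssw(D2, g_int)
  structure(list(pseudo_F = f_obs, p_value = p,
                 df = c(between = a - 1L, within = n - a),
                 ss = c(between = ss_t - ss_w, within = ss_w, total = ss_t),
                 n_permutations = n_perm_out,
                 permutation_scheme = scheme, seed = seed),
            class = "permanova")
}

permanova_ssw <- function(D2, g_int) {
  ss_w <- 0
  for (lev in unique(g_int)) {
    idx <- which(g_int == lev)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_w
}

permanova_f <- function(D2, g_int, a) {
  n <- nrow(D2)
  ss_t <- sum(D2) / (2 * n)
  ss_w <- permanova_ssw(D2, g_int)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$permutation_scheme, " permutations)\n", sep = "")
  cat(sprintf("pseudo-F = %.4f on df %d, %d;  p = %s  (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], format(x$p_value),
              x$n_permutations))
  invisible(x)
}

#' Pairwise blocked PERMANOVA between all group pairs
#'
#' Runs [permanova()] with the `exhaustive_within_block` scheme (by default)
#' on every unordered pair of groups, the design used for pairwise body-site
#' comparisons in a complete blocked survey. P-values are reported raw, with
#' no multiplicity correction.
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `p`.
#' @export
pairwise_permanova <- function(dm, groups, blocks,
                               scheme = "exhaustive_within_block",
                               n_permutations = 9999, seed = NULL) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- dist_matrix(dm)
  groups <- factor(groups)
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    sel <- which(groups %in% pr)
    fit <- permanova(unclass(dm)[sel, sel], droplevels(groups[sel]),
                     n_permutations = n_permutations, scheme = scheme,
                     blocks = factor(blocks[sel]), seed = seed)
    c(fit$pseudo_F, fit$p_value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             pseudo_F = res[1, ], p = res[2, ], row.names = NULL)
}
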