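#' Shannon diversity index per sample
#'
#' H = -sum p log(p) over the nonzero proportions of each sample, in the
#' chosen logarithm base. Base 2 is the default (the convention of common
#' upstream 16S platforms); natural log is available via `base = exp(1)`.
#' Computed with [vegan::diversity()].
#'
#' @param x a [feature_table()], [family_table()], samples-by-taxa matrix,
#'   or a single count vector.
#' @param base logarithm base (default 2).
#' @return Named numeric vector of per-sample H values, with the base
#'   recorded in attribute `"base"`.
#' @examples
#' shannon(c(1, 1, 1, 1)) # log2(4) = 2
#' @export
shannon <- function(x, base = 2) {
  m <- community_matrix(x)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero sample: ", rownames(m)[zero][1] %||% which(zero)[1],
         call. = FALSE)
  h <- vegan::diversity(m, index = "shannon", base = base)
  attr(h, "base") <- base
  h
}

# Coerce supported inputs to a samples-by-taxa numeric matrix.
community_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(t(x$counts + 0))
  if (inherits(x, "family_table")) return(t(x$abund))
  if (is.matrix(x)) return(x + 0)
  if (is.numeric(x)) return(matrix(x, nrow = 1))
  stop("unsupported community input of class ", class(x)[1], call. = FALSE)
}

#' Pairwise Kruskal-Wallis tests between groups
#'
#' One rank-based Kruskal-Wallis test (tie-corrected H, chi-square reference
#' with 1 df) per unordered pair of groups, via [stats::kruskal.test()].
#' No multiplicity correction is applied; each pair is reported raw.
#'
#' @param values numeric observations (e.g. per-sample Shannon values).
#' @param groups group labels, one per observation; every group needs at
#'   least two observations.
#' @return Data frame with columns `group1`, `group2`, `H`, `p`.
#' @export
pairwise_kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  n <- table(groups)
  if (any(n < 2))
    stop("group '", names(n)[n < 2][1], "' has fewer than 2 observations",
         call. = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    sel <- groups %in% pr
    kt <- stats::kruskal.test(values[sel], droplevels(groups[sel]))
    # a fully tied pair (all observations equal) carries no evidence
    if (!is.finite(kt$statistic)) return(c(H = 0, p = 1))
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             H = out["H", ], p = out["p", ], row.names = NULL)
}
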