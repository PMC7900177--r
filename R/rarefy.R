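#' Rarefy a feature table to an even sampling depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' sequences (via [vegan::rrarefy()]), equalizing sequencing effort before
#' diversity comparisons. Samples whose library size falls below `depth`
#' are dropped with a warning naming them; samples exactly at `depth` pass
#' through unchanged. Deterministic given `seed`.
#'
#' @param x a [feature_table()].
#' @param depth target depth (positive integer).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return A [feature_table()] whose library sizes all equal `depth`
#'   (possibly with zero samples if none is deep enough).
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  depth <- stop_scalar_count(depth, "depth")
  ls <- library_sizes(x)
  drop <- ls < depth
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(x$sample_ids[drop], collapse = ", "), call. = FALSE)
  keep <- x$counts[, !drop, drop = FALSE]
  if (ncol(keep) == 0) {
    return(structure(list(counts = keep[, 0, drop = FALSE],
                          feature_ids = x$feature_ids,
                          sample_ids = character(0)),
                     class = "feature_table"))
  }
  # counts are validated integer already; muffle vegan's "observed counts"
  # heuristic warning for tables whose smallest count exceeds 1
  sub <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(keep), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  feature_table(t(sub))
}

#' Sequence retention after rarefaction
#'
#' Desk arithmetic for reporting: rarefying `n_retained` samples at `depth`
#' keeps exactly `depth * n_retained` sequences; the fraction is taken
#' against the pre-rarefaction total.
#'
#' @param pre_total total sequences before rarefaction.
#' @param depth rarefaction depth.
#' @param n_retained number of samples at or above `depth`.
#' @return List with `retained_total` and `retained_fraction`.
#' @examples
#' retention_summary(2163951, 59157, 24) # 1419768 sequences, 65.61%
#' @export
retention_summary <- function(pre_total, depth, n_retained) {
  pre_total <- stop_scalar_count(pre_total, "pre_total")
  depth <- stop_scalar_count(depth, "depth")
  n_retained <- stop_scalar_count(n_retained, "n_retained")
  retained <- as.double(depth) * n_retained
  if (retained > pre_total)
    stop("inconsistent inputs: retained total ", format(retained),
         " exceeds pre-rarefaction total ", format(pre_total), call. = FALSE)
  list(retained_total = retained, retained_fraction = retained / pre_total)
}
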