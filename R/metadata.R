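#' Construct sample metadata for a blocked animal-by-site design
#'
#' Each sample is one (horse, body site) combination; horses are the blocks
#' of the design. Any number of blocks and sites is allowed (the motivating
#' study used 6 horses and 4 sites: cecum, ventral colon, dorsal colon,
#' feces), but a given (horse, site) pair may occur at most once.
#'
#' @param sample_id,horse_id,body_site parallel vectors, one entry per
#'   sample. `body_site` may be a factor whose level order fixes the
#'   anatomical (proximal-to-distal) site order; for character input the
#'   order of first appearance is used unless `site_levels` is given.
#' @param site_levels optional explicit site level order.
#' @return A `sample_metadata` data frame with columns `sample_id`,
#'   `horse_id` (factor) and `body_site` (factor).
#' @export
sample_metadata <- function(sample_id, horse_id, body_site,
                            site_levels = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1],
         call. = FALSE)
  if (is.null(site_levels)) {
    site_levels <- if (is.factor(body_site)) levels(body_site)
                   else unique(as.character(body_site))
  }
  body_site <- factor(as.character(body_site), levels = site_levels)
  if (anyNA(body_site)) stop("body_site outside site_levels", call. = FALSE)
  horse_id <- factor(as.character(horse_id))
  key <- paste(horse_id, body_site, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicated (horse, site) pair: horse '%s', site '%s'",
                 horse_id[d], body_site[d]), call. = FALSE)
  }
  structure(
    data.frame(sample_id = sample_id, horse_id = horse_id,
               body_site = body_site, stringsAsFactors = FALSE),
    class = c("sample_metadata", "data.frame"))
}

#' Read or write sample metadata TSV
#'
#' Three tab-separated columns: `sample_id`, `horse_id`, `body_site`.
#'
#' @param path file path.
#' @param site_levels optional explicit site level order (default: order of
#'   first appearance in the file).
#' @return `read_sample_metadata()` returns a [sample_metadata()] frame.
#' @export
read_sample_metadata <- function(path, site_levels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "horse_id", "body_site")
  if (!all(need %in% colnames(raw)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sample_metadata(raw$sample_id, raw$horse_id, raw$body_site, site_levels)
}

#' @rdname read_sample_metadata
#' @param x a [sample_metadata()] frame.
#' @export
write_sample_metadata <- function(x, path) {
  stopifnot(inherits(x, "sample_metadata"))
  out <- data.frame(sample_id = x$sample_id,
                    horse_id = as.character(x$horse_id),
                    body_site = as.character(x$body_site))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
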