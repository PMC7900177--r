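#' @keywords internal
tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
tax_prefixes <- c("k", "p", "c", "o", "f", "g", "s")

#' Parse GreenGenes-style lineage strings into a taxonomy table
#'
#' Lineages are semicolon-delimited rank fields with `k__`/`p__`/`c__`/`o__`/
#' `f__`/`g__`/`s__` prefixes, kingdom through species. An empty field (e.g.
#' `"f__"`) or a short lineage marks the rank unassigned; assignment is
#' prefix-closed, so everything deeper than the first unassigned rank is
#' truncated to unassigned as well. Unknown rank prefixes are an error.
#'
#' @param lineages character vector of lineage strings.
#' @param feature_ids identifiers, one per lineage.
#' @return A `taxonomy` object: a character matrix with one row per feature
#'   and columns kingdom..species, `NA` marking unassigned ranks.
#' @examples
#' taxonomy("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__;g__;s__",
#'          "asv1")
#' @export
taxonomy <- function(lineages, feature_ids = names(lineages)) {
  force(feature_ids)
  lineages <- as.character(lineages)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_along(lineages))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id in taxonomy: ",
         feature_ids[duplicated(feature_ids)][1], call. = FALSE)
  m <- t(vapply(lineages, parse_lineage, character(7), USE.NAMES = FALSE))
  dimnames(m) <- list(feature_ids, tax_ranks)
  structure(m, class = "taxonomy")
}

parse_lineage <- function(s) {
  out <- rep(NA_character_, 7)
  if (is.na(s) || !nzchar(trimws(s))) return(out)
  tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (length(tokens) > 7)
    stop("lineage has more than 7 rank fields: '", s, "'", call. = FALSE)
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok)) next
    if (!grepl("^[a-z]__", tok))
      stop("malformed rank field '", tok, "' in lineage '", s, "'",
           call. = FALSE)
    pre <- substr(tok, 1, 1)
    if (pre != tax_prefixes[i])
      stop("unknown or out-of-order rank prefix '", pre, "__' at position ",
           i, " in lineage '", s, "' (expected '", tax_prefixes[i], "__')",
           call. = FALSE)
    name <- substr(tok, 4, nchar(tok))
    out[i] <- if (nzchar(name)) name else NA_character_
  }
  # prefix closure: truncate at the first unassigned rank
  first_na <- which(is.na(out))
  if (length(first_na)) out[first_na[1]:7] <- NA_character_
  out
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("taxonomy: %d features\n", nrow(x)))
  depth <- rowSums(!is.na(unclass(x)))
  tab <- table(factor(tax_ranks[pmax(depth, 1)], levels = tax_ranks))
  cat("deepest assigned rank:\n")
  print(tab)
  invisible(x)
}

#' Is each feature assigned at a given rank?
#' @param x a [taxonomy()] object.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return Named logical vector over features.
#' @export
assigned_at <- function(x, rank = "family") {
  stopifnot(inherits(x, "taxonomy"))
  rank <- match.arg(rank, tax_ranks)
  !is.na(unclass(x)[, rank])
}

#' Read or write a feature-id to lineage TSV
#'
#' Two tab-separated columns, `feature_id` and the GreenGenes-style lineage;
#' writing emits the full seven-field form (`k__X;p__Y;...;f__;g__;s__`) so
#' that a canonical file round-trips bit-exactly.
#'
#' @param path file path.
#' @return `read_taxonomy()` returns a [taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2)
    stop("taxonomy file must have feature_id and lineage columns",
         call. = FALSE)
  taxonomy(raw[[2]], raw[[1]])
}

#' @rdname read_taxonomy
#' @param x a [taxonomy()] object.
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "taxonomy"))
  m <- unclass(x)
  lineage <- apply(m, 1, function(r) {
    paste0(tax_prefixes, "__", ifelse(is.na(r), "", r), collapse = ";")
  })
  utils::write.table(
    data.frame(feature_id = rownames(m), lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
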