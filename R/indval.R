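#' Faithfulness of a taxon to a body site
#'
#' The constancy of presence of taxon `r` at site `i` across the blocks:
#' `F = (1/n_horses) * sum_j 1[y(i, j, r) > 0]`.
#'
#' @param x a [family_table()] with a complete (site x horse) design.
#' @param site site name or index.
#' @param taxon taxon label or index.
#' @return A fraction in \[0, 1\].
#' @export
faithfulness <- function(x, site, taxon) {
  stopifnot(inherits(x, "family_table"))
  s <- resolve_level(site, levels(x$site), "site")
  r <- resolve_level(taxon, x$taxa, "taxon")
  sel <- as.integer(x$site) == s
  mean(x$abund[r, sel] > 0)
}

#' Exclusiveness of a taxon to a body site
#'
#' The site's share of the taxon's across-site mean abundance:
#' `E = ybar(i, r) / sum_i ybar(i, r)`, where `ybar(i, r)` is the mean over
#' horses at site `i`. A taxon absent everywhere gets `E = 0` by convention.
#'
#' @inheritParams faithfulness
#' @return A fraction in \[0, 1\]; for any taxon the values sum to 1 over
#'   sites (or are all 0).
#' @export
exclusiveness <- function(x, site, taxon) {
  stopifnot(inherits(x, "family_table"))
  s <- resolve_level(site, levels(x$site), "site")
  r <- resolve_level(taxon, x$taxa, "taxon")
  ybar <- tapply(x$abund[r, ], x$site, mean)
  tot <- sum(ybar)
  if (tot == 0) return(0)
  unname(ybar[s] / tot)
}

resolve_level <- function(key, values, what) {
  if (is.character(key)) {
    i <- match(key, values)
    if (is.na(i)) stop("unknown ", what, ": '", key, "'", call. = FALSE)
    return(i)
  }
  key <- as.integer(key)
  if (key < 1 || key > length(values))
    stop(what, " index out of bounds", call. = FALSE)
  key
}

# --- vectorized engine -------------------------------------------------------

# E, F and IV for every (group, taxon) pair given an integer site vector.
# `TA`/`TP`: samples x taxa abundance and presence (0/1) matrices.
# `cmb`: NULL for single sites, or a list of integer site-index vectors.
# Site means use the per-site horse count `n_h`; the denominator of E is a
# sum of per-site means, which is invariant under within-block relabelling.
iv_engine <- function(TA, TP, site_int, n_sites, n_h, cmb = NULL) {
  sums <- rowsum(TA, site_int)          # n_sites x R
  pres <- rowsum(TP, site_int)
  M <- sums / n_h
  Fm <- pres / n_h
  if (is.null(cmb)) {
    tot <- .colSums(M, n_sites, ncol(M))
    E <- sweep(M, 2, tot, "/")
    E[, tot == 0] <- 0
    IV <- sqrt(E * Fm)
    return(list(E = E, F = Fm, IV = IV))
  }
  tot <- .colSums(M, n_sites, ncol(M))
  k <- length(cmb)
  E <- Fm_c <- matrix(0, k, ncol(M))
  for (g in seq_len(k)) {
    C <- cmb[[g]]
    yC <- .colSums(M[C, , drop = FALSE], length(C), ncol(M)) / length(C)
    denom <- yC + (tot - .colSums(M[C, , drop = FALSE], length(C), ncol(M)))
    e <- yC / denom
    e[denom == 0] <- 0
    E[g, ] <- e
    Fm_c[g, ] <- .colSums(Fm[C, , drop = FALSE], length(C), ncol(M)) /
      length(C)
  }
  list(E = E, F = Fm_c, IV = sqrt(E * Fm_c))
}

# Validate and normalize a combinations argument into a named list of
# integer site-index vectors.
normalize_combinations <- function(cmb, site_levels) {
  ns <- length(site_levels)
  out <- lapply(cmb, function(C) {
    if (is.character(C)) C <- match(C, site_levels)
    C <- sort(unique(as.integer(C)))
    if (anyNA(C) || any(C < 1) || any(C > ns))
      stop("unknown site in combination", call. = FALSE)
    if (length(C) == 0) stop("empty site combination", call. = FALSE)
    if (length(C) == ns)
      stop("a combination of all sites is not allowed (exclusiveness degenerates to 1)",
           call. = FALSE)
    C
  })
  names(out) <- vapply(out, function(C)
    paste(site_levels[C], collapse = " & "), character(1))
  out
}

#' Indicator value (IndVal) analysis with blocked randomization
#'
#' For every taxon and every candidate group -- each single body site, or
#' each supplied combination of sites -- computes exclusiveness E,
#' faithfulness F and the indicator value `IV = sqrt(E * F)`. The taxon's
#' overall indicator value is the maximum over the candidate groups, with
#' the achieving group recorded (ties broken toward the first group in site
#' order and flagged). Significance comes from a blocked Monte-Carlo
#' randomization: in each of `n_perm` rounds the site labels are shuffled
#' independently within every horse, one relabelled table shared by all
#' taxa, and the full statistic (including the max-over-groups step) is
#' recomputed; `p = (1 + #\{IV* >= IV_obs\}) / (1 + n_perm)`. P-values are
#' corrected with Benjamini-Hochberg over the taxa of the run.
#'
#' For a combination C of sites, faithfulness is the presence constancy
#' over all samples in C and exclusiveness is `ybar_C / (ybar_C +
#' sum_{i not in C} ybar_i)` with `ybar_C` the mean over all samples in C;
#' for a singleton C this reduces exactly to the single-site definitions.
#'
#' @param x a [family_table()] with a complete (site x horse) design.
#' @param combinations `NULL` for the single-site analysis, or a list of
#'   site sets (names or indices), each a non-empty proper subset of sites.
#' @param n_perm number of randomizations (default 9999).
#' @param seed integer seed; results are deterministic given the seed.
#' @param fdr false discovery rate for the selection (default 0.05).
#' @return Object of class `indval` with `stats` (one row per taxon:
#'   `taxon`, `group`, `E`, `F`, `IV`, `p_raw`, `q`, `significant`, `tie`),
#'   the full `E`, `F` and `IV` group-by-taxon matrices, `groups`,
#'   `n_perm`, `seed`, `fdr`.
#' @seealso [indicator_table()] for the formatted significant-taxa table.
#' @export
indval <- function(x, combinations = NULL, n_perm = 9999, seed = NULL,
                   fdr = 0.05) {
  stopifnot(inherits(x, "family_table"))
  if (!is_complete_design(x))
    stop("blocked randomization requires every horse to have every site",
         call. = FALSE)
  n_perm <- stop_scalar_count(n_perm, "n_perm")
  site_levels <- levels(x$site)
  ns <- length(site_levels)
  nh <- nlevels(x$horse)
  TA <- t(x$abund)
  TP <- (TA > 0) + 0
  site_int <- as.integer(x$site)
  cmb <- if (!is.null(combinations))
    normalize_combinations(combinations, site_levels)
  group_names <- if (is.null(cmb)) site_levels else names(cmb)

  obs <- iv_engine(TA, TP, site_int, ns, nh, cmb)
  iv_obs <- apply(obs$IV, 2, max)
  best <- apply(obs$IV, 2, which.max)
  tie <- apply(obs$IV, 2, function(v) sum(v >= max(v) - 1e-12) > 1)

  # permutation stream: one relabelled table per round, shared across taxa.
  # The E denominator (sum of per-site means) is invariant under within-block
  # relabelling, so it is precomputed; squared IVs are compared to avoid a
  # matrix sqrt per round.
  horse_members <- split(seq_along(site_int), x$horse)
  n <- length(site_int)
  R_t <- ncol(TA)
  tot <- .colSums(rowsum(TA, site_int), ns, R_t) / nh
  inv_tot <- ifelse(tot > 0, 1 / tot, 0)
  iv2_obs <- iv_obs^2 - 1e-12  # margin so exact ties survive FP noise
  single <- is.null(cmb)
  B_max <- 512L
  scale_cell <- matrix(rep(inv_tot / nh^2, each = ns * B_max), ns * B_max)
  thr <- matrix(iv2_obs, B_max, R_t, byrow = TRUE)
  count <- with_seed(seed, {
    cnt <- numeric(R_t)
    done <- 0L
    while (done < n_perm) {
      B <- min(B_max, n_perm - done)
      # permutations are drawn one round at a time, horses in block order,
      # so the stream matches blocked_randomization_test() exactly
      s_mat <- matrix(0L, n, B)
      s_perm <- site_int
      for (k in seq_len(B)) {
        for (idx in horse_members)
          s_perm[idx] <- site_int[idx][sample.int(length(idx))]
        s_mat[, k] <- s_perm
      }
      # one indicator matrix for the whole batch: row (k-1)*ns + i collects
      # the samples assigned to site i in round k
      ri <- as.vector(s_mat + rep((seq_len(B) - 1L) * ns, each = n))
      G <- matrix(0, ns * B, n)
      G[cbind(ri, rep(seq_len(n), B))] <- 1
      sums <- G %*% TA
      pres <- G %*% TP
      if (single) {
        iv2_all <- sums * pres * scale_cell[seq_len(ns * B), , drop = FALSE]
        mx <- iv2_all[seq(1, ns * B, by = ns), , drop = FALSE]
        for (i in seq_len(ns)[-1])
          mx <- pmax(mx, iv2_all[seq(i, ns * B, by = ns), , drop = FALSE])
      } else {
        mx <- NULL
        for (g in seq_along(cmb)) {
          C <- cmb[[g]]
          rows_C <- as.vector(outer(C, (seq_len(B) - 1L) * ns, "+"))
          grp <- rep(seq_len(B), each = length(C))
          SC <- rowsum(sums[rows_C, , drop = FALSE], grp) / nh
          yC <- SC / length(C)
          denom <- yC + rep(tot, each = B) - SC
          e <- ifelse(denom > 0, yC / denom, 0)
          fC <- rowsum(pres[rows_C, , drop = FALSE], grp) /
            (nh * length(C))
          iv2_g <- e * fC
          mx <- if (is.null(mx)) iv2_g else pmax(mx, iv2_g)
        }
      }
      cnt <- cnt + .colSums(mx >= thr[seq_len(B), , drop = FALSE], B, R_t)
      done <- done + B
    }
    cnt
  })
  p_raw <- (1 + count) / (1 + n_perm)
  adj <- bh_fdr(p_raw, fdr)

  stats_df <- data.frame(
    taxon = x$taxa,
    group = group_names[best],
    E = obs$E[cbind(best, seq_along(best))],
    F = obs$F[cbind(best, seq_along(best))],
    IV = iv_obs,
    p_raw = p_raw,
    q = adj$q,
    significant = adj$q <= fdr,
    tie = tie,
    row.names = NULL)
  dimnames(obs$IV) <- dimnames(obs$E) <- dimnames(obs$F) <-
    list(group_names, x$taxa)
  structure(list(stats = stats_df, E = obs$E, F = obs$F, IV = obs$IV,
                 groups = group_names, combinations = cmb,
                 site_levels = site_levels, n_perm = n_perm, seed = seed,
                 fdr = fdr),
            class = "indval")
}

colMax <- function(m) do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))

#' @export
print.indval <- function(x, ...) {
  kind <- if (is.null(x$combinations)) "single body sites"
          else "combined body sites"
  cat(sprintf("IndVal analysis (%s): %d taxa, %d candidate groups\n", kind,
              nrow(x$stats), length(x$groups)))
  cat(sprintf("%d randomizations within blocks; BH FDR %.2f: %d significant\n",
              x$n_perm, x$fdr, sum(x$stats$significant)))
  sig <- indicator_table(x)
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' @export
summary.indval <- function(object, ...) {
  out <- object$stats[order(match(object$stats$group, object$groups),
                            -object$stats$IV), ]
  rownames(out) <- NULL
  out
}

#' Formatted table of significant indicator taxa
#'
#' One row per significant taxon (BH q below the run's FDR level), ordered
#' by group (site order) then descending indicator value, with IV and
#' p-value formatted to 4 decimal places. With no significant taxa an empty
#' table with the same columns is returned.
#'
#' @param object an [indval()] fit.
#' @param digits decimal places for IV and p.
#' @return Data frame with columns `body_site`, `taxon`, `IV`, `p_value`,
#'   `q_value`.
#' @export
indicator_table <- function(object, digits = 4) {
  stopifnot(inherits(object, "indval"))
  s <- object$stats[object$stats$significant, , drop = FALSE]
  s <- s[order(match(s$group, object$groups), -s$IV), , drop = FALSE]
  fmt <- paste0("%.", digits, "f")
  data.frame(body_site = s$group, taxon = s$taxon,
             IV = sprintf(fmt, s$IV), p_value = sprintf(fmt, s$p_raw),
             q_value = sprintf(fmt, s$q), row.names = NULL)
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` returning both the
#' adjusted values and the selected set at level `fdr`.
#'
#' @param p raw p-values in (0, 1\].
#' @param fdr selection level (default 0.05).
#' @return List with `q` (adjusted values) and `selected` (indices with
#'   `q <= fdr`). Empty input gives empty output.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))$q  # 0.04 0.04 0.04 0.50
#' @export
bh_fdr <- function(p, fdr = 0.05) {
  if (!length(p)) return(list(q = numeric(0), selected = integer(0)))
  if (any(p <= 0 | p > 1 | !is.finite(p)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, selected = which(q <= fdr))
}

#' Blocked Monte-Carlo randomization p-values for an arbitrary statistic
#'
#' The generic form of the randomization used by [indval()]: site labels
#' are shuffled independently within every horse `n_perm` times and the
#' supplied statistic is recomputed on each relabelled table; add-one
#' p-values count relabelled statistics at or above the observed ones. All
#' statistic components share the same shuffle stream (one relabelled table
#' per round).
#'
#' @param x a [family_table()] with a complete design.
#' @param statistic function taking a `family_table` and returning a
#'   numeric vector (larger = more extreme).
#' @param n_perm number of randomizations.
#' @param seed integer seed.
#' @return List with `observed`, `p` (both vectors as returned by
#'   `statistic`), `n_perm`, `seed`.
#' @export
blocked_randomization_test <- function(x, statistic, n_perm = 9999,
                                       seed = NULL) {
  stopifnot(inherits(x, "family_table"), is.function(statistic))
  if (!is_complete_design(x))
    stop("blocks with unequal site sets: every horse needs every site",
         call. = FALSE)
  n_perm <- stop_scalar_count(n_perm, "n_perm")
  obs <- statistic(x)
  horse_members <- split(seq_along(x$site), x$horse)
  count <- with_seed(seed, {
    cnt <- integer(length(obs))
    for (k in seq_len(n_perm)) {
      site_perm <- x$site
      for (idx in horse_members)
        site_perm[idx] <- x$site[idx][sample.int(length(idx))]
      xp <- x
      xp$site <- site_perm
      cnt <- cnt + (statistic(xp) >= obs)
    }
    cnt
  })
  list(observed = obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm,
       seed = seed)
}
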