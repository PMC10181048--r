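#' Bin genotypes into score groups
#'
#' Genotypes are grouped by where their score falls among descending
#' breakpoints.  With the default breaks `0.7, 0.6, 0.5, 0.4` the groups are
#' group 1 = \[0.70, 1.00\], group 2 = \[0.60, 0.70), group 3 = \[0.50, 0.60),
#' group 4 = \[0.40, 0.50), group 5 = \[0.00, 0.40).  Bins are closed on the
#' lower bound, so a score exactly on a breakpoint goes to the better group
#' (0.70 is group 1).  Groups 1 and 2 — scores at or above 0.6 — are the
#' conventional superior-genotype classes.
#'
#' @param x a `"siig"` fit or a numeric vector of scores in \[0, 1\].
#' @param breaks strictly decreasing breakpoints in (0, 1).
#' @return integer vector of group labels (1 = best group), named by
#'   genotype when names are available.
#' @examples
#' siig_groups(c(a = 0.72, b = 0.70, c = 0.55, d = 0.1))
#' @export
siig_groups <- function(x, breaks = c(0.7, 0.6, 0.5, 0.4)) {
  s <- if (inherits(x, "siig")) x$scores else x
  if (!is.numeric(s)) stop("`x` must be a siig fit or numeric scores", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(breaks), strictly = TRUE) || any(breaks <= 0 | breaks >= 1))
    stop("`breaks` must be strictly decreasing and inside (0, 1)", call. = FALSE)
  g <- length(breaks) + 1L - findInterval(s, sort(breaks))
  stats::setNames(as.integer(g), names(s))
}

#' Per-group counts and trait means
#'
#' Summarizes a grouping (from [siig_groups()]) against the raw trait matrix
#' the scores came from: membership count and the unweighted arithmetic mean
#' of every trait within each group, in the trait's original units.  Groups
#' with no members are reported with count 0 and `NA` means unless
#' `drop_empty` is set.
#'
#' @param groups integer group labels named by genotype, or a `"siig"` fit
#'   (grouped with default breaks).
#' @param x the genotype-by-trait matrix the groups refer to (or a `"siig"`
#'   fit, whose stored matrix is used).
#' @param drop_empty drop groups with no members instead of reporting them.
#' @return data frame with columns `group`, `n`, then one mean per trait.
#' @export
group_summary <- function(groups, x = NULL, drop_empty = FALSE) {
  if (inherits(groups, "siig")) {
    if (is.null(x)) x <- groups$traits
    groups <- siig_groups(groups)
  }
  if (inherits(x, "siig")) x <- x$traits
  m <- as_trait_matrix(x)
  if (is.null(names(groups))) {
    if (length(groups) != nrow(m))
      stop("`groups` length does not match the trait matrix", call. = FALSE)
  } else {
    if (!setequal(names(groups), rownames(m)))
      stop("`groups` and the trait matrix cover different genotypes", call. = FALSE)
    groups <- groups[rownames(m)]
  }
  labels <- seq_len(max(groups))
  out <- data.frame(group = labels, n = 0L)
  means <- matrix(NA_real_, nrow = length(labels), ncol = ncol(m),
                  dimnames = list(NULL, colnames(m)))
  for (g in labels) {
    members <- which(groups == g)
    out$n[g] <- length(members)
    if (length(members))
      means[g, ] <- colMeans(m[members, , drop = FALSE])
  }
  out <- cbind(out, as.data.frame(means))
  if (drop_empty) out <- out[out$n > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotypes at or above a score threshold
#'
#' The headline use of the index is a simple cut: genotypes with scores at
#' or above 0.6 are flagged superior.  The comparison is inclusive
#' (`>= tau`).
#'
#' @param x a `"siig"` fit or named numeric scores.
#' @param tau threshold in \[0, 1\].
#' @return list with `count` and `ids` (identifiers ordered by decreasing
#'   score, ties by input order).
#' @examples
#' threshold_select(c(g1 = 0.7, g2 = 0.59, g3 = 0.6), tau = 0.6)
#' @export
threshold_select <- function(x, tau = 0.6) {
  s <- if (inherits(x, "siig")) x$scores else x
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("`tau` must be a single value in [0, 1]", call. = FALSE)
  keep <- which(s >= tau)
  keep <- keep[order(-s[keep])]
  ids <- if (is.null(names(s))) as.character(keep) else names(s)[keep]
  list(count = length(keep), ids = ids)
}
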