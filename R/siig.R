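#' Vector-normalize trait columns
#'
#' Divides every entry of a trait column by the column's root sum of squares,
#' so each column has unit Euclidean norm.  This makes the columns unit-free
#' and mutually comparable without shifting them: a genotype keeps its
#' relative standing within each trait.
#'
#' @param x genotype-by-trait matrix (or anything [as_trait_matrix()] accepts).
#' @return matrix of the same shape with `colSums(out^2) == 1` per column.
#' @examples
#' normalize_traits(cbind(YLD = c(3, 4)))  # 0.6, 0.8
#' @export
normalize_traits <- function(x) {
  m <- as_trait_matrix(x)
  norms <- sqrt(colSums(m^2))
  zero <- which(norms == 0)
  if (length(zero))
    stop("all-zero trait column(s): ", paste(colnames(m)[zero], collapse = ", "),
         call. = FALSE)
  sweep(m, 2L, norms, "/")
}

#' Ideal and non-ideal genotype profiles per trait
#'
#' For each trait the ideal profile takes the best normalized value across
#' genotypes and the non-ideal profile the worst, where "best" is the maximum
#' for benefit traits and the minimum for cost traits.
#'
#' @param normalized normalized matrix from [normalize_traits()].
#' @param directions direction spec (see [siig_directions()]).
#' @return list with numeric vectors `r_plus` (ideal) and `r_minus`
#'   (non-ideal), one entry per trait.
#' @export
ideal_profiles <- function(normalized, directions = "warm-barley") {
  signs <- direction_signs(directions, colnames(normalized))
  hi <- apply(normalized, 2L, max)
  lo <- apply(normalized, 2L, min)
  list(r_plus  = ifelse(signs > 0, hi, lo),
       r_minus = ifelse(signs > 0, lo, hi))
}

#' Euclidean distances to the ideal and non-ideal profiles
#'
#' @param normalized normalized matrix from [normalize_traits()].
#' @param profiles list from [ideal_profiles()].
#' @return list with nonnegative numeric vectors `d_plus` and `d_minus`
#'   (one entry per genotype).
#' @export
ideal_distances <- function(normalized, profiles) {
  if (length(profiles$r_plus) != ncol(normalized) ||
      length(profiles$r_minus) != ncol(normalized))
    stop("profile length does not match the number of traits", call. = FALSE)
  list(
    d_plus  = sqrt(rowSums(sweep(normalized, 2L, profiles$r_plus)^2)),
    d_minus = sqrt(rowSums(sweep(normalized, 2L, profiles$r_minus)^2))
  )
}

#' Closeness coefficient and ranks from the two distances
#'
#' The score of genotype i is `d_minus / (d_plus + d_minus)`, which lies in
#' \[0, 1\]: 1 means the genotype sits exactly on the ideal profile, 0 on the
#' non-ideal one.  If both distances are zero (all genotypes identical on
#' every trait) the genotype is simultaneously ideal and non-ideal; the score
#' is set to 0.5 with a warning rather than erroring.
#'
#' @param d distance list from [ideal_distances()].
#' @param ties rank tie policy: `"first"` (stable, ties broken by input
#'   order — matches tables that print distinct ranks) or `"average"`
#'   (use for rank correlations).
#' @return list with `siig` (scores in \[0, 1\]) and `rank`
#'   (1 = best, a permutation of `1..n` under `"first"`).
#' @export
siig_scores <- function(d, ties = c("first", "average")) {
  ties <- match.arg(ties)
  denom <- d$d_plus + d$d_minus
  degenerate <- denom == 0
  if (any(degenerate)) {
    warning("d+ and d- are both zero for ", sum(degenerate),
            " genotype(s); scoring them 0.5", call. = FALSE)
    denom[degenerate] <- 1
  }
  s <- d$d_minus / denom
  s[degenerate] <- 0.5
  list(siig = s, rank = rank(-s, ties.method = ties))
}

#' Selection index of the ideal genotype
#'
#' Scores and ranks genotypes by how close each one sits to a hypothetical
#' ideal genotype that attains the best observed value of every trait.
#' The chain is: vector-normalize the trait columns
#' ([normalize_traits()]), take per-trait directed extrema as ideal and
#' non-ideal profiles ([ideal_profiles()]), measure each genotype's Euclidean
#' distance to both ([ideal_distances()]), and score it by the closeness
#' coefficient d-/(d+ + d-) ([siig_scores()]).  Scores are unit-free,
#' unchanged by rescaling any trait, and require no trait weights.
#'
#' @param x genotype-by-trait matrix or data frame (first non-numeric column
#'   taken as genotype identifiers); see [as_trait_matrix()].
#' @param directions trait direction spec: a preset name such as
#'   `"warm-barley"`, a named vector (`c(YLD = "benefit", DMA = "cost")`),
#'   or a config file path.  See [siig_directions()].
#' @param ties rank tie policy, as in [siig_scores()].
#' @param id_col optional identifier column when `x` is a data frame.
#' @return an object of class `"siig"`: a list with components
#'   `scores` (named numeric, in \[0, 1\]), `rank` (1 = best), `d_plus`,
#'   `d_minus`, `normalized` (the unit-norm matrix), `ideal` (the two
#'   profiles), `directions`, `traits` (the input matrix) and `call`.
#'   Methods: [print.siig()], [summary.siig()], [coef.siig()],
#'   [as.data.frame.siig()], [plot.siig()].
#' @examples
#' trial <- siig_fixture("table4")
#' fit <- siig(trial[c("genotype", "DHE", "DMA", "GFP", "PLH", "TKW", "YLD")])
#' head(as.data.frame(fit))
#' @export
siig <- function(x, directions = "warm-barley", ties = c("first", "average"),
                 id_col = NULL) {
  m <- as_trait_matrix(x, id_col = id_col)
  r <- normalize_traits(m)
  profiles <- ideal_profiles(r, directions)
  d <- ideal_distances(r, profiles)
  sc <- siig_scores(d, ties = ties)
  structure(list(
    scores = stats::setNames(sc$siig, rownames(m)),
    rank = stats::setNames(as.integer(sc$rank), rownames(m)),
    d_plus = stats::setNames(d$d_plus, rownames(m)),
    d_minus = stats::setNames(d$d_minus, rownames(m)),
    normalized = r,
    ideal = profiles,
    directions = siig_directions(directions)[colnames(m)],
    traits = m,
    ties = match.arg(ties),
    call = match.call()
  ), class = "siig")
}

#' @export
print.siig <- function(x, digits = 3, ...) {
  n <- length(x$scores)
  cat("Selection index of ideal genotype\n")
  cat(sprintf("  %d genotypes x %d traits (%s)\n", n, ncol(x$traits),
              paste0(names(x$directions), ifelse(x$directions == "benefit",
                                                 "+", "-"), collapse = " ")))
  top <- order(x$rank)[seq_len(min(5L, n))]
  cat("  top genotypes: ",
      paste(sprintf("%s (%.*f)", names(x$scores)[top], digits,
                    x$scores[top]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract the index scores
#' @param object a `"siig"` fit.
#' @param ... unused.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
coef.siig <- function(object, ...) object$scores

#' Per-genotype results as a data frame
#'
#' @param x a `"siig"` fit.
#' @param row.names,optional ignored (S3 signature).
#' @param ... unused.
#' @return data frame with columns `genotype`, `d_plus`, `d_minus`, `siig`,
#'   `rank`, in input genotype order.
#' @export
as.data.frame.siig <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(genotype = names(x$scores),
             d_plus = unname(x$d_plus),
             d_minus = unname(x$d_minus),
             siig = unname(x$scores),
             rank = unname(x$rank),
             stringsAsFactors = FALSE)
}

#' Summarize an index fit
#'
#' Reports the score distribution, the default score groups (see
#' [siig_groups()]) and the leading genotypes.
#'
#' @param object a `"siig"` fit.
#' @param n_top number of leading genotypes to show.
#' @param breaks group breakpoints passed to [siig_groups()].
#' @param ... unused.
#' @export
summary.siig <- function(object, n_top = 10L, breaks = c(0.7, 0.6, 0.5, 0.4),
                         ...) {
  groups <- siig_groups(object, breaks = breaks)
  top <- order(object$rank)[seq_len(min(n_top, length(object$scores)))]
  structure(list(
    n = length(object$scores),
    traits = colnames(object$traits),
    directions = object$directions,
    quantiles = stats::quantile(object$scores),
    group_counts = table(groups),
    breaks = breaks,
    top = as.data.frame(object)[top, , drop = FALSE]
  ), class = "summary.siig")
}

#' @export
print.summary.siig <- function(x, digits = 3, ...) {
  cat(sprintf("SIIG over %d genotypes, traits: %s\n", x$n,
              paste0(x$traits, ifelse(x$directions == "benefit", "+", "-"),
                     collapse = " ")))
  cat("Score quantiles:\n")
  print(round(x$quantiles, digits))
  cat("Group sizes (breaks ", paste(x$breaks, collapse = ", "), "):\n", sep = "")
  print(x$group_counts)
  cat("Leading genotypes:\n")
  print(x$top, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot an index fit
#'
#' `type = "scores"` draws the sorted scores with the conventional
#' superior-genotype thresholds at 0.6 and 0.7; `type = "distances"` draws
#' each genotype in the (d+, d-) plane, where the upper-left corner is ideal.
#'
#' @param x a `"siig"` fit.
#' @param type which display to draw.
#' @param ... passed to the underlying plot call.
#' @export
plot.siig <- function(x, type = c("scores", "distances"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    ord <- order(x$scores, decreasing = TRUE)
    graphics::plot(seq_along(ord), x$scores[ord], type = "h",
                   xlab = "genotype (ranked)", ylab = "SIIG",
                   ylim = c(0, 1), ...)
    graphics::abline(h = c(0.6, 0.7), lty = 2, col = "grey40")
  } else {
    graphics::plot(x$d_plus, x$d_minus,
                   xlab = "distance to ideal (d+)",
                   ylab = "distance to non-ideal (d-)", ...)
    graphics::text(x$d_plus, x$d_minus, names(x$scores), pos = 3, cex = 0.6)
  }
  invisible(x)
}
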