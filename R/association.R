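#' Pearson correlation with significance stars
#'
#' Product-moment correlation between two trait (or score) vectors, with a
#' two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and the
#' usual star code: `"*"` for p < 0.05, `"**"` for p < 0.01, `""` otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return list with `r`, `p`, `stars`, `n`.
#' @examples
#' siig_correlate(1:10, (1:10) + rnorm(10, sd = 0.1))
#' @export
siig_correlate <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  list(r = r, p = p, stars = sig_stars(p), n = n)
}

pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' All-pairs correlation report
#'
#' Pairwise Pearson correlations among the numeric columns of `x`, each with
#' a two-sided p-value and star code, ready for a correlation heat map.
#' When a `"siig"` fit is supplied through `siig`, its scores are appended as
#' an extra `SIIG` column so trait-index associations appear in the same
#' report.  Constant columns yield `NA` entries (with a warning) rather than
#' aborting the report.
#'
#' @param x genotype-by-trait matrix or data frame of numeric columns.
#' @param siig optional `"siig"` fit or numeric vector aligned with the rows
#'   of `x`.
#' @return object of class `"siig_cortab"`: a list with matrices `r` and `p`,
#'   a character matrix `stars`, and `n`.  `as.data.frame()` turns it into a
#'   long table (`trait_a`, `trait_b`, `r`, `p`, `stars`) over the lower
#'   triangle.
#' @export
correlation_matrix <- function(x, siig = NULL) {
  m <- as_trait_matrix(x)
  if (!is.null(siig)) {
    s <- if (inherits(siig, "siig")) siig$scores else siig
    if (length(s) != nrow(m))
      stop("`siig` scores do not match the rows of `x`", call. = FALSE)
    if (!is.null(names(s)) && !is.null(rownames(m))) s <- s[rownames(m)]
    m <- cbind(m, SIIG = unname(s))
  }
  k <- ncol(m)
  constant <- which(apply(m, 2L, stats::sd) == 0)
  if (length(constant))
    warning("constant column(s), correlations undefined: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  p <- r
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (i %in% constant || j %in% constant) next
      ct <- siig_correlate(m[, i], m[, j])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  structure(list(r = r, p = p, stars = sig_stars(p), n = nrow(m)),
            class = "siig_cortab")
}

#' @export
print.siig_cortab <- function(x, digits = 2, ...) {
  shown <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                  nrow = nrow(x$r), dimnames = dimnames(x$r))
  shown[is.na(x$r)] <- "NA"
  shown[upper.tri(shown)] <- ""
  cat(sprintf("Pearson correlations (n = %d; * p<0.05, ** p<0.01)\n", x$n))
  print(shown, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.siig_cortab <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  data.frame(trait_a = rownames(x$r)[idx[, 1L]],
             trait_b = colnames(x$r)[idx[, 2L]],
             r = x$r[idx],
             p = x$p[idx],
             stars = x$stars[idx],
             stringsAsFactors = FALSE)
}

#' Per-trait summary statistics
#'
#' Arithmetic mean, minimum and maximum of each trait column, in the trait's
#' own units.
#'
#' @param x genotype-by-trait matrix or data frame.
#' @return data frame with columns `trait`, `mean`, `min`, `max`.
#' @export
trait_summary <- function(x) {
  m <- as_trait_matrix(x)
  data.frame(trait = colnames(m),
             mean = colMeans(m),
             min = apply(m, 2L, min),
             max = apply(m, 2L, max),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Difference between two trait column means
#'
#' @param x genotype-by-trait matrix or data frame.
#' @param a,b trait (column) names; the result is `mean(a) - mean(b)`.
#' @return single number in the traits' units.
#' @export
trait_mean_diff <- function(x, a, b) {
  m <- as_trait_matrix(x)
  for (nm in c(a, b))
    if (!nm %in% colnames(m)) stop("unknown trait column: ", nm, call. = FALSE)
  mean(m[, a]) - mean(m[, b])
}
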