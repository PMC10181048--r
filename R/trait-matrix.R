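#' Coerce an object to a validated genotype-by-trait matrix
#'
#' Accepts a numeric matrix or a data frame and returns a plain numeric matrix
#' with genotype identifiers as row names and trait names as column names.
#' Data frames may carry the identifiers either as row names or in a leading
#' non-numeric column (e.g. the first column of a file read with
#' [read_trait_table()]); matrices must carry them as row names, otherwise
#' `1..n` is used.
#'
#' Invariants enforced: at least two genotypes and one trait, distinct
#' genotype identifiers, distinct trait names, and no missing or non-finite
#' value.  Negative trait values are mathematically fine for the index but
#' are usually a data error for agronomic traits, so they raise a warning.
#'
#' @param x matrix or data frame of trait values.
#' @param id_col optional name or index of the identifier column when `x` is
#'   a data frame; by default a single leading non-numeric column is detected.
#' @return numeric matrix (genotypes in rows, traits in columns).
#' @examples
#' as_trait_matrix(data.frame(genotype = c("a", "b"), YLD = c(3, 4)))
#' @export
as_trait_matrix <- function(x, id_col = NULL) {
  if (is.data.frame(x)) {
    ids <- NULL
    if (!is.null(id_col)) {
      ids <- as.character(x[[id_col]])
      x[[id_col]] <- NULL
    } else {
      numeric_col <- vapply(x, is.numeric, logical(1))
      if (!numeric_col[1L] && all(numeric_col[-1L])) {
        ids <- as.character(x[[1L]])
        x <- x[-1L]
      }
    }
    m <- as.matrix(x)
    if (!is.null(ids)) rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("`x` must be a matrix or data frame of trait values", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("trait", seq_len(ncol(m)))
  validate_trait_matrix(m)
  m
}

validate_trait_matrix <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 genotypes, got ", nrow(m), call. = FALSE)
  if (ncol(m) < 1L) stop("need at least 1 trait", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate genotype identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate trait names: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L, function(rc) {
      paste0("genotype ", rownames(m)[rc[1L]], " / trait ", colnames(m)[rc[2L]])
    })
    stop("missing or non-finite trait values at: ", paste(cells, collapse = "; "),
         call. = FALSE)
  }
  if (any(m < 0))
    warning("trait matrix contains negative values; the index is defined but ",
            "check the data", call. = FALSE)
  invisible(m)
}

#' Read a genotype-by-trait table from a delimited text file
#'
#' Expects a header row, a first column of genotype identifiers, and numeric
#' trait columns.  The delimiter is inferred from the file extension
#' (`.csv` comma, anything else tab) unless `sep` is given.  Only the plain
#' decimal point is supported.
#'
#' @param path file to read.
#' @param sep field delimiter; `NULL` (default) infers it from the extension.
#' @return numeric genotype-by-trait matrix, as from [as_trait_matrix()].
#' @seealso [write_trait_table()]
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L)
    stop("expected a genotype-ID column plus at least one trait column in ", path,
         call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      raw <- as.character(vals[[j]])
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) | !nzchar(trimws(raw)))
      if (length(bad))
        stop("non-numeric or blank cell in column '", names(vals)[j],
             "', row ", bad[1L], " (genotype ", ids[bad[1L]], ")", call. = FALSE)
      vals[[j]] <- num
    }
    miss <- which(is.na(vals[[j]]))
    if (length(miss))
      stop("missing value in column '", names(vals)[j], "', row ", miss[1L],
           " (genotype ", ids[miss[1L]], ")", call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_trait_matrix(m)
  m
}

#' Write a genotype-by-trait table to a delimited text file
#'
#' Inverse of [read_trait_table()]: writes a header row and a leading
#' `genotype` column.  Values are written at full precision so that
#' `read_trait_table(write_trait_table(x))` round-trips exactly.
#'
#' @param x genotype-by-trait matrix (or anything [as_trait_matrix()] accepts).
#' @param path file to write.
#' @param sep field delimiter; `NULL` infers it from the extension as in
#'   [read_trait_table()].
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path, sep = NULL) {
  m <- as_trait_matrix(x)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(genotype = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Grain-filling period from heading and maturity dates
#'
#' The grain-filling period (GFP, days) is the stretch between heading and
#' physiological maturity: `GFP = DMA - DHE`.  Both arguments are day counts
#' from sowing, so maturity can never precede heading; a negative result is
#' reported as an error naming the genotype.
#'
#' @param dhe numeric vector, days to heading.
#' @param dma numeric vector, days to physiological maturity (same length,
#'   same genotype order).
#' @param genotypes optional identifiers used in error messages; defaults to
#'   the names of `dhe` or `1..n`.
#' @return numeric vector of grain-filling periods in days.
#' @examples
#' derive_gfp(dhe = c(101, 99), dma = c(134, 138))  # 33, 39
#' @export
derive_gfp <- function(dhe, dma, genotypes = NULL) {
  if (length(dhe) != length(dma))
    stop("`dhe` and `dma` must have the same length", call. = FALSE)
  if (is.null(genotypes)) genotypes <- names(dhe)
  if (is.null(genotypes)) genotypes <- as.character(seq_along(dhe))
  gfp <- dma - dhe
  neg <- which(gfp < 0)
  if (length(neg))
    stop("maturity precedes heading for genotype ",
         paste(genotypes[neg], collapse = ", "), call. = FALSE)
  names(gfp) <- names(dhe)
  gfp
}
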