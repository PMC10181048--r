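#' Bundled multi-environment barley trial tables
#'
#' The package ships the published summary tables of a 111-genotype barley
#' trial grown in four warm-climate environments of Iran (Ahvaz, Gonbad,
#' Zabol, Darab):
#'
#' * `"table3"` — per-environment grain yield (kg/ha) together with the
#'   per-environment index value and rank of every genotype: columns
#'   `genotype`, `YLD_<env>`, `SIIG_<env>`, `rank_<env>`.
#' * `"table4"` — across-environment genotype means of the six traits
#'   (`DHE`, `DMA`, `GFP`, `PLH`, `TKW`, `YLD`), the per-trait ranks as
#'   printed, and the published overall `SIIG` and `rank`.
#'
#' Values are transcribed from the printed tables verbatim (rounded as
#' printed).  Note that `GFP` in `table4` can differ from `DMA - DHE` by up
#' to one day because the grain-filling period was recorded in only three of
#' the four environments, so its mean averages a different environment
#' subset than the heading/maturity means.
#'
#' @param name `"table3"` or `"table4"`.
#' @return data frame with 111 rows; `genotype` is character.
#' @examples
#' trial <- siig_fixture("table4")
#' subset(trial, genotype == "86")
#' @export
siig_fixture <- function(name = c("table4", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "siig",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$genotype <- as.character(df$genotype)
  # integrity checks on the shipped data
  stopifnot(nrow(df) == 111L, !anyDuplicated(df$genotype))
  siig_cols <- grep("^SIIG", names(df), value = TRUE)
  stopifnot(length(siig_cols) >= 1L,
            all(unlist(df[siig_cols]) >= 0), all(unlist(df[siig_cols]) <= 1))
  df
}

#' Trait matrix of the bundled trial
#'
#' Convenience accessor: the `table4` fixture reduced to its genotype
#' identifiers and six trait-mean columns, ready for [siig()].
#'
#' @return numeric 111 x 6 matrix with genotype row names.
#' @examples
#' fit <- siig(fixture_trait_matrix())
#' names(which(fit$rank == 1))
#' @export
fixture_trait_matrix <- function() {
  df <- siig_fixture("table4")
  as_trait_matrix(df[c("genotype", "DHE", "DMA", "GFP", "PLH", "TKW", "YLD")])
}
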