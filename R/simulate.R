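# Default simulated trait set: means are the grand genotype means of the
# bundled warm-climate barley trial; SDs are the empirical SDs of its
# across-environment genotype means; correlation signs follow the trial's
# trait associations (yield up with grain-filling period, down with maturity
# via the heading/maturity coupling).
.sim_defaults <- list(
  traits = c("DHE", "DMA", "GFP", "PLH", "TKW", "YLD"),
  means = c(DHE = 101.8, DMA = 135.7, GFP = 32.5, PLH = 84.6,
            TKW = 38.4, YLD = 3750),
  sds = c(DHE = 2.5, DMA = 2.0, GFP = 1.7, PLH = 6.2, TKW = 3.4, YLD = 450)
)

.sim_default_cor <- function() {
  traits <- .sim_defaults$traits
  S <- diag(length(traits))
  dimnames(S) <- list(traits, traits)
  set_pair <- function(a, b, v) {
    S[a, b] <<- v
    S[b, a] <<- v
  }
  set_pair("DHE", "DMA", 0.6)
  set_pair("YLD", "GFP", 0.3)
  set_pair("YLD", "DMA", -0.3)
  set_pair("YLD", "DHE", -0.2)
  S
}

#' Simulate a genotype-by-trait matrix
#'
#' Draws genotype trait vectors from a multivariate normal with the requested
#' per-trait means, standard deviations and inter-trait correlation matrix.
#' The defaults emulate a warm-climate barley trial: six traits (DHE, DMA,
#' GFP, PLH, TKW, YLD) with the bundled trial's grand means and dispersions,
#' yield positively correlated with grain-filling period and negatively with
#' days to heading/maturity.
#'
#' With `planted_winner = TRUE`, one genotype (the last row, labelled
#' `"winner"`) is overwritten with the directed extremum of every trait
#' pushed a further 3 SD in the favourable direction, so it strictly
#' dominates the rest and must come out ranked 1 with a score of 1.
#'
#' Day-count traits are left continuous by default since the index is
#' scale-free; `round_days` rounds every column whose name is a day trait
#' (DHE, DMA, GFP) to whole days.
#'
#' @param n number of genotypes (>= 2).
#' @param means,sds named numeric vectors of per-trait moments; defaults to
#'   the barley trait set above.
#' @param cor_matrix inter-trait correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite); defaults to the barley structure.
#' @param directions direction spec used to orient the planted winner;
#'   defaults to `"warm-barley"` when the default traits are used, otherwise
#'   required when `planted_winner = TRUE`.
#' @param planted_winner plant a strictly dominant genotype (see above).
#' @param round_days round day-count traits to integers.
#' @param seed optional integer seed; fixes all randomness.
#' @return numeric genotype-by-trait matrix with genotype row names.
#' @examples
#' m <- simulate_traits(20, seed = 1)
#' siig(m)
#' @export
simulate_traits <- function(n, means = .sim_defaults$means,
                            sds = .sim_defaults$sds,
                            cor_matrix = NULL,
                            directions = NULL,
                            planted_winner = FALSE,
                            round_days = FALSE,
                            seed = NULL) {
  if (n < 2L) stop("need at least 2 genotypes", call. = FALSE)
  if (!is.null(names(means)) && !is.null(names(sds))) sds <- sds[names(means)]
  if (length(means) != length(sds) || anyNA(sds))
    stop("`means` and `sds` must cover the same traits", call. = FALSE)
  if (any(sds <= 0)) stop("`sds` must be positive", call. = FALSE)
  traits <- names(means)
  if (is.null(traits)) traits <- paste0("trait", seq_along(means))
  if (is.null(cor_matrix)) {
    cor_matrix <- if (identical(traits, .sim_defaults$traits))
      .sim_default_cor() else diag(length(means))
  }
  if (!isTRUE(all.equal(cor_matrix, t(cor_matrix))) ||
      !isTRUE(all.equal(unname(diag(cor_matrix)), rep(1, length(means)))))
    stop("`cor_matrix` must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(cor_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`cor_matrix` is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # MVN draw via eigendecomposition (handles the semi-definite boundary too)
  ed <- eigen(cor_matrix, symmetric = TRUE)
  root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), length(means))
  z <- matrix(stats::rnorm(n * length(means)), nrow = n)
  m <- z %*% t(root)
  m <- sweep(sweep(m, 2L, sds, "*"), 2L, means, "+")
  dimnames(m) <- list(paste0("g", seq_len(n)), traits)

  if (planted_winner) {
    if (is.null(directions)) {
      if (!identical(traits, .sim_defaults$traits))
        stop("`directions` is required to plant a winner for custom traits",
             call. = FALSE)
      directions <- "warm-barley"
    }
    signs <- direction_signs(directions, traits)
    body <- m[-n, , drop = FALSE]
    best <- ifelse(signs > 0, apply(body, 2L, max), apply(body, 2L, min))
    m[n, ] <- best + signs * 3 * sds
    rownames(m)[n] <- "winner"
  }
  if (round_days) {
    day_traits <- intersect(traits, c("DHE", "DMA", "GFP"))
    m[, day_traits] <- round(m[, day_traits])
  }
  m
}
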