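test_that("vector normalization matches hand computation and unit-norm invariant", {
  # single benefit column [3, 4]: norms to [0.6, 0.8]
  r <- normalize_traits(cbind(YLD = c(3, 4)))
  expect_equal(unname(r[, 1]), c(0.6, 0.8))

  # constant column: every entry 1/sqrt(n)
  n <- 7
  r <- normalize_traits(cbind(t = rep(5, n)))
  expect_equal(unname(r[, 1]), rep(1 / sqrt(n), n))

  # unit column sum of squares on an arbitrary matrix
  set.seed(11)
  m <- random_trait_matrix(23, 4)
  expect_equal(unname(colSums(normalize_traits(m)^2)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("normalization of the trial yield column matches direct summation", {
  t4 <- siig_fixture("table4")
  yld <- t4$YLD
  # oracle: direct summation over the printed column
  ss <- 0
  for (v in yld) ss <- ss + v * v
  expected <- 4466 / sqrt(ss)
  r <- normalize_traits(fixture_trait_matrix())
  expect_equal(unname(r[t4$genotype == "86", "YLD"]), expected,
               tolerance = 1e-12)
})

test_that("normalization rejects bad columns with informative errors", {
  expect_error(normalize_traits(cbind(a = c(1, 2), zeroed = c(0, 0))),
               "zeroed")
  expect_error(as_trait_matrix(cbind(a = c(1, NA), b = c(2, 3))),
               "non-finite")
  expect_warning(as_trait_matrix(cbind(a = c(-1, 2))), "negative")
})

test_that("ideal profiles take directed extrema and respect orientation", {
  r <- normalize_traits(cbind(t1 = c(3, 4)))
  p <- ideal_profiles(r, c(t1 = "benefit"))
  expect_equal(unname(p$r_plus), 0.8)
  expect_equal(unname(p$r_minus), 0.6)
  p <- ideal_profiles(r, c(t1 = "cost"))
  expect_equal(unname(p$r_plus), 0.6)
  expect_equal(unname(p$r_minus), 0.8)

  # every profile entry is an attained column value; orientation inequality
  set.seed(21)
  m <- random_trait_matrix(15, 5)
  dirs <- random_directions(5)
  rn <- normalize_traits(m)
  p <- ideal_profiles(rn, dirs)
  for (j in seq_len(5)) {
    expect_true(p$r_plus[j] %in% rn[, j])
    expect_true(p$r_minus[j] %in% rn[, j])
    if (dirs[j] == "benefit") expect_gte(p$r_plus[j], p$r_minus[j])
    else expect_lte(p$r_plus[j], p$r_minus[j])
  }

  # trait missing from the spec is an error naming it
  expect_error(ideal_profiles(rn, c(t1 = "benefit")), "t2")
})

test_that("distances agree with an elementwise loop and trivial cases", {
  r <- normalize_traits(cbind(t1 = c(3, 4)))
  p <- ideal_profiles(r, c(t1 = "benefit"))
  d <- ideal_distances(r, p)
  expect_equal(unname(d$d_plus), c(0.2, 0))
  expect_equal(unname(d$d_minus), c(0, 0.2))

  set.seed(31)
  m <- random_trait_matrix(3, 2)
  rn <- normalize_traits(m)
  p <- ideal_profiles(rn, c(t1 = "benefit", t2 = "cost"))
  d <- ideal_distances(rn, p)
  for (i in 1:3) {
    dp <- sqrt((rn[i, 1] - p$r_plus[1])^2 + (rn[i, 2] - p$r_plus[2])^2)
    dn <- sqrt((rn[i, 1] - p$r_minus[1])^2 + (rn[i, 2] - p$r_minus[2])^2)
    expect_equal(unname(d$d_plus[i]), unname(dp), tolerance = 1e-14)
    expect_equal(unname(d$d_minus[i]), unname(dn), tolerance = 1e-14)
  }
  # triangle inequality against the ideal/non-ideal separation
  sep <- sqrt(sum((p$r_plus - p$r_minus)^2))
  expect_true(all(d$d_plus <= sep + d$d_minus + 1e-12))

  expect_error(ideal_distances(rn, list(r_plus = 1, r_minus = 1)), "match")
})

test_that("closeness coefficient handles the extremes and the degenerate case", {
  s <- siig_scores(list(d_plus = c(0, 0.3), d_minus = c(0.5, 0.3)))
  expect_equal(s$siig, c(1, 0.5))
  expect_equal(s$rank, c(1, 2))
  expect_warning(
    s <- siig_scores(list(d_plus = c(0, 0), d_minus = c(0, 0))),
    "0.5")
  expect_equal(s$siig, c(0.5, 0.5))
})

test_that("the composed pipeline equals its stages and handles edge geometries", {
  # two-point single benefit trait: anti-ideal scores 0, ideal scores 1
  fit <- siig(cbind(YLD = c(3, 4)), directions = c(YLD = "benefit"))
  expect_equal(unname(fit$scores), c(0, 1))

  # dominance: a genotype best on every trait scores exactly 1
  m <- rbind(g1 = c(10, 5), g2 = c(8, 7), g3 = c(20, 1))
  colnames(m) <- c("t1", "t2")
  fit <- siig(m, directions = c(t1 = "benefit", t2 = "cost"))
  expect_equal(unname(fit$scores["g3"]), 1)
  expect_equal(unname(fit$rank["g3"]), 1L)

  # composition equals running the four stages by hand
  set.seed(41)
  m <- random_trait_matrix(12, 4)
  dirs <- random_directions(4)
  fit <- siig(m, directions = dirs)
  rn <- normalize_traits(m)
  d <- ideal_distances(rn, ideal_profiles(rn, dirs))
  expect_equal(unname(fit$scores), unname(siig_scores(d)$siig),
               tolerance = 1e-15)
})

test_that("grain-filling period is maturity minus heading", {
  expect_equal(derive_gfp(dhe = 101, dma = 134), 33)
  expect_equal(derive_gfp(dhe = 99, dma = 138), 39)
  expect_equal(derive_gfp(dhe = 100, dma = 100), 0)
  expect_error(derive_gfp(dhe = c(a = 90, b = 120), dma = c(a = 130, b = 110)),
               "b")
  expect_error(derive_gfp(dhe = 1:3, dma = 1:2), "length")
})

test_that("siig object methods expose scores, table, and printing", {
  fit <- siig(fixture_trait_matrix())
  expect_s3_class(fit, "siig")
  expect_equal(coef(fit), fit$scores)
  df <- as.data.frame(fit)
  expect_named(df, c("genotype", "d_plus", "d_minus", "siig", "rank"))
  expect_equal(nrow(df), 111L)
  expect_output(print(fit), "111 genotypes x 6 traits")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.siig")
  expect_output(print(sm), "Leading genotypes")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, type = "distances"))
})
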