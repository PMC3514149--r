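# Differential expression: size factors, mean-variance trend, exact
# conditional test, BH adjustment, dual cut-off calling.

test_that("size factors: symmetry, forced two-sample case, brute-force oracle", {
  # identical columns -> all factors 1
  m <- matrix(rpois(40, 30) + 1L, 10, 4)
  m <- m[, c(1, 1, 1, 1)]
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # column 2 = 2 x column 1 -> (1/sqrt(2), sqrt(2))
  m2 <- cbind(c(10L, 25L, 40L), c(20L, 50L, 80L))
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # random positive matrix vs an independent median-of-ratios computation
  # written out longhand (odd gene count so the median is a data point)
  set.seed(5)
  m3 <- matrix(rpois(51 * 4, 100) + 1L, 51, 4)
  sf <- estimate_size_factors(m3)
  geo <- apply(m3, 1, function(r) prod(r)^(1 / length(r)))
  oracle <- apply(m3, 2, function(col) median(col / geo))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-9)
})

test_that("size factors: equivariance under per-sample scaling and degenerate input", {
  set.seed(11)
  m <- matrix(rpois(60 * 5, 80) + 1L, 60, 5)
  sf1 <- estimate_size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  sf2 <- estimate_size_factors(m2)
  # scaling one column by c multiplies its factor by c relative to the rest
  rel <- (sf2 / sf1)
  expect_equal(unname(rel[3] / rel[1]), 4, tolerance = 1e-9)

  # every row contains a zero -> unidentifiable
  bad <- diag(5L)
  expect_error(estimate_size_factors(bad), "unidentifiable")
})

test_that("size factors agree with the DESeq2 reference up to its lack of rescaling", {
  set.seed(21)
  m <- matrix(rnbinom(200 * 6, mu = 150, size = 5) + 1L, 200, 6)
  sf <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ratio <- sf / ref
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("mean-variance trend recovers Poisson and NB regimes", {
  # near-Poisson counts: fitted variance at m = 100 close to 100
  sim <- simulate_counts(5000, de_fraction = 0, dispersion = 0,
                         depth_factors = rep(1, 6), seed = 2)
  sf <- estimate_size_factors(sim$counts)
  fit <- fit_dispersion(sim$counts, sf, sim$condition)
  expect_gte(predict(fit, 100) / 100, 0.9)
  expect_lte(predict(fit, 100) / 100, 1.3)

  # NB dispersion 0.1: implied dispersion at m = 1000 within [0.07, 0.13]
  sim2 <- simulate_counts(5000, de_fraction = 0, dispersion = 0.1,
                          depth_factors = rep(1, 6), seed = 2)
  sf2 <- estimate_size_factors(sim2$counts)
  fit2 <- fit_dispersion(sim2$counts, sf2, sim2$condition)
  d_hat <- dispersion_at(fit2, 1000)
  expect_gte(d_hat, 0.07)
  expect_lte(d_hat, 0.13)

  # fitted variance is monotone and floored at the mean
  grid <- exp(seq(log(1), log(5000), length.out = 60))
  v <- predict(fit2, grid)
  expect_true(all(diff(v) >= -1e-9))
  expect_true(all(v >= grid))
})

test_that("replicate-constant counts degenerate to the Poisson floor", {
  m <- cbind(a1 = rep(50L, 20), a2 = rep(50L, 20), a3 = rep(50L, 20),
             b1 = rep(80L, 20), b2 = rep(80L, 20), b3 = rep(80L, 20))
  cond <- factor(rep(c("A", "B"), each = 3))
  sf <- rep(1, 6)
  fit <- fit_dispersion(m, sf, cond)
  expect_true(all(fit$table$raw_variance == 0))
  expect_equal(predict(fit, c(10, 200)), c(10, 200))
})

test_that("exact conditional test: conventions and brute-force enumeration", {
  sf <- rep(1, 6)
  vf <- function(m) m + 0.05 * m^2
  expect_equal(nb_test(c(50, 50, 50), c(50, 50, 50), sf[1:3], sf[4:6], vf), 1)
  expect_equal(nb_test(c(0, 0, 0), c(0, 0, 0), sf[1:3], sf[4:6], vf), 1)

  p <- nb_test(c(5, 6, 4), c(40, 38, 45), sf[1:3], sf[4:6], vf)
  p_oracle <- bruteforce_split_p(c(5, 6, 4), c(40, 38, 45),
                                 sf[1:3], sf[4:6], vf)
  expect_equal(p, p_oracle, tolerance = 1e-12)
  expect_lt(p, 1e-6)

  # property: exact agreement with enumeration for random genes, K <= 500,
  # including unequal size factors
  set.seed(42)
  for (i in 1:20) {
    ca <- rpois(3, sample(5:60, 1))
    cb <- rpois(3, sample(5:60, 1))
    sfa <- runif(3, 0.7, 1.4)
    sfb <- runif(3, 0.7, 1.4)
    d <- runif(1, 0.01, 0.3)
    vfun <- function(m) m + d * m^2
    expect_equal(nb_test(ca, cb, sfa, sfb, vfun),
                 bruteforce_split_p(ca, cb, sfa, sfb, vfun),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment: hand-computed case and edge cases", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  # order-preserving and never below raw
  set.seed(8)
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_len(50))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
})

test_that("dual cut-off calling gates on both adjusted P and fold", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                    fold_change = c(1.4, 3.0, 2.69, 0.2, NA),
                    padj = c(0.04, 0.06, 0.018, 0.001, 0.001))
  out <- call_de(tab, alpha = 0.05, min_fold = 1.5)
  expect_equal(out$table$significant, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$table$direction[3], "up-in-B")
  expect_equal(out$table$direction[4], "up-in-A")
  expect_equal(out$up_in_b, "g3")
  expect_equal(out$up_in_a, "g4")
})

test_that("fold change reproduces printed ratios and handles sentinels", {
  expect_equal(round(fold_change(363.6, 976.7), 2), 2.69)
  expect_equal(round(fold_change(3014.8, 620.9), 2), 0.21)
  expect_equal(fold_change(5, 5), 1)
  expect_identical(fold_change(0, 3), Inf)
  expect_true(is.na(fold_change(0, 0)))
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("dge_test is internally consistent on a planted simulation", {
  sim <- simulate_counts(400, de_fraction = 0.15, seed = 31)
  res <- dge_test(sim$counts, sim$condition)
  tab <- res$table
  expect_equal(nrow(tab), 400)
  expect_true(all(tab$pvalue > 0 & tab$pvalue <= 1))
  expect_true(all(tab$padj >= tab$pvalue))
  expect_equal(sum(tab$significant),
               length(res$up_in_a) + length(res$up_in_b))
  # directions match fold changes
  expect_true(all(tab$fold_change[tab$direction == "up-in-B"] > 1))
  expect_true(all(tab$fold_change[tab$direction == "up-in-A"] < 1))
  # printing works
  expect_output(print(res), "significant")
})
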