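# 3-point chain at x = 0, 1, 2 m with threshold 1 m: neighbor pairs
# {1-2, 2-3} only. Raw values (1, 1, 3) center to z = (-2/3, -2/3, 4/3)
# with second moment m = sum(z^2)/N = 8/9.
chain <- function() {
  w <- build_weights(c(0, 1, 2), c(0, 0, 0), threshold = 1)
  v <- c(1, 1, 3)
  list(w = w, z = v - mean(v))
}

test_that("distance-band weights enumerate neighbor pairs and S0", {
  ch <- chain()
  expect_equal(ch$w$neighbors, list(2L, c(1L, 3L), 2L))
  expect_equal(ch$w$S0, 4)
  expect_true(all(weights_matrix(ch$w) == t(weights_matrix(ch$w))))
  expect_error(build_weights(c(0, 10), c(0, 0), threshold = 1), "isolated")
  expect_warning(w2 <- build_weights(c(0, 1, 10), c(0, 0, 0), threshold = 1),
                 "isolated")
  expect_true(w2$isolated[3])
})

test_that("inverse-distance weights equal 1/d within the band", {
  w <- build_weights(c(0, 1, 2), c(0, 0, 0), threshold = 2,
                     style = "inverse_distance")
  expect_equal(w$weights[[1]], c(1, 0.5))
  expect_equal(w$weights[[2]], c(1, 1))
})

test_that("local Moran reproduces the hand-derived chain values", {
  ch <- chain()
  res <- local_moran(ch$z, ch$w)
  expect_equal(res$I, c(0.5, -0.5, -1.0))
  expect_equal(res$lag, c(-2/3, 2/3, -2/3))
  expect_equal(res$quadrant, c("LL", "LH", "HL"))
  expect_error(local_moran(ch$z[1:2], ch$w), "length")
})

test_that("sum of local statistics equals S0 times brute-force global Moran", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(10:40, 1)
    x <- runif(n, 0, 10); y <- runif(n, 0, 10)
    v <- rnorm(n)
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    w <- suppressWarnings(build_weights(x, y, threshold = 4))
    if (any(w$isolated)) next
    res <- local_moran(z, w)
    expect_equal(sum(res$I), w$S0 * global_moran_brute(z, weights_matrix(w)),
                 tolerance = 1e-10)
  }
})

test_that("local Moran is invariant to point ordering", {
  set.seed(7)
  x <- runif(30); y <- runif(30); z <- rnorm(30); z <- z - mean(z)
  w <- build_weights(x, y, threshold = 0.4)
  res <- local_moran(z, w)
  ord <- sample(30)
  w2 <- build_weights(x[ord], y[ord], threshold = 0.4)
  res2 <- local_moran(z[ord], w2)
  expect_equal(res2$I[order(ord)], res$I)
})

test_that("quadrant labels survive positive rescaling of weight rows", {
  set.seed(12)
  x <- runif(40); y <- runif(40); z <- rnorm(40); z <- z - mean(z)
  w <- build_weights(x, y, threshold = 0.5)
  q1 <- local_moran(z, w)$quadrant
  w$weights <- lapply(w$weights, function(wi) wi * runif(1, 0.1, 10))
  q2 <- local_moran(z, w)$quadrant
  expect_equal(q2, q1)
})

test_that("pseudo p-values are bounded, seeded and attain their floor", {
  ch <- chain()
  p <- permutation_pvalues(ch$z, ch$w, n_permutations = 99, seed = 3,
                           sided = "folded")
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_identical(p, permutation_pvalues(ch$z, ch$w, 99, seed = 3,
                                          sided = "folded"))
  expect_false(identical(p, permutation_pvalues(ch$z, ch$w, 99, seed = 4,
                                                sided = "folded")))
  # two spatially separated cliques of opposite extreme values: the folded
  # floor (0+1)/1000 and the two-sided floor 2/1000 are both attained
  set.seed(20)
  x <- c(runif(20, 0, 1), runif(20, 9, 10))
  y <- runif(40, 0, 1)
  v <- c(rep(5, 20), rep(-5, 20)) + rnorm(40, 0, 0.01)
  z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  w <- build_weights(x, y, threshold = 2)
  expect_true(any(permutation_pvalues(z, w, 999, seed = 5,
                                      sided = "folded") == 0.001))
  expect_true(any(permutation_pvalues(z, w, 999, seed = 5) == 0.002))
})

test_that("two-sided pseudo p-values match the nominal level under the null", {
  # flagged fraction at alpha = 0.05 over pooled replicates stays near 0.05
  # for the calibrated default and near 2 x 0.05 for the folded variant
  flag2 <- flagf <- n_tot <- 0
  for (r in 1:10) {
    set.seed(800 + r)
    x <- runif(150, 0, 15); y <- runif(150, 0, 15)
    v <- rnorm(150)
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    w <- suppressWarnings(build_weights(x, y, threshold = 1.75))
    ok <- !w$isolated
    p2 <- permutation_pvalues(z, w, 499, seed = 800 + r)
    pf <- permutation_pvalues(z, w, 499, seed = 800 + r, sided = "folded")
    flag2 <- flag2 + sum(p2[ok] <= 0.05)
    flagf <- flagf + sum(pf[ok] <= 0.05)
    n_tot <- n_tot + sum(ok)
  }
  expect_lt(abs(flag2 / n_tot - 0.05), 0.02)
  expect_gt(flagf / n_tot, flag2 / n_tot)
})

test_that("Monte Carlo pseudo p matches the exhaustive conditional oracle", {
  set.seed(33)
  x <- c(0, 1, 2, 1, 0.5, 1.5)
  y <- c(0, 0, 0, 1, 0.6, 0.6)
  v <- rnorm(6)
  z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  w <- build_weights(x, y, threshold = 1.1)
  M <- 4999
  p_mc <- permutation_pvalues(z, w, M, seed = 8, sided = "folded")
  for (i in seq_along(z)) {
    f <- exact_cond_fraction(z, w, i)
    tol <- 4 * sqrt(f * (1 - f) / M) + 2 / M
    expect_equal(p_mc[i], f, tolerance = max(tol / max(f, 1e-12), 0.02))
  }
})

test_that("classification applies the alpha rule with NS fallback", {
  lisa <- data.frame(I = c(1, -1, 2), lag = c(1, 1, -1),
                     quadrant = c("HH", "LH", "HL"))
  out <- classify_lisa(lisa, c(0.001, 0.011, NA), alpha = 0.01)
  expect_equal(out$class, c("HH", "NS", "NS"))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  all_in <- classify_lisa(lisa, c(0.5, 0.9, 1.0), alpha = 1.0)
  expect_equal(all_in$class, lisa$quadrant)
  # boundary: exactly alpha is significant
  expect_true(classify_lisa(lisa[1, ], 0.01, alpha = 0.01)$significant)
})

test_that("scatterplot slope with row-standardized weights equals global Moran", {
  for (s in 1:20) {
    set.seed(s + 500)
    n <- sample(15:35, 1)
    x <- runif(n, 0, 8); y <- runif(n, 0, 8)
    v <- rnorm(n)
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    w <- suppressWarnings(build_weights(x, y, threshold = 4))
    if (any(w$isolated)) next
    sc <- moran_scatterplot_data(z, w, row_standardize = TRUE)
    slope <- unname(coef(lm(sc$lag ~ sc$z))[2])
    Wr <- weights_matrix(w)
    Wr <- Wr / rowSums(Wr)
    expect_equal(slope, global_moran_brute(z, Wr), tolerance = 1e-8)
  }
})

test_that("scatterplot quadrants mirror the chain signs", {
  ch <- chain()
  sc <- moran_scatterplot_data(ch$z, ch$w, row_standardize = FALSE)
  expect_equal(sign(sc$z), c(-1, -1, 1))
  expect_equal(sign(sc$lag), c(-1, 1, -1))
  expect_equal(sc$quadrant, c("LL", "LH", "HL"))
})

test_that("run_lisa drops outliers first and reports isolated points as NS", {
  set.seed(9)
  plants <- data.frame(plant_id = 1:21,
                       x = c(runif(20, 0, 3), 50), y = c(runif(20, 0, 3), 50),
                       z = rnorm(21), outlier = c(rep(FALSE, 20), FALSE))
  plants$z <- plants$z - mean(plants$z)
  res <- suppressWarnings(run_lisa(plants, threshold = 2, n_permutations = 99,
                                   seed = 2))
  expect_equal(nrow(res), 21)
  expect_equal(res$class[21], "NS")
  expect_true(is.na(res$pseudo_p[21]))
  plants$outlier[1] <- TRUE
  res2 <- suppressWarnings(run_lisa(plants, threshold = 2, n_permutations = 99,
                                    seed = 2))
  expect_equal(nrow(res2), 20)
})
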