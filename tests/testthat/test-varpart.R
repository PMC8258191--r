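test_that("circular date predictor lies on the unit circle", {
  p <- circular_date_predictor(c(91, 365))
  expect_equal(unname(p[1, ]), c(sin(2 * pi * 91 / 365), cos(2 * pi * 91 / 365)))
  expect_equal(unname(p[1, "doy_sin"]), 1, tolerance = 1e-4)
  expect_equal(unname(p[1, "doy_cos"]), 0.0043, tolerance = 2e-3)
  expect_equal(unname(p[2, ]), c(0, 1), tolerance = 1e-12)
  expect_true(all(abs(rowSums(p^2) - 1) < 1e-12))
  expect_error(circular_date_predictor(0), "366")
  expect_error(circular_date_predictor(400), "366")
})

test_that("the year boundary is seasonally continuous", {
  sept <- circular_date_predictor(266)  # late September
  aug <- circular_date_predictor(238)   # late August, nominally 'a year apart'
  apr <- circular_date_predictor(100)
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(d(sept, aug), d(sept, apr))
})

test_that("RDA R2 spans its extremes and the Ezekiel penalty", {
  set.seed(21)
  X <- cbind(rnorm(12), rnorm(12))
  B <- matrix(rnorm(2 * 4), 2)
  Y <- X %*% B                      # exactly linear in X
  fit <- rda_adjusted_r2(Y, X)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # response orthogonal to the centred predictor space
  Xc <- scale(X, scale = FALSE)
  E <- matrix(rnorm(12 * 3), 12)
  E <- E - Xc %*% solve(crossprod(Xc), crossprod(Xc, E))
  E <- scale(E, scale = FALSE)
  fit0 <- rda_adjusted_r2(E, X)
  expect_equal(fit0$r2, 0, tolerance = 1e-10)
  expect_lt(fit0$adj_r2, 0)

  # Ezekiel formula with n = 24, m = 2 applied to the measured R2
  set.seed(22)
  Y24 <- matrix(rnorm(24 * 5), 24)
  X24 <- cbind(rnorm(24), rnorm(24))
  f <- rda_adjusted_r2(Y24, X24)
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * 23 / 21, tolerance = 1e-12)
  expect_equal(1 - (1 - 0.5) * 23 / 21, 0.452381, tolerance = 1e-6)
})

test_that("RDA agrees with vegan and honours rank deficiency", {
  skip_if_not_installed("vegan")
  set.seed(23)
  Y <- hellinger_transform(matrix(rexp(24 * 6), 24))
  X <- circular_date_predictor(rep(seq(15, 350, length.out = 8), 3))
  ours <- rda_adjusted_r2(Y, X)
  ref <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(ours$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(ours$adj_r2, ref$adj.r.squared, tolerance = 1e-10)

  # duplicated predictor column: rank reduced, same fit, warning
  expect_warning(dup <- rda_adjusted_r2(Y, cbind(X, X[, 1])), "rank")
  expect_equal(dup$r2, ours$r2, tolerance = 1e-12)
  expect_equal(dup$rank, 2)
})

test_that("variation partitioning identities hold exactly", {
  set.seed(24)
  Y <- hellinger_transform(matrix(rexp(24 * 7), 24))
  station <- rep(c("C", "B", "T"), each = 8)
  doy <- rep(seq(10, 350, length.out = 8), 3)
  vp <- variation_partition(Y, station, doy)
  f <- vp$fractions
  expect_equal(unname(f["a"] + f["b"] + f["c"] + f["d"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["a"]), vp$adj_combined - vp$adj_station, tolerance = 1e-12)
  expect_equal(unname(f["c"]), vp$adj_combined - vp$adj_date, tolerance = 1e-12)
  expect_equal(unname(f["b"]),
               vp$adj_date + vp$adj_station - vp$adj_combined, tolerance = 1e-12)
})

test_that("any full-rank coding of the station factor gives the same fractions", {
  set.seed(25)
  Y <- matrix(rnorm(18 * 4), 18)
  station <- factor(rep(c("C", "B", "T"), each = 6))
  doy <- rep(seq(20, 340, length.out = 6), 3)
  X <- circular_date_predictor(doy)
  treatment <- stats::model.matrix(~ station)[, -1]
  helmert <- stats::model.matrix(~ station,
    contrasts.arg = list(station = "contr.helmert"))[, -1]
  v1 <- variation_partition(Y, station, X)
  # feed the alternative coding through the matrix interface
  adj_s1 <- rda_adjusted_r2(Y, treatment)$adj_r2
  adj_s2 <- rda_adjusted_r2(Y, helmert)$adj_r2
  expect_equal(adj_s1, adj_s2, tolerance = 1e-10)
  expect_equal(v1$adj_station, adj_s1, tolerance = 1e-10)
})

test_that("variation partitioning matches vegan::varpart", {
  skip_if_not_installed("vegan")
  set.seed(26)
  Y <- hellinger_transform(matrix(rexp(24 * 6), 24))
  station <- factor(rep(c("C", "B", "T"), each = 8))
  doy <- rep(seq(10, 350, length.out = 8), 3)
  X <- circular_date_predictor(doy)
  vp <- variation_partition(Y, station, X)
  S <- stats::model.matrix(~ station)[, -1]
  ref <- vegan::varpart(Y, X, S)$part$indfract$Adj.R.square
  # vegan lists unique-date, unique-station, shared, residual
  expect_equal(unname(vp$fractions[c("a", "c", "b", "d")]), ref, tolerance = 1e-8)
})

test_that("a purely seasonal response yields no unique station fraction", {
  set.seed(27)
  cvals <- numeric(100); avals <- numeric(100)
  station <- factor(rep(c("C", "B", "T"), each = 8))
  doy <- rep(seq(10, 350, length.out = 8), 3)
  X <- circular_date_predictor(doy)
  for (r in 1:100) {
    B <- matrix(rnorm(2 * 5), 2)
    Y <- X %*% B + matrix(rnorm(24 * 5, sd = 0.3), 24)
    vp <- variation_partition(Y, station, X)
    avals[r] <- vp$fractions["a"]
    cvals[r] <- vp$fractions["c"]
  }
  expect_true(all(avals > 0))
  expect_lt(mean(abs(cvals)), 0.05)
})

test_that("pure noise explains (almost) nothing after adjustment", {
  set.seed(28)
  station <- factor(rep(c("C", "B", "T"), each = 8))
  doy <- rep(seq(10, 350, length.out = 8), 3)
  X <- circular_date_predictor(doy)
  # noise matrix at the study size: 24 samples x 28 taxa
  small <- logical(200)
  for (r in 1:200) {
    Y <- matrix(rnorm(24 * 28), 24)
    f <- variation_partition(Y, station, X)$fractions
    small[r] <- all(f[c("a", "b", "c")] <= 0.05)
  }
  expect_gte(mean(small), 0.95)
})

test_that("confounded predictors do not error", {
  # date fully nested in station: every station sampled on its own date
  set.seed(29)
  station <- factor(rep(c("C", "B", "T"), each = 4))
  doy <- rep(c(50, 150, 250), each = 4)
  Y <- matrix(rnorm(12 * 3), 12)
  expect_no_error(vp <- variation_partition(Y, station, doy))
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-12)
})
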