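# Estimator validation against series with known properties.  The noisy
# sine stands in for a measured limit cycle (histogram AMI of a noiseless
# digitised sine is degenerate); the strictly periodic sine is kept for the
# geometric checks where exact repetition is the point.

noisy_sine <- function(n = 5000, period = 100, sd = 0.1, seed = 11) {
  withr::with_seed(seed, sin(2 * pi * (1:n) / period) + rnorm(n, 0, sd))
}

test_that("AMI delay finds the quarter period of an oscillation", {
  a <- ami_delay(noisy_sine(), max_lag = 60)
  expect_s3_class(a, "ami_delay")
  expect_gte(a$delay, 23)
  expect_lte(a$delay, 27)
  expect_false(a$fallback)
})

test_that("AMI delay of independent noise is 1, and constants error", {
  u <- withr::with_seed(1, runif(1e5))
  a <- ami_delay(u, max_lag = 30)
  expect_equal(a$delay, 1L)
  expect_true(all(a$ami < 0.05))
  expect_error(ami_delay(rep(1, 1000)), "constant")
})

test_that("FNN selects the attractor dimension of canonical systems", {
  x <- sin(2 * pi * (1:4000) / 100)
  expect_equal(fnn_dimension(x, delay = 25)$dimension, 2L)
  h <- henon_map(a = 1.4, b = 0.3, n = 10000, seed = 1)$values
  expect_equal(fnn_dimension(h, delay = 1)$dimension, 2L)
  lz <- lorenz_series(n = 5000)$values
  expect_equal(fnn_dimension(lz, delay = 17)$dimension, 3L)
  expect_error(fnn_dimension(x[1:30], delay = 25), "short")
})

test_that("correlation sums match a brute-force all-pairs oracle", {
  x <- henon_map(n = 1500, seed = 2)$values
  emb <- embed_delay(x, 1, 2)
  radii <- exp(seq(log(0.01), log(2), length.out = 12))
  fast <- hippoflow:::corr_count_cpp(emb, radii, 3L)
  d <- as.matrix(dist(emb))
  lag <- abs(row(d) - col(d))
  oracle <- vapply(radii, function(r)
    sum(d < r & lag > 3 & upper.tri(d)), 0)
  expect_equal(as.numeric(fast), oracle)
})

test_that("correlation dimension recovers known geometries", {
  un <- withr::with_seed(2, runif(12000))
  d2n <- correlation_dimension(un, embedding_params(1, 2, theiler = 10))
  expect_lt(abs(d2n$value - 2), 0.15)
  h <- henon_map(n = 10000, seed = 1)$values
  d2h <- correlation_dimension(h, embedding_params(1, 2, theiler = 10))
  expect_gte(d2h$value, 1.1)
  expect_lte(d2h$value, 1.3)
  xi <- sin(2 * pi * (1:6000) / 103.7)
  d2s <- correlation_dimension(xi, embedding_params(26, 2, theiler = 110))
  expect_lt(abs(d2s$value - 1), 0.1)
  # sanity: D2 never exceeds the embedding dimension (beyond tolerance)
  expect_lte(d2n$value, 2.2)
})

test_that("recurrence entropy is exact on constructed histograms", {
  expect_equal(histogram_entropy(c(8)), 0)        # single class
  expect_equal(histogram_entropy(c(8, 8)), 1)     # two equal classes: 1 bit
  expect_equal(histogram_entropy(c(2, 1, 1)), 1.5)
  expect_equal(histogram_entropy(numeric(0)), 0)
  expect_gte(histogram_entropy(c(5, 3, 9, 1)), 0)
})

test_that("white noise carries more recurrence entropy than a pure tone", {
  xp <- sin(2 * pi * (1:4000) / 100)
  rs <- rqa_entropy(xp, embedding_params(25, 2, theiler = 100))
  wn <- withr::with_seed(3, runif(4000))
  rn <- rqa_entropy(wn, embedding_params(1, 2, theiler = 10))
  expect_lt(abs(rs$recurrence_rate - 0.1), 0.05)
  expect_lt(abs(rn$recurrence_rate - 0.1), 0.01)
  expect_gt(rn$entropy, rs$entropy)
  expect_error(rqa_entropy(rep(1, 500), embedding_params(1, 2)), "degenerate")
})

test_that("the Lyapunov estimator matches analytic map exponents", {
  lg <- logistic_map(4, 0.3, 5000)
  ly <- max_lyapunov(lg$values, embedding_params(1, 2, theiler = 5))
  expect_lt(abs(ly$value - log(2)) / log(2), 0.1)
  # stable period-2 regime: contraction, negative exponent
  lp <- logistic_map(3.2, 0.3, 5000)
  ly2 <- max_lyapunov(lp$values, embedding_params(1, 2, theiler = 5))
  expect_lt(ly2$value, 0)
  # limit cycle: no divergence
  x <- sin(2 * pi * (1:4000) / 100)
  lys <- max_lyapunov(x, embedding_params(25, 2, theiler = 100))
  expect_lte(lys$value, 0.01)
})

test_that("complexity measures are invariant under amplitude scaling", {
  h <- henon_map(n = 4000, seed = 4)$values
  for (c_scale in c(0.2, 5)) {
    emb <- embedding_params(1, 2, theiler = 10)
    a <- correlation_dimension(h, emb)$value
    b <- correlation_dimension(c_scale * h, emb)$value
    expect_equal(a, b, tolerance = 1e-8)
    la <- max_lyapunov(h, emb)$value
    lb <- max_lyapunov(c_scale * h, emb)$value
    expect_equal(la, lb, tolerance = 1e-6)
    da <- ami_delay(h, max_lag = 20)$delay
    db <- ami_delay(c_scale * h, max_lag = 20)$delay
    expect_equal(da, db)
  }
})

test_that("shuffled surrogates fill the embedding space", {
  h <- henon_map(n = 6000, seed = 5)$values
  sur <- withr::with_seed(6, sample(h))
  emb <- embedding_params(1, 2, theiler = 10)
  d2_orig <- correlation_dimension(h, emb)$value
  d2_sur <- correlation_dimension(sur, emb)$value
  expect_gt(d2_sur, d2_orig)     # closer to the embedding dimension
  expect_gt(d2_sur, 1.6)
})

test_that("automatic embedding choice combines AMI and FNN", {
  ep <- choose_embedding(noisy_sine(3000), max_lag = 40, max_dim = 5)
  expect_s3_class(ep, "embedding_params")
  expect_gte(ep$delay, 1)
  expect_gte(ep$dimension, 2)
  expect_equal(ep$theiler, ep$delay * ep$dimension)
})
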