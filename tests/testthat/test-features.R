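test_that("ApEn of a constant sequence is zero", {
  expect_equal(approximate_entropy(rep(2.5, 50)), 0)
})

test_that("ApEn matches the brute-force double-loop oracle", {
  x <- rep(c(1, 2), 6) # the 12-point alternating sequence
  expect_equal(approximate_entropy(x, m = 2, r = 0.5),
               apen_bruteforce(x, m = 2, r = 0.5), tolerance = 1e-12)
  set.seed(42)
  for (n in c(10, 17, 23, 30)) {
    y <- runif(n)
    r <- 0.2 * stats::sd(y)
    expect_equal(approximate_entropy(y, m = 2, r = r),
                 apen_bruteforce(y, m = 2, r = r), tolerance = 1e-12)
    expect_equal(approximate_entropy(y, m = 3, r = r),
                 apen_bruteforce(y, m = 3, r = r), tolerance = 1e-12)
  }
})

test_that("ApEn with an SD-relative radius is invariant to affine rescaling", {
  set.seed(7)
  x <- runif(60)
  expect_equal(approximate_entropy(x), approximate_entropy(3 * x + 5),
               tolerance = 1e-10)
})

test_that("a periodic sequence has lower ApEn than its random permutations", {
  x <- as.vector(generate_archetype(0, 1, 300, seed = 9))
  ap_x <- approximate_entropy(x)
  set.seed(10)
  ap_perm <- replicate(20, approximate_entropy(sample(x)))
  expect_lt(ap_x, mean(ap_perm))
})

test_that("sequences too short for the embedding are rejected", {
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("the coefficient of variation matches hand arithmetic", {
  x <- c(2, 4, 6, 8)
  # sample sd: deviations (-3,-1,1,3), ss = 20, sd = sqrt(20/3); mean = 5
  expect_equal(dispersion_feature(x), sqrt(20 / 3) / 5, tolerance = 1e-14)
  expect_equal(dispersion_feature(x, sd_type = "population"),
               sqrt(20 / 4) / 5, tolerance = 1e-14)
})

test_that("cv is scale-invariant but translation-sensitive; lag-1 autocovariance the reverse", {
  set.seed(3)
  x <- runif(40, 1, 2)
  expect_equal(dispersion_feature(x), dispersion_feature(2 * x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dispersion_feature(x), dispersion_feature(x + 1))))
  expect_equal(dispersion_feature(x, "lag1_autocov"),
               dispersion_feature(x + 5, "lag1_autocov"), tolerance = 1e-12)
})

test_that("degenerate dispersion inputs behave per contract", {
  expect_equal(dispersion_feature(rep(4, 10)), 0)
  expect_equal(dispersion_feature(rep(4, 10), "lag1_autocov"), 0)
  expect_error(dispersion_feature(c(-1, 1)), "mean is zero")
  expect_error(dispersion_feature(3), "at least 2")
})

test_that("lag-1 autocovariance matches its defining sum", {
  x <- c(1, 3, 2, 5)
  xc <- x - mean(x)
  expect_equal(dispersion_feature(x, "lag1_autocov"),
               mean(xc[1:3] * xc[2:4]), tolerance = 1e-14)
})

test_that("fusion widths follow the four ablation configurations", {
  set.seed(5)
  code <- matrix(runif(30), 3, 10)
  feats <- data.frame(cov = c(0.1, 0.2, 0.3), apen = c(1, 2, 3))
  sc <- fit_scaler(feats, method = "minmax")
  expect_equal(ncol(fuse_features(code, feats, sc, FALSE, FALSE)), 10L)
  expect_equal(ncol(fuse_features(code, feats, sc, TRUE, FALSE)), 11L)
  expect_equal(ncol(fuse_features(code, feats, sc, FALSE, TRUE)), 11L)
  expect_equal(ncol(fuse_features(code, feats, sc, TRUE, TRUE)), 12L)
})

test_that("with an identity scaler the fused tail is (cov, apen) verbatim", {
  code <- matrix(0.5, 2, 4)
  feats <- data.frame(cov = c(0.7, 0.9), apen = c(1.1, 1.3))
  sc <- fit_scaler(feats, method = "none")
  fused <- fuse_features(code, feats, sc)
  expect_equal(fused[, 5:6], as.matrix(feats), ignore_attr = TRUE)
})

test_that("an unfitted scaler is rejected", {
  code <- matrix(0.5, 2, 4)
  feats <- data.frame(cov = c(0.7, 0.9), apen = c(1.1, 1.3))
  expect_error(fuse_features(code, feats, NULL), "scaler not fitted")
  expect_error(apply_scaler(as.matrix(feats), structure(list(fitted = FALSE),
                                                        class = "feature_scaler")),
               "scaler not fitted")
})

test_that("min-max scaling is fitted on the training set and frozen", {
  train <- data.frame(cov = c(0, 1), apen = c(2, 4))
  sc <- fit_scaler(train, "minmax")
  out <- apply_scaler(matrix(c(0.5, 2, 3, 6), 2, byrow = FALSE), sc)
  expect_equal(out[, 1], c(0.5, 2))   # cov column: (x - 0)/1
  expect_equal(out[, 2], c(0.5, 2))   # apen column: (x - 2)/2
})
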