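test_that("uniform combination reproduces the closed-form special cases", {
  expect_equal(as.numeric(uniformCombination(3 + 0i, 3 + 0i)), 0.5)
  expect_equal(as.numeric(uniformCombination(2, -2)), -0.5)
  expect_equal(as.numeric(uniformCombination(0 + 0i, 1 + 0i)), 0)
  # 0/0 voxels come back as 0 with the degenerate flag, never NaN
  u <- uniformCombination(c(0 + 0i, 1 + 0i), c(0 + 0i, 1 + 0i))
  expect_equal(as.numeric(u), c(0, 0.5))
  expect_equal(attr(u, "degenerate"), c(TRUE, FALSE))
})

test_that("robust combination matches hand evaluation and its limits", {
  expect_equal(as.numeric(robustCombination(1, 2, beta = 1)), 1 / 7)
  for (b in c(1e-6, 0.5, 1e6))
    expect_identical(as.numeric(robustCombination(0 + 0i, 0 + 0i, beta = b)), -0.5)
  expect_error(robustCombination(1, 2, beta = -1), "nonnegative")

  # beta = 0 reduces exactly to the uniform combination
  s <- randomSignals(1e4, seed = 5)
  expect_equal(as.numeric(robustCombination(s$s1, s$s2, beta = 0)),
               as.numeric(uniformCombination(s$s1, s$s2)), tolerance = 1e-12)
})

test_that("both combinations stay within [-0.5, 0.5] on random input", {
  s <- randomSignals(2e5, seed = 9)
  for (b in c(0, 1e-6, 1, 1e4)) {
    v <- as.numeric(robustCombination(s$s1, s$s2, beta = b))
    expect_true(all(abs(v) <= 0.5 + 1e-12))
  }
})

test_that("the uniform ratio is self-bias-correcting; beta sets the scale", {
  s <- randomSignals(2e4, seed = 13)
  set.seed(14)
  cf <- complex(modulus = 10^runif(2e4, -1, 1), argument = runif(2e4, -pi, pi))
  expect_equal(as.numeric(uniformCombination(cf * s$s1, cf * s$s2)),
               as.numeric(uniformCombination(s$s1, s$s2)), tolerance = 1e-12)
  # scaling the signals by c is the same as dividing beta by |c|^2
  beta <- 2.5
  expect_equal(as.numeric(robustCombination(3i * s$s1, 3i * s$s2, beta = beta)),
               as.numeric(robustCombination(s$s1, s$s2, beta = beta / 9)),
               tolerance = 1e-12)
})

test_that("the robust bias shrinks monotonically with signal power", {
  scales <- 2^(0:12)
  s1 <- 0.3 + 0.1i; s2 <- 0.8 - 0.2i
  dev <- vapply(scales, function(k) {
    abs(as.numeric(robustCombination(k * s1, k * s2, beta = 1)) -
        as.numeric(uniformCombination(s1, s2)))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("robustFromMagnitude agrees with the complex-mode computation", {
  expect_equal(robustFromMagnitude(0.2, 1, 2, beta = 1)[[1]], 0)
  expect_identical(robustFromMagnitude(0, 0, 0, beta = 2)[[1]], -0.5)
  expect_error(robustFromMagnitude(0.7, 1, 1, beta = 1), "\\[-0.5, 0.5\\]")

  s <- randomSignals(1e4, seed = 21)
  u <- as.numeric(uniformCombination(s$s1, s$s2))
  m1 <- Mod(s$s1); m2 <- Mod(s$s2)
  for (b in c(0, 3)) {
    expect_equal(as.numeric(robustFromMagnitude(u, m1, m2, beta = b)),
                 as.numeric(robustCombination(s$s1, s$s2, beta = b)),
                 tolerance = 1e-10)
  }
  # beta = 0 returns the uniform volume unchanged where signal exists
  expect_equal(as.numeric(robustFromMagnitude(u, m1, m2, beta = 0)), u)
})

test_that("magnitude-mode pairs reproduce the complex-mode images", {
  tp <- makeTestPair(c(24L, 24L, 24L), seed = 6)
  pair <- tp$pair
  uimg <- uniformCombination(pair)
  mpair <- ComplexVolumePair(Mod(inv1(pair)), Mod(inv2(pair)),
                             uniform = imageData(uimg))
  for (b in c(1e-6, 5e-6)) {
    expect_equal(imageData(robustCombination(mpair, beta = b)),
                 imageData(robustCombination(pair, beta = b)),
                 tolerance = 1e-9)
  }
})

test_that("estimateBeta is zero without noise and linear in the multiplier", {
  ph <- makePhantom(c(24L, 24L, 24L), seed = 2)
  clean <- simulateAcquisition(ph, noise_sigma = 0, seed = 2)
  expect_identical(as.numeric(estimateBeta(clean)), 0)

  noisy <- simulateAcquisition(ph, noise_sigma = 1e-4, seed = 2)
  b1 <- estimateBeta(noisy, multiplier = 100)
  b2 <- estimateBeta(noisy, multiplier = 200)
  expect_gt(as.numeric(b1), 0)
  expect_equal(as.numeric(b2), 2 * as.numeric(b1))

  zero <- ComplexVolumePair(array(0 + 0i, c(8, 8, 8)), array(0 + 0i, c(8, 8, 8)))
  expect_warning(bz <- estimateBeta(zero), "all-zero")
  expect_identical(as.numeric(bz), 0)
})

test_that("the noise-variance estimate is consistent across seeds", {
  ph <- makePhantom(c(48L, 48L, 48L), seed = 3)
  sigma <- 8e-5
  s2hat <- vapply(1:10, function(seed) {
    pr <- simulateAcquisition(ph, noise_sigma = sigma, seed = seed)
    attr(estimateBeta(pr), "sigma2")
  }, numeric(1))
  expect_lt(abs(mean(s2hat) / sigma^2 - 1), 0.15)
})

test_that("betaSweep preserves order and suppresses background monotonically", {
  tp <- makeTestPair(c(32L, 32L, 32L), seed = 4)
  b <- as.numeric(estimateBeta(tp$pair))
  expect_identical(betaSweep(tp$pair, numeric(0)), list())

  sw <- betaSweep(tp$pair, c(0, b / 10, b, 10 * b, b))
  expect_equal(imageData(sw[[1]]), imageData(uniformCombination(tp$pair)))
  expect_identical(imageData(sw[[3]]), imageData(sw[[5]]))  # same beta twice

  bg <- tissueMask(tp$phantom, "background")
  stds <- vapply(sw[c(2, 3, 4)], function(img) backgroundStats(img, bg)$std,
                 numeric(1))
  expect_true(all(diff(stds) < 0))
})
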