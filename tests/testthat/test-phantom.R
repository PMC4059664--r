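test_that("phantom generation is deterministic and well-formed", {
  a <- makePhantom(c(32L, 32L, 32L), seed = 5)
  b <- makePhantom(c(32L, 32L, 32L), seed = 5)
  expect_identical(phantomLabels(a), phantomLabels(b))
  expect_identical(b1PlusMap(a), b1PlusMap(b))
  d <- makePhantom(c(32L, 32L, 32L), seed = 6)
  expect_false(identical(b1PlusMap(a), b1PlusMap(d)))

  expect_error(makePhantom(c(8L, 8L, 8L)), "at least 16")
  expect_error(makePhantom(c(32L, 32L, 32L),
                           tissue_table = defaultTissueTable()[-1, ]),
               "tissue")
  expect_error(tissueMask(a, "bone"), "unknown tissue")
})

test_that("labels partition the volume and every tissue is populated", {
  ph <- makePhantom(c(64L, 64L, 64L), seed = 7)
  bg <- tissueMask(ph, "background")
  expect_false(any(bg & brainMask(ph)))
  counts <- table(phantomLabels(ph))
  expect_setequal(names(counts), as.character(0:4))
  expect_true(all(counts > 0))
  # ground truth is exact: pd = 0 outside the head, positive T1 everywhere
  expect_true(all(phantomPD(ph)[bg] == 0))
  expect_true(all(phantomT1(ph) > 0))
})

test_that("field maps respect strength bounds and brain-mean normalization", {
  expect_equal(makeField(c(16L, 16L, 16L), "b1plus", 0, seed = 1),
               array(1, c(16, 16, 16)))
  f1 <- makeField(c(24L, 24L, 24L), "b1plus", 0.4, seed = 9)
  f2 <- makeField(c(24L, 24L, 24L), "b1plus", 0.4, seed = 9)
  expect_identical(f1, f2)
  expect_gte(min(f1), 0.6)
  expect_lte(max(f1), 1.4)
  expect_gte(max(f1) / min(f1), 1.3)
  expect_equal(mean(f1), 1, tolerance = 1e-12)

  ph <- makePhantom(c(32L, 32L, 32L), seed = 1)
  expect_equal(mean(b1PlusMap(ph)[brainMask(ph)]), 1, tolerance = 1e-12)
  expect_true(all(efficiencyMap(ph) > 0.6 & efficiencyMap(ph) <= 0.96))
})

test_that("simulated noise matches its nominal level; background is pure noise", {
  ph <- makePhantom(c(32L, 32L, 32L), seed = 8)
  clean <- simulateAcquisition(ph, noise_sigma = 0, seed = 8)
  bg <- tissueMask(ph, "background")
  expect_true(all(inv1(clean)[bg] == 0 + 0i))
  expect_true(all(inv2(clean)[bg] == 0 + 0i))

  sigma <- 5e-5
  noisy <- simulateAcquisition(ph, noise_sigma = sigma, seed = 8)
  expect_lt(abs(sd(Re(inv1(noisy)[bg])) / sigma - 1), 0.05)
  expect_lt(abs(sd(Im(inv2(noisy)[bg])) / sigma - 1), 0.05)
  # the two readouts carry independent draws
  expect_lt(abs(cor(Re(inv1(noisy)[bg]), Re(inv2(noisy)[bg]))), 0.05)
})

test_that("the uniform image cancels the receive field exactly", {
  ph <- makePhantom(c(32L, 32L, 32L), seed = 10)
  flat <- ph
  flat@b1minus <- array(1, dim = dim(phantomLabels(ph)))
  u1 <- imageData(uniformCombination(simulateAcquisition(ph, noise_sigma = 0, seed = 1)))
  u2 <- imageData(uniformCombination(simulateAcquisition(flat, noise_sigma = 0, seed = 1)))
  expect_lt(max(abs(u1 - u2)), 1e-10)
})

test_that("poor-inversion regions push the uniform intensity towards +0.5", {
  # emulates the 7T inversion artifact: with failing inversion the two
  # readouts approach each other and the ratio heads to the bright end
  p <- defaultProtocol()
  s_good <- mp2rageSignals(p, t1 = 1.85, efficiency = 0.96)
  s_poor <- mp2rageSignals(p, t1 = 1.85, efficiency = 0.1)
  u_good <- as.numeric(uniformCombination(s_good$s1, s_good$s2))
  u_poor <- as.numeric(uniformCombination(s_poor$s1, s_poor$s2))
  expect_gt(u_poor, u_good)
  expect_gt(u_poor, 0)   # GM flips from dark (-0.22) to artificially bright
})
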