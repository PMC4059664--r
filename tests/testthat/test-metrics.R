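test_that("backgroundStats handles constant and degenerate input", {
  mask <- array(TRUE, c(4, 4, 4))
  st <- backgroundStats(array(-0.5, c(4, 4, 4)), mask)
  expect_equal(st$mean, -0.5)
  expect_equal(st$std, 0)
  # boundary-exclusive interval: a fully collapsed -0.5 background counts as
  # spread, while frac_above flags it as fully suppressed
  expect_equal(st$spread_fraction, 1)
  expect_equal(st$frac_above, 0)
  expect_error(backgroundStats(array(0, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
})

test_that("bias ratio is 1 at beta = 0 and guards the uniform zero-crossing", {
  tp <- makeTestPair(c(24L, 24L, 24L), seed = 12)
  u <- uniformCombination(tp$pair)
  r0 <- robustCombination(tp$pair, beta = 0)
  br <- biasRatio(r0, u, mask = brainMask(tp$phantom),
                  labels = phantomLabels(tp$phantom))
  expect_true(all(abs(br$map[br$valid] - 1) < 1e-12))
  expect_equal(unname(br$summary), rep(1, 3))
  expect_false(any(abs(imageData(u)[br$valid]) <= 1e-3))
  expect_warning(biasRatio(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))),
                 "no valid voxels")
})

test_that("tissue contrast is ordered WM > GM > CSF in both modes", {
  ph <- makePhantom(c(32L, 32L, 32L), seed = 14)
  pair <- simulateAcquisition(ph, noise_sigma = 0, seed = 14)
  masks <- list(CSF = tissueMask(ph, "CSF"), GM = tissueMask(ph, "GM"),
                WM = tissueMask(ph, "WM"))
  for (img in list(uniformCombination(pair),
                   robustCombination(pair, beta = 1e-6))) {
    ct <- tissueContrast(img, masks)
    expect_gt(ct$wm_mean, ct$gm_mean)
    expect_gt(ct$gm_mean, ct$csf_mean)
    expect_gt(ct$gm_wm_separation, 0)
  }
  ct1 <- tissueContrast(uniformCombination(pair), masks)
  ct2 <- tissueContrast(uniformCombination(pair), masks)
  expect_identical(ct1, ct2)
  expect_error(tissueContrast(imageData(uniformCombination(pair)),
                              list(GM = array(FALSE, dim(phantomLabels(ph))),
                                   WM = masks$WM, CSF = masks$CSF)),
               "empty or missing mask")
})

test_that("volumetric reproducibility matches hand computation", {
  r1 <- volumetricReproducibility(c(A = 100), c(A = 110))
  expect_equal(r1$per_structure[["A"]], 100 * 10 / 105)
  expect_equal(r1$worst_case_pct, 100 * 10 / 105)

  r2 <- volumetricReproducibility(c(A = 100, B = 50), c(A = 100, B = 60))
  expect_equal(r2$per_structure[["B"]], 100 * 10 / 55)
  expect_equal(r2$mean_pct, (0 + 100 * 10 / 55) / 2)
  expect_equal(r2$worst_case_pct, 100 * 10 / 55)
})

test_that("reproducibility is symmetric, scale-invariant, and checks structures", {
  v1 <- c(hippocampus = 4100, thalamus = 7300, striatum = 9800)
  v2 <- c(hippocampus = 4350, thalamus = 7100, striatum = 9805)
  a <- volumetricReproducibility(v1, v2)
  b <- volumetricReproducibility(v2, v1)
  expect_equal(a, b)
  k <- volumetricReproducibility(3.7 * v1, 3.7 * v2)
  expect_equal(a$per_structure, k$per_structure)
  expect_error(volumetricReproducibility(v1, v2[-2]), "thalamus")
  # data-frame input (the CSV form) is accepted
  df <- function(v) data.frame(structure = names(v), volume = unname(v))
  expect_equal(volumetricReproducibility(df(v1), df(v2)), a)
})

test_that("labelVolumes respects voxel size", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1, 1] <- 3L
  v <- labelVolumes(lab, voxel_size = c(1, 1, 1.2))
  expect_equal(v[["WM"]], 2 * 1.2)
  expect_equal(v[["CSF"]], 0)
})

test_that("mask baseline blanks low-m2 voxels only", {
  tp <- makeTestPair(c(24L, 24L, 24L), seed = 15)
  u <- uniformCombination(tp$pair)
  m2 <- Mod(inv2(tp$pair))
  expect_equal(imageData(maskBaseline(u, m2, 0)), imageData(u))
  allmask <- maskBaseline(u, m2, Inf)
  expect_true(all(imageData(allmask) == -0.5))
  bg <- tissueMask(tp$phantom, "background")
  thr <- stats::quantile(m2[!bg], 0.01)
  masked <- maskBaseline(u, m2, thr)
  expect_lt(backgroundStats(masked, bg)$std, backgroundStats(u, bg)$std)
})
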