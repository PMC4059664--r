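# Independent brute-force oracle for the steady state: apply the cycle map
# pulse by pulse in an explicit scalar loop (no affine composition, no
# geometric sums), iterating from Mz = 1 until convergence.

applyCycleOnce <- function(mz, protocol, t1, b1plus = 1,
                           efficiency = protocol@inversion_efficiency) {
  g <- gapTimes(protocol)
  relax <- function(mz, t) 1 + (mz - 1) * exp(-t / t1)
  e <- exp(-protocol@tr_readout / t1)
  mz <- -efficiency * mz
  mz <- relax(mz, g[["TA"]])
  c1 <- cos(protocol@alpha1 * pi / 180 * b1plus)
  for (i in seq_len(protocol@n_readout)) mz <- mz * c1 * e + (1 - e)
  mz <- relax(mz, g[["TB"]])
  c2 <- cos(protocol@alpha2 * pi / 180 * b1plus)
  for (i in seq_len(protocol@n_readout)) mz <- mz * c2 * e + (1 - e)
  relax(mz, g[["TC"]])
}

bruteForceMz <- function(protocol, t1, b1plus = 1,
                         efficiency = protocol@inversion_efficiency,
                         iters = 500) {
  mz <- 1
  for (i in seq_len(iters))
    mz <- applyCycleOnce(mz, protocol, t1, b1plus, efficiency)
  mz
}

# small noisy phantom acquisition shared across tests
makeTestPair <- function(shape = c(32L, 32L, 32L), seed = 11,
                         noise_sigma = 8e-5, ...) {
  ph <- makePhantom(shape, seed = seed)
  list(phantom = ph,
       pair = simulateAcquisition(ph, noise_sigma = noise_sigma, seed = seed,
                                  ...))
}

randomSignals <- function(n, seed = 42) {
  set.seed(seed)
  amp <- function() 10^runif(n, -4, 4)
  list(s1 = complex(modulus = amp(), argument = runif(n, -pi, pi)),
       s2 = complex(modulus = amp(), argument = runif(n, -pi, pi)))
}
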