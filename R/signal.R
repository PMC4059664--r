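# Forward model of the MP2RAGE steady-state signal.
#
# Every element of the cycle acts on the longitudinal magnetization Mz
# (in units of M0) as an affine map Mz -> m*Mz + b:
#   inversion            m = -eff,            b = 0
#   free relaxation (t)  m = exp(-t/T1),      b = 1 - exp(-t/T1)
#   readout excitation   m = cos(a*b1+)*E_r,  b = 1 - E_r   (E_r = exp(-tr/T1))
# A train of j identical excitations composes to m^j and the geometric sum of
# b. The steady state is the fixed point b_tot/(1 - m_tot) of the full-cycle
# composition; |m_tot| < 1 for any physical input since every factor has
# magnitude <= 1 and the gap relaxations are strictly contractive.
# All helpers are vectorized over voxels.

.affCompose <- function(f, g) list(m = g$m * f$m, b = g$m * f$b + g$b)  # g after f

.affRelax <- function(t, t1) {
  e <- exp(-t / t1)
  list(m = e, b = 1 - e)
}

.affPulses <- function(j, alpha_deg, b1plus, t1, tr) {
  e <- exp(-tr / t1)
  m1 <- cos(alpha_deg * pi / 180 * b1plus) * e
  mj <- m1^j
  den <- 1 - m1
  b <- ifelse(abs(den) < 1e-14, j * (1 - e), (1 - e) * (1 - mj) / den)
  list(m = mj, b = b)
}

# Composed affine maps for one cycle: $total, plus the partial compositions
# $p1/$p2 from cycle start to just before the center pulse of train 1/2.
.cycleAffine <- function(protocol, t1, b1plus = 1, efficiency = NULL) {
  stopifnot(all(t1 > 0), all(b1plus > 0))
  eff <- efficiency %||% protocol@inversion_efficiency
  n <- length(t1)
  t1 <- as.numeric(t1)
  b1plus <- rep_len(as.numeric(b1plus), n)
  eff <- rep_len(as.numeric(eff), n)
  g <- gapTimes(protocol)
  nr <- protocol@n_readout
  k <- nr %/% 2L
  tr <- protocol@tr_readout

  acc <- list(m = -eff, b = rep(0, n))                       # inversion
  acc <- .affCompose(acc, .affRelax(g[["TA"]], t1))
  acc <- .affCompose(acc, .affPulses(k, protocol@alpha1, b1plus, t1, tr))
  p1 <- acc
  acc <- .affCompose(acc, .affPulses(nr - k, protocol@alpha1, b1plus, t1, tr))
  acc <- .affCompose(acc, .affRelax(g[["TB"]], t1))
  acc <- .affCompose(acc, .affPulses(k, protocol@alpha2, b1plus, t1, tr))
  p2 <- acc
  acc <- .affCompose(acc, .affPulses(nr - k, protocol@alpha2, b1plus, t1, tr))
  acc <- .affCompose(acc, .affRelax(g[["TC"]], t1))
  list(total = acc, p1 = p1, p2 = p2)
}

#' Steady-state longitudinal magnetization at cycle start
#'
#' Closed-form fixed point of the full-cycle affine map on Mz (inversion,
#' relaxation gaps, and both readout trains), in units of M0. Vectorized over
#' \code{t1}, \code{b1plus} and \code{efficiency}.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param t1 longitudinal relaxation time(s) in seconds, > 0.
#' @param b1plus transmit field scale(s) multiplying the nominal flip angles.
#' @param efficiency optional per-voxel inversion efficiency overriding the
#'   protocol value.
#' @return Numeric vector of Mz at the start of the cycle (just before the
#'   inversion pulse), as a fraction of M0.
#' @examples
#' steadyStateMz(defaultProtocol(), t1 = c(0.5, 1, 2, 4))
#' @export
steadyStateMz <- function(protocol, t1, b1plus = 1, efficiency = NULL) {
  validObject(protocol)
  cyc <- .cycleAffine(protocol, t1, b1plus, efficiency)
  cyc$total$b / (1 - cyc$total$m)
}

#' MP2RAGE signals of the two readout trains
#'
#' Propagates the steady-state magnetization to the center excitation of each
#' train and returns the pair of complex signals
#' \code{s_i = pd * b1minus * sin(alpha_i * b1plus) * Mz_i * exp(1i*phase)},
#' optionally damped by \code{exp(-te/t2star)}. The sign of Mz is preserved:
#' for long T1 the train-1 signal is still inverted at TI1, and that sign is
#' precisely the information the uniform combination exploits. The receive
#' scale, phase and T2* factor are common to both signals and therefore
#' cancel in the combination.
#'
#' All arguments after \code{protocol} are vectorized over voxels.
#'
#' @inheritParams steadyStateMz
#' @param pd proton density (arbitrary units, >= 0).
#' @param b1minus receive field scale.
#' @param phase receive phase in radians.
#' @param t2star optional T2* (s); \code{NULL} omits the decay factor.
#' @return \code{list(s1 =, s2 =)} of complex vectors.
#' @examples
#' s <- mp2rageSignals(defaultProtocol(), t1 = 1.2)
#' uniformCombination(s$s1, s$s2)
#' @export
mp2rageSignals <- function(protocol, t1, pd = 1, b1plus = 1, b1minus = 1,
                           phase = 0, t2star = NULL, efficiency = NULL) {
  validObject(protocol)
  stopifnot(all(pd >= 0))
  n <- max(length(t1), length(pd), length(b1plus), length(b1minus),
           length(phase), length(efficiency %||% 1))
  t1 <- rep_len(t1, n); pd <- rep_len(pd, n)
  b1plus <- rep_len(b1plus, n); b1minus <- rep_len(b1minus, n)
  phase <- rep_len(phase, n)
  cyc <- .cycleAffine(protocol, t1, b1plus, efficiency)
  mzss <- cyc$total$b / (1 - cyc$total$m)
  mz1 <- cyc$p1$m * mzss + cyc$p1$b
  mz2 <- cyc$p2$m * mzss + cyc$p2$b
  common <- pd * b1minus * exp(1i * phase)
  if (!is.null(t2star)) common <- common * exp(-protocol@te / rep_len(t2star, n))
  rad <- pi / 180
  list(s1 = common * sin(protocol@alpha1 * rad * b1plus) * mz1,
       s2 = common * sin(protocol@alpha2 * rad * b1plus) * mz2)
}
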