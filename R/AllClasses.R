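#' MP2RAGE acquisition protocol
#'
#' Timing, flip-angle and matrix parameters of one MP2RAGE protocol. Times are
#' in seconds, flip angles in degrees, voxel size in mm. The inversion times
#' \code{ti1}/\code{ti2} are defined to the center of each gradient-echo
#' readout train (linear k-space ordering), so the protocol implies three
#' relaxation gaps: \code{TA = ti1 - (n/2) tr_readout} between inversion and
#' the first train, \code{TB} between trains, and \code{TC} after the second
#' train; all three must be nonnegative.
#'
#' @slot tr_mp2rage full cycle repetition time (s).
#' @slot tr_readout echo spacing of the gradient-echo train (s).
#' @slot te echo time (s); only used through the optional T2* factor.
#' @slot ti1,ti2 inversion times to the center of train 1 / train 2 (s).
#' @slot alpha1,alpha2 excitation flip angles of train 1 / train 2 (degrees).
#' @slot n_readout number of excitations per train (inner-loop partitions).
#' @slot inversion_efficiency fraction of Mz inverted by the adiabatic pulse,
#'   in \[0, 1\]; the inversion maps \code{Mz -> -eff * Mz}.
#' @slot matrix acquisition matrix (3 positive integers).
#' @slot voxel_size voxel dimensions in mm (3 positive numbers).
#'
#' @seealso [AcquisitionProtocol()], [defaultProtocol()], [gapTimes()]
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(
    tr_mp2rage = "numeric", tr_readout = "numeric", te = "numeric",
    ti1 = "numeric", ti2 = "numeric",
    alpha1 = "numeric", alpha2 = "numeric",
    n_readout = "integer", inversion_efficiency = "numeric",
    matrix = "integer", voxel_size = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("tr_mp2rage", "tr_readout", "te", "ti1", "ti2",
              "alpha1", "alpha2", "inversion_efficiency"))
    if (!sc(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(msg)) return(msg)
  if (object@tr_mp2rage <= 0 || object@tr_readout <= 0)
    msg <- c(msg, "tr_mp2rage and tr_readout must be positive")
  if (!(object@ti1 < object@ti2 && object@ti2 < object@tr_mp2rage))
    msg <- c(msg, "need ti1 < ti2 < tr_mp2rage")
  if (object@inversion_efficiency < 0 || object@inversion_efficiency > 1)
    msg <- c(msg, "inversion_efficiency must be in [0, 1]")
  if (length(object@n_readout) != 1L || object@n_readout < 1L)
    msg <- c(msg, "n_readout must be a positive integer")
  if (length(object@matrix) != 3L || any(object@matrix < 1L))
    msg <- c(msg, "matrix must be 3 positive integers")
  if (length(object@voxel_size) != 3L || any(object@voxel_size <= 0))
    msg <- c(msg, "voxel_size must be 3 positive numbers")
  if (!length(msg)) {
    g <- gapTimes(object)
    bad <- names(g)[g < -1e-12]
    if (length(bad))
      msg <- c(msg, sprintf(
        "degenerate timing: gap(s) %s negative; readout train does not fit",
        paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Co-registered pair of MP2RAGE readout volumes
#'
#' Holds the two inversion-time volumes (GRE_TI1, GRE_TI2), either as
#' complex-valued arrays (\code{mode = "complex"}) or, for scanner exports
#' that only provide magnitudes, as nonnegative magnitude arrays together
#' with a precomputed uniform volume supplying the sign information
#' (\code{mode = "magnitude"}).
#'
#' @slot s1,s2 arrays of identical shape: complex signals, or magnitudes.
#' @slot mode \code{"complex"} or \code{"magnitude"}.
#' @slot uniform in magnitude mode, the accompanying uniform image in
#'   \[-0.5, 0.5\]; otherwise an empty array.
#'
#' @seealso [ComplexVolumePair()], [uniformCombination()], [robustCombination()]
#' @exportClass ComplexVolumePair
setClass("ComplexVolumePair",
  representation(s1 = "array", s2 = "array", mode = "character",
                 uniform = "array"))

setValidity("ComplexVolumePair", function(object) {
  msg <- character()
  if (!identical(dim(object@s1), dim(object@s2)))
    msg <- c(msg, "s1 and s2 must have identical shapes")
  if (!object@mode %in% c("complex", "magnitude"))
    msg <- c(msg, "mode must be 'complex' or 'magnitude'")
  if (identical(object@mode, "magnitude")) {
    if (is.complex(object@s1) || is.complex(object@s2))
      msg <- c(msg, "magnitude mode requires real, nonnegative arrays")
    else if (any(object@s1 < 0, na.rm = TRUE) || any(object@s2 < 0, na.rm = TRUE))
      msg <- c(msg, "magnitudes must be nonnegative")
    if (!identical(dim(object@uniform), dim(object@s1)))
      msg <- c(msg, "magnitude mode requires a uniform volume of the same shape")
    else if (any(abs(object@uniform) > 0.5 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "uniform volume must lie in [-0.5, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' Combined (uniform or robust) T1-weighted image
#'
#' @slot values real array in \[-0.5, 0.5\].
#' @slot mode \code{"uniform"} or \code{"robust"}.
#' @slot beta regularization constant in squared raw-signal units (0 for the
#'   uniform combination).
#' @slot degenerate logical array flagging voxels where the uniform ratio was
#'   0/0 (returned as 0); empty if none were flagged.
#' @slot protocol the [AcquisitionProtocol-class] the volumes came from, or
#'   \code{NULL}.
#'
#' @seealso [uniformCombination()], [robustCombination()]
#' @exportClass CombinedImage
setClass("CombinedImage",
  representation(values = "array", mode = "character", beta = "numeric",
                 degenerate = "array", protocol = "ANY"))

setValidity("CombinedImage", function(object) {
  msg <- character()
  if (!object@mode %in% c("uniform", "robust"))
    msg <- c(msg, "mode must be 'uniform' or 'robust'")
  if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta < 0)
    msg <- c(msg, "beta must be a single nonnegative number")
  if (identical(object@mode, "uniform") && object@beta != 0)
    msg <- c(msg, "uniform images must have beta = 0")
  v <- object@values
  if (any(!is.finite(v)))
    msg <- c(msg, "values must all be finite")
  else if (any(abs(v) > 0.5 + 1e-9))
    msg <- c(msg, "values must lie in [-0.5, 0.5]")
  if (length(object@degenerate) &&
      !identical(dim(object@degenerate), dim(object@values)))
    msg <- c(msg, "degenerate flag map must match the value array shape")
  if (length(msg)) msg else TRUE
})

#' Digital head phantom with ground truth
#'
#' Nested-ellipsoid head (skull-fat shell, CSF rim and ventricles, cortical
#' GM ribbon, WM core) with per-voxel tissue parameters and the smooth
#' multiplicative field maps the MP2RAGE combination is designed to cancel or
#' tolerate: transmit (B1+) scaling of flip angles, receive (B1-) scaling of
#' signal intensity, and a spatially varying inversion efficiency emulating
#' the poor-B1+ inferior regions where inversion artifacts arise.
#'
#' @slot labels integer array; 0 = background, 1 = CSF, 2 = GM, 3 = WM,
#'   4 = skull-fat.
#' @slot t1,pd per-voxel T1 (s) and proton density (background pd = 0).
#' @slot b1plus,b1minus smooth positive fields, mean 1 over the brain.
#' @slot efficiency per-voxel inversion efficiency in \[0, 1\].
#' @slot voxel_size voxel dimensions in mm.
#'
#' @seealso [makePhantom()], [simulateAcquisition()], [tissueMask()]
#' @exportClass Phantom
setClass("Phantom",
  representation(labels = "array", t1 = "array", pd = "array",
                 b1plus = "array", b1minus = "array", efficiency = "array",
                 voxel_size = "numeric"))

setValidity("Phantom", function(object) {
  msg <- character()
  dm <- dim(object@labels)
  for (s in c("t1", "pd", "b1plus", "b1minus", "efficiency"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("'%s' must share the label volume shape", s))
  if (!length(msg)) {
    if (any(object@pd[object@labels == 0L] != 0))
      msg <- c(msg, "background voxels must have pd = 0")
    if (any(object@t1 <= 0) || any(object@b1plus <= 0) || any(object@b1minus <= 0))
      msg <- c(msg, "t1, b1plus and b1minus must be strictly positive")
    if (any(object@efficiency < 0 | object@efficiency > 1))
      msg <- c(msg, "efficiency must be in [0, 1]")
  }
  if (length(object@voxel_size) != 3L || any(object@voxel_size <= 0))
    msg <- c(msg, "voxel_size must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' Lookup table between uniform-image intensity and T1
#'
#' Tabulates the forward-model uniform intensity on a strictly increasing T1
#' grid (at a fixed B1+ scale) and records the maximal T1 interval on which
#' the intensity is strictly monotone, so the intensity-to-T1 map is
#' single-valued there.
#'
#' @slot t1 T1 grid in seconds, strictly increasing.
#' @slot s uniform intensities from the forward model at each grid node.
#' @slot monotone_idx integer start/end node indices of the maximal strictly
#'   monotone run.
#' @slot b1plus the B1+ scale the table was built at.
#' @slot protocol the generating [AcquisitionProtocol-class].
#'
#' @seealso [buildLookupTable()], [t1FromUniform()]
#' @exportClass T1LookupTable
setClass("T1LookupTable",
  representation(t1 = "numeric", s = "numeric", monotone_idx = "integer",
                 b1plus = "numeric", protocol = "ANY"))

setValidity("T1LookupTable", function(object) {
  msg <- character()
  if (length(object@t1) < 2L || any(diff(object@t1) <= 0))
    msg <- c(msg, "t1 grid must be strictly increasing with >= 2 nodes")
  if (length(object@s) != length(object@t1))
    msg <- c(msg, "s must match the t1 grid length")
  mi <- object@monotone_idx
  if (length(mi) != 2L || mi[1] < 1L || mi[2] > length(object@t1) || mi[1] >= mi[2])
    msg <- c(msg, "monotone_idx must be a valid index pair")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcquisitionProtocol", function(object) {
  g <- gapTimes(object)
  cat("MP2RAGE acquisition protocol\n")
  cat(sprintf("  TR %.3g s | TR_readout %.3g ms | TE %.3g ms\n",
              object@tr_mp2rage, 1e3 * object@tr_readout, 1e3 * object@te))
  cat(sprintf("  TI1/TI2 %.3g/%.3g s | alpha1/alpha2 %g/%g deg | n_readout %d\n",
              object@ti1, object@ti2, object@alpha1, object@alpha2,
              object@n_readout))
  cat(sprintf("  gaps TA/TB/TC %.3f/%.3f/%.3f s | inversion efficiency %.2f\n",
              g["TA"], g["TB"], g["TC"], object@inversion_efficiency))
  cat(sprintf("  matrix %s | voxel %s mm\n",
              paste(object@matrix, collapse = "x"),
              paste(object@voxel_size, collapse = "x")))
  invisible(object)
})

setMethod("show", "ComplexVolumePair", function(object) {
  cat(sprintf("ComplexVolumePair: %s volumes, shape %s\n", object@mode,
              paste(dim(object@s1), collapse = "x")))
  invisible(object)
})

setMethod("show", "CombinedImage", function(object) {
  v <- object@values
  cat(sprintf("CombinedImage (%s%s): shape %s, range [%.3f, %.3f]\n",
              object@mode,
              if (object@mode == "robust") sprintf(", beta = %.3g", object@beta) else "",
              paste(dim(v), collapse = "x"), min(v), max(v)))
  if (length(object@degenerate))
    cat(sprintf("  %d degenerate (0/0) voxel(s) set to 0\n",
                sum(object@degenerate)))
  invisible(object)
})

setMethod("show", "Phantom", function(object) {
  tab <- table(factor(object@labels, levels = 0:4,
                      labels = c("background", "CSF", "GM", "WM", "fat")))
  cat(sprintf("Phantom: shape %s, voxel %s mm\n",
              paste(dim(object@labels), collapse = "x"),
              paste(object@voxel_size, collapse = "x")))
  cat("  voxels:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "T1LookupTable", function(object) {
  mr <- monotoneRange(object)
  cat(sprintf("T1LookupTable: %d nodes over [%.3g, %.3g] s (b1plus = %g)\n",
              length(object@t1), min(object@t1), max(object@t1), object@b1plus))
  cat(sprintf("  strictly monotone over [%.3g, %.3g] s, intensities [%.4f, %.4f]\n",
              mr[1], mr[2], min(object@s), max(object@s)))
  invisible(object)
})
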