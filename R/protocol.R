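#' Construct an MP2RAGE acquisition protocol
#'
#' All arguments default to the reference 7T protocol returned by
#' [defaultProtocol()]. Units: seconds, degrees, mm.
#'
#' @param tr_mp2rage full cycle TR (s).
#' @param tr_readout echo spacing of the GRE train (s).
#' @param te echo time (s).
#' @param ti1,ti2 inversion times to the center of each readout train (s).
#' @param alpha1,alpha2 excitation flip angles (degrees).
#' @param n_readout excitations per train; defaults to the third matrix
#'   dimension (inner loop).
#' @param inversion_efficiency fraction of Mz inverted, in \[0, 1\].
#' @param matrix acquisition matrix (3 integers).
#' @param voxel_size voxel size in mm (3 numbers).
#' @return A validated [AcquisitionProtocol-class] object.
#' @examples
#' p <- AcquisitionProtocol(ti1 = 0.9)
#' gapTimes(p)
#' @export
AcquisitionProtocol <- function(tr_mp2rage = 6, tr_readout = 6.5e-3,
                                te = 2.89e-3, ti1 = 0.8, ti2 = 2.7,
                                alpha1 = 4, alpha2 = 5,
                                n_readout = matrix[3],
                                inversion_efficiency = 0.96,
                                matrix = c(256L, 240L, 176L),
                                voxel_size = c(1, 1, 1.2)) {
  new("AcquisitionProtocol",
      tr_mp2rage = as.numeric(tr_mp2rage), tr_readout = as.numeric(tr_readout),
      te = as.numeric(te), ti1 = as.numeric(ti1), ti2 = as.numeric(ti2),
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      n_readout = as.integer(n_readout),
      inversion_efficiency = as.numeric(inversion_efficiency),
      matrix = as.integer(matrix), voxel_size = as.numeric(voxel_size))
}

#' Reference 7T MP2RAGE protocol
#'
#' TR_MP2RAGE/TR_readout/TE = 6 s / 6.5 ms / 2.89 ms, flip angles 4/5 deg,
#' TI 0.8/2.7 s, matrix 256x240x176 at 1.0x1.0x1.2 mm, 176 excitations per
#' train, inversion efficiency 0.96.
#'
#' @return An [AcquisitionProtocol-class] object.
#' @examples
#' defaultProtocol()
#' @export
defaultProtocol <- function() AcquisitionProtocol()

#' Relaxation gaps implied by a protocol
#'
#' With linear k-space ordering and contrast defined at the train center,
#' the cycle decomposes into inversion, gap TA, train 1, gap TB, train 2,
#' gap TC. Each readout excitation is modeled as an instantaneous rotation
#' followed by \code{tr_readout} of relaxation, so a train occupies
#' \code{n_readout * tr_readout} seconds.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @return Named numeric vector \code{c(TA =, TB =, TC =)} in seconds.
#' @export
gapTimes <- function(protocol) {
  n <- protocol@n_readout
  k <- n %/% 2L                       # pulses before the train-center pulse
  tr <- protocol@tr_readout
  c(TA = protocol@ti1 - k * tr,
    TB = protocol@ti2 - protocol@ti1 - n * tr,
    TC = protocol@tr_mp2rage - protocol@ti2 - (n - k) * tr)
}

.protocolFields <- c("tr_mp2rage", "tr_readout", "te", "ti1", "ti2",
                     "alpha1", "alpha2", "n_readout", "inversion_efficiency",
                     "matrix", "voxel_size")

#' Read / write a protocol as flat YAML
#'
#' The YAML file holds the protocol fields under their slot names, with the
#' units of the class definition (seconds, degrees, mm). Missing keys fall
#' back to the [defaultProtocol()] values.
#'
#' @param path file path.
#' @param protocol an [AcquisitionProtocol-class] (for writing).
#' @return \code{readProtocol} returns an [AcquisitionProtocol-class];
#'   \code{writeProtocol} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeProtocol(defaultProtocol(), f)
#' readProtocol(f)
#' @export
readProtocol <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .protocolFields)
  if (length(unknown))
    stop("unknown protocol field(s): ", paste(unknown, collapse = ", "))
  do.call(AcquisitionProtocol, vals)
}

#' @rdname readProtocol
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  vals <- lapply(setNames(.protocolFields, .protocolFields),
                 function(f) slot(protocol, f))
  yaml::write_yaml(vals, path)
  invisible(path)
}
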