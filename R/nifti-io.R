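# NIfTI reading/writing. All volume I/O goes through RNifti; coordinates
# follow the NIfTI affine and no reorientation is performed.

#' Read a NIfTI volume
#'
#' @param path a \code{.nii} / \code{.nii.gz} file.
#' @return An \code{RNifti} image (array with header attributes).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  RNifti::readNifti(path)
}

#' Write a volume as float32 NIfTI
#'
#' @param volume numeric array.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param reference optional NIfTI image or path whose header/affine is
#'   copied.
#' @param voxel_size voxel dimensions in mm used when no reference is given.
#' @param datatype NIfTI storage type (default \code{"float"} = float32).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, reference = NULL, voxel_size = NULL,
                        datatype = "float") {
  if (is.character(reference)) reference <- readVolume(reference)
  img <- RNifti::asNifti(volume, reference = reference)
  if (is.null(reference) && !is.null(voxel_size))
    RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.sameGeometry <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(RNifti::xform(a), RNifti::xform(b), tolerance = 1e-6,
                     check.attributes = FALSE))
}

#' Read a complex volume from a magnitude/phase file pair
#'
#' Phase images are expected in radians (the common scanner-export
#' convention); pass \code{phase_scale} to convert e.g. integer-scaled
#' exports. The two files must agree in shape and affine.
#'
#' @param mag_path,phase_path NIfTI paths.
#' @param phase_scale factor applied to the phase values before use.
#' @return \code{list(data = complex array, reference = magnitude image)}.
#' @export
readComplexVolume <- function(mag_path, phase_path, phase_scale = 1) {
  mag <- readVolume(mag_path)
  ph <- readVolume(phase_path)
  if (!.sameGeometry(mag, ph))
    stop("shape/affine mismatch between '", mag_path, "' and '", phase_path, "'")
  list(data = array(as.numeric(mag) * exp(1i * as.numeric(ph) * phase_scale),
                    dim = dim(mag)),
       reference = mag)
}

#' Write a complex volume as magnitude + phase NIfTI files
#'
#' @param data complex array.
#' @param mag_path,phase_path output paths.
#' @param reference optional header/affine source.
#' @param voxel_size used when no reference is given.
#' @return \code{c(mag_path, phase_path)}, invisibly.
#' @export
writeComplexVolume <- function(data, mag_path, phase_path, reference = NULL,
                               voxel_size = NULL) {
  writeVolume(Mod(data), mag_path, reference, voxel_size)
  writeVolume(Arg(data), phase_path, reference, voxel_size)
  invisible(c(mag_path, phase_path))
}

# sidecar JSON capturing the resolved parameters of a run
.writeSidecar <- function(out_path, params) {
  side <- paste0(sub("\\.nii(\\.gz)?$", "", out_path), ".json")
  params$software <- paste0("mp2rage ", as.character(packageVersion("mp2rage")))
  jsonlite::write_json(params, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(side)
}
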