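# Evaluation surface: background-noise statistics, bias-ratio maps, tissue
# contrast, and repeat-scan volumetric reproducibility.

.imgValues <- function(image) {
  if (is(image, "CombinedImage")) image@values else image
}

#' Background noise statistics of a combined image
#'
#' On the uniform image the background is salt-and-pepper noise: the
#' combination of two independent circular complex Gaussians is uniformly
#' distributed over the whole \[-0.5, 0.5\] range, so a fraction of exactly
#' 0.2 of pure-noise voxels falls outside \[-0.4, 0.4\]. The robust image
#' collapses the background towards -0.5.
#'
#' \code{spread_fraction} counts voxels strictly outside the
#' boundary-exclusive interval \[-threshold, threshold\] (a constant -0.5
#' background therefore counts as fully "spread"; the separate
#' \code{frac_above} statistic, the fraction above \code{-threshold}, is the
#' operational flag for full suppression).
#'
#' @param image a [CombinedImage-class] or numeric array.
#' @param background_mask logical array selecting background voxels.
#' @param threshold spread interval half-width (default 0.4).
#' @return \code{list(mean, std, spread_fraction, frac_above, n)}.
#' @export
backgroundStats <- function(image, background_mask, threshold = 0.4) {
  v <- .imgValues(image)[background_mask]
  if (!length(v)) stop("empty background mask")
  list(mean = mean(v),
       std = if (length(v) > 1L) sd(v) else 0,
       spread_fraction = mean(abs(v) > threshold),
       frac_above = mean(v > -threshold),
       n = length(v))
}

#' Ratio of the robust over the uniform image
#'
#' Voxelwise robust/uniform map, computed only where the uniform magnitude
#' exceeds \code{epsilon} (the uniform image crosses zero inside the brain,
#' where the ratio is undefined), with per-tissue median summaries when a
#' label volume is supplied. Deviations of the median from 1 localize the
#' intensity bias the regularization introduces: they grow where the signal
#' power is low relative to beta.
#'
#' @param robust,uniform [CombinedImage-class] objects (or arrays) of one
#'   shape.
#' @param mask logical array restricting the comparison (e.g. brain mask).
#' @param labels optional integer label array (phantom convention: 1 = CSF,
#'   2 = GM, 3 = WM) for per-tissue medians.
#' @param epsilon uniform-magnitude guard (default 1e-3).
#' @return \code{list(map, valid, summary)}: the ratio map (\code{NA} where
#'   undefined), the validity mask, and a named vector of per-tissue median
#'   ratios (\code{NULL} without labels).
#' @export
biasRatio <- function(robust, uniform, mask = NULL, labels = NULL,
                      epsilon = 1e-3) {
  rv <- .imgValues(robust); uv <- .imgValues(uniform)
  stopifnot(identical(dim(rv), dim(uv)))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(uv))
  valid <- mask & abs(uv) > epsilon
  if (!any(valid)) warning("no valid voxels: uniform image is below epsilon everywhere in the mask")
  map <- array(NA_real_, dim = dim(uv))
  map[valid] <- rv[valid] / uv[valid]
  summary <- NULL
  if (!is.null(labels)) {
    tl <- .tissueLabels[c("CSF", "GM", "WM")]
    summary <- vapply(tl, function(l) {
      sel <- valid & labels == l
      if (any(sel)) median(map[sel]) else NA_real_
    }, numeric(1))
  }
  list(map = map, valid = valid, summary = summary)
}

#' Per-tissue means and GM/WM separation
#'
#' @param image a [CombinedImage-class] or numeric array.
#' @param masks named list with logical arrays \code{GM}, \code{WM},
#'   \code{CSF}.
#' @return \code{list(gm_mean, wm_mean, csf_mean, gm_wm_separation)} where
#'   the separation is \code{wm_mean - gm_mean} (positive for the expected
#'   T1w contrast).
#' @export
tissueContrast <- function(image, masks) {
  v <- .imgValues(image)
  pick <- function(nm) {
    m <- masks[[nm]]
    if (is.null(m) || !any(m)) stop("empty or missing mask '", nm, "'")
    mean(v[m])
  }
  gm <- pick("GM"); wm <- pick("WM"); csf <- pick("CSF")
  list(gm_mean = gm, wm_mean = wm, csf_mean = csf,
       gm_wm_separation = wm - gm)
}

#' Repeat-scan volumetric reproducibility
#'
#' Relative volumetric difference per structure between two repetitions,
#' normalized by the mean of the two volumes (symmetric and bounded):
#' \deqn{d(s) = 100 \cdot |V_1(s) - V_2(s)| / ((V_1(s) + V_2(s))/2).}
#' The worst-case error is the maximum of \eqn{d} across structures.
#'
#' @param rep1,rep2 named numeric vectors, or data frames with columns
#'   \code{structure} and \code{volume}; the structure sets must match.
#' @return \code{list(per_structure, mean_pct, worst_case_pct)}.
#' @examples
#' volumetricReproducibility(c(A = 100, B = 50), c(A = 100, B = 60))
#' @export
volumetricReproducibility <- function(rep1, rep2) {
  v1 <- .asVolumetry(rep1); v2 <- .asVolumetry(rep2)
  only1 <- setdiff(names(v1), names(v2))
  only2 <- setdiff(names(v2), names(v1))
  if (length(only1) || length(only2))
    stop("structure sets differ: only in rep1 {",
         paste(only1, collapse = ", "), "}; only in rep2 {",
         paste(only2, collapse = ", "), "}")
  v2 <- v2[names(v1)]
  if (any(v1 < 0) || any(v2 < 0)) stop("volumes must be nonnegative")
  if (any(v1 + v2 == 0)) stop("structure with zero total volume")
  d <- 100 * abs(v1 - v2) / ((v1 + v2) / 2)
  list(per_structure = d, mean_pct = mean(d), worst_case_pct = max(d))
}

.asVolumetry <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("structure", "volume") %in% names(x)))
    return(setNames(as.numeric(x$volume), as.character(x$structure)))
  }
  stopifnot(is.numeric(x), !is.null(names(x)), !anyNA(names(x)))
  x
}

#' Structure volumes from a label map
#'
#' @param labels integer label array.
#' @param voxel_size voxel dimensions in mm.
#' @param names optional \code{label = name} mapping; defaults to the phantom
#'   tissue labels.
#' @return Named numeric vector of volumes in mm^3.
#' @export
labelVolumes <- function(labels, voxel_size = c(1, 1, 1),
                         names = .tissueLabels[c("CSF", "GM", "WM", "fat")]) {
  vox <- prod(voxel_size)
  vapply(setNames(as.integer(names), base::names(names)),
         function(l) sum(labels == l) * vox, numeric(1))
}

#' Threshold-mask comparison baseline
#'
#' The classical alternative to the robust combination: blank the uniform
#' image wherever the second-readout magnitude falls below a threshold,
#' setting those voxels to -0.5. Kept as a comparison baseline only -- it
#' risks thresholding out genuine low-signal structure.
#'
#' @param uniform a [CombinedImage-class] (or numeric array).
#' @param m2_volume magnitude of the GRE_TI2 readout, same shape.
#' @param threshold magnitude cut-off; 0 leaves the image unchanged.
#' @return Object of the same type as \code{uniform} with masked voxels at
#'   -0.5.
#' @export
maskBaseline <- function(uniform, m2_volume, threshold) {
  v <- .imgValues(uniform)
  stopifnot(identical(dim(v), dim(m2_volume)), threshold >= 0)
  v[m2_volume < threshold] <- -0.5
  if (is(uniform, "CombinedImage")) {
    out <- uniform
    out@values <- v
    out
  } else v
}
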