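#' Construct a ComplexVolumePair
#'
#' @param s1,s2 arrays of identical shape: complex signals
#'   (\code{mode = "complex"}) or nonnegative magnitudes
#'   (\code{mode = "magnitude"}).
#' @param uniform required in magnitude mode: the uniform image carrying the
#'   sign information, in \[-0.5, 0.5\].
#' @param mode determined from the input type by default.
#' @return A validated [ComplexVolumePair-class].
#' @examples
#' ComplexVolumePair(array(1 + 0i, c(2, 2, 2)), array(2 + 0i, c(2, 2, 2)))
#' @export
ComplexVolumePair <- function(s1, s2, uniform = NULL,
                              mode = if (is.null(uniform)) "complex" else "magnitude") {
  asArr <- function(x) if (is.array(x)) x else array(x, dim = length(x))
  s1 <- asArr(s1); s2 <- asArr(s2)
  if (mode == "complex") {
    storage.mode(s1) <- "complex"; storage.mode(s2) <- "complex"
    uniform <- array(numeric(0))
  } else {
    if (is.null(uniform)) stop("magnitude mode requires a uniform volume")
    uniform <- asArr(uniform)
  }
  new("ComplexVolumePair", s1 = s1, s2 = s2, mode = mode, uniform = uniform)
}

#' Accessors for the S4 containers
#'
#' Slot access for [ComplexVolumePair-class], [CombinedImage-class],
#' [Phantom-class] and [T1LookupTable-class] objects.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
inv1 <- function(x) { stopifnot(is(x, "ComplexVolumePair")); x@s1 }

#' @rdname accessors
#' @export
inv2 <- function(x) { stopifnot(is(x, "ComplexVolumePair")); x@s2 }

#' @rdname accessors
#' @export
pairMode <- function(x) { stopifnot(is(x, "ComplexVolumePair")); x@mode }

#' @rdname accessors
#' @export
imageData <- function(x) {
  stopifnot(is(x, "CombinedImage"))
  x@values
}

#' @rdname accessors
#' @export
betaValue <- function(x) { stopifnot(is(x, "CombinedImage")); x@beta }

#' @rdname accessors
#' @export
combinationMode <- function(x) { stopifnot(is(x, "CombinedImage")); x@mode }

#' @rdname accessors
#' @export
degenerateMask <- function(x) {
  stopifnot(is(x, "CombinedImage"))
  if (length(x@degenerate)) x@degenerate
  else array(FALSE, dim = dim(x@values))
}

.tissueLabels <- c(background = 0L, CSF = 1L, GM = 2L, WM = 3L, fat = 4L)

#' @rdname accessors
#' @export
phantomLabels <- function(x) { stopifnot(is(x, "Phantom")); x@labels }

#' Per-tissue and brain masks of a phantom
#'
#' @param x a [Phantom-class].
#' @param tissue one of \code{"background"}, \code{"CSF"}, \code{"GM"},
#'   \code{"WM"}, \code{"fat"}.
#' @return Logical array. \code{brainMask} is the union of CSF, GM and WM.
#' @export
tissueMask <- function(x, tissue) {
  stopifnot(is(x, "Phantom"))
  if (!tissue %in% names(.tissueLabels))
    stop("unknown tissue name '", tissue, "'; expected one of ",
         paste(names(.tissueLabels), collapse = ", "))
  x@labels == .tissueLabels[[tissue]]
}

#' @rdname tissueMask
#' @export
brainMask <- function(x) {
  stopifnot(is(x, "Phantom"))
  x@labels %in% .tissueLabels[c("CSF", "GM", "WM")]
}

#' @rdname accessors
#' @export
phantomT1 <- function(x) { stopifnot(is(x, "Phantom")); x@t1 }

#' @rdname accessors
#' @export
phantomPD <- function(x) { stopifnot(is(x, "Phantom")); x@pd }

#' @rdname accessors
#' @export
b1PlusMap <- function(x) { stopifnot(is(x, "Phantom")); x@b1plus }

#' @rdname accessors
#' @export
b1MinusMap <- function(x) { stopifnot(is(x, "Phantom")); x@b1minus }

#' @rdname accessors
#' @export
efficiencyMap <- function(x) { stopifnot(is(x, "Phantom")); x@efficiency }

#' @rdname accessors
#' @export
t1Grid <- function(x) { stopifnot(is(x, "T1LookupTable")); x@t1 }

#' @rdname accessors
#' @export
lutIntensities <- function(x) { stopifnot(is(x, "T1LookupTable")); x@s }

#' T1 interval on which a lookup table is invertible
#'
#' @param x a [T1LookupTable-class].
#' @return \code{c(t1_min, t1_max)} of the maximal strictly monotone run.
#' @export
monotoneRange <- function(x) {
  stopifnot(is(x, "T1LookupTable"))
  x@t1[x@monotone_idx]
}

#' Rescale a combined image to 12-bit integers
#'
#' Maps \[-0.5, 0.5\] linearly to \[0, 4095\] for viewers that expect
#' unsigned integer T1w intensities. Off by default everywhere else in the
#' package: the natural \[-0.5, 0.5\] units are kept in all computations.
#'
#' @param x a [CombinedImage-class].
#' @return Integer array in \[0, 4095\].
#' @export
rescaleToInt <- function(x) {
  stopifnot(is(x, "CombinedImage"))
  v <- round((x@values + 0.5) * 4095)
  storage.mode(v) <- "integer"
  v
}
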