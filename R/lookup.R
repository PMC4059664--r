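# Lookup-table T1 mapping. Quantitative T1 must be derived from the uniform
# image: the robust image is biased exactly where the signal power is
# comparable to beta, so feeding it through the same table distorts T1 in
# low-signal regions (see t1FromUniform).

#' Build a T1 lookup table for a protocol
#'
#' Evaluates the forward model ([mp2rageSignals()] + [uniformCombination()])
#' on a T1 grid at unit proton density and a fixed B1+ scale, and detects the
#' maximal interval on which the intensity is strictly monotone in T1 (the
#' invertible range). With the default protocol the curve is monotone
#' decreasing over the whole default grid \[0.1, 6\] s at 5 ms spacing.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param t1_grid strictly increasing T1 grid in seconds.
#' @param b1plus transmit scale the table is built at (default 1). A 2-D
#'   intensity-by-B1+ correction is available through [t1FromUniformB1()] but
#'   is off by default, since the standard pipeline does not use measured B1+
#'   maps.
#' @return A [T1LookupTable-class].
#' @examples
#' lut <- buildLookupTable(defaultProtocol(), seq(0.5, 3, by = 0.05))
#' monotoneRange(lut)
#' @export
buildLookupTable <- function(protocol, t1_grid = seq(0.1, 6, by = 0.005),
                             b1plus = 1) {
  validObject(protocol)
  if (length(t1_grid) < 2L) stop("t1_grid needs at least 2 nodes")
  if (any(diff(t1_grid) <= 0)) stop("t1_grid must be strictly increasing")
  sig <- mp2rageSignals(protocol, t1 = t1_grid, b1plus = b1plus)
  s <- as.numeric(uniformCombination(sig$s1, sig$s2))
  run <- .longestMonotoneRun(s)
  if (is.null(run))
    stop("uniform intensity is nowhere strictly monotone on this grid; ",
         "the protocol cannot be inverted for T1")
  new("T1LookupTable", t1 = as.numeric(t1_grid), s = s,
      monotone_idx = run, b1plus = as.numeric(b1plus), protocol = protocol)
}

# start/end node indices of the longest run of strictly monotone differences
.longestMonotoneRun <- function(s) {
  d <- sign(diff(s))
  if (!length(d) || all(d == 0)) return(NULL)
  best <- NULL; bestLen <- 0L
  i <- 1L
  while (i <= length(d)) {
    if (d[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < length(d) && d[j + 1L] == d[i]) j <- j + 1L
    if (j - i + 1L > bestLen) { bestLen <- j - i + 1L; best <- c(i, j + 1L) }
    i <- j + 1L
  }
  if (is.null(best)) NULL else as.integer(best)
}

#' Map uniform-image intensities to T1
#'
#' Piecewise-linear interpolation of the inverse intensity-to-T1 relation
#' inside the table's monotone range. Intensities outside the attainable
#' range are flagged invalid (returned as \code{NA}) rather than silently
#' clamped, because out-of-range values mark exactly the inversion-artifact
#' and noise regions where a T1 estimate would be meaningless; set
#' \code{clamp = TRUE} to clamp them to the range endpoints instead.
#'
#' @param u uniform-image intensities (vector or array).
#' @param lut a [T1LookupTable-class].
#' @param clamp clamp out-of-range intensities instead of flagging.
#' @return Numeric object shaped like \code{u}: T1 in seconds, with a logical
#'   \code{"invalid"} attribute marking flagged voxels.
#' @examples
#' lut <- buildLookupTable(defaultProtocol(), seq(0.3, 5, by = 0.01))
#' t1FromUniform(lutIntensities(lut)[5], lut)  # recovers t1Grid(lut)[5]
#' @export
t1FromUniform <- function(u, lut, clamp = FALSE) {
  stopifnot(is(lut, "T1LookupTable"))
  idx <- lut@monotone_idx[1]:lut@monotone_idx[2]
  sv <- lut@s[idx]; tv <- lut@t1[idx]
  if (sv[1] > sv[length(sv)]) { sv <- rev(sv); tv <- rev(tv) }
  lo <- sv[1]; hi <- sv[length(sv)]
  uin <- as.numeric(u)
  invalid <- !is.finite(uin) | uin < lo | uin > hi
  if (clamp) {
    uin <- pmin(pmax(uin, lo), hi)
    invalid <- !is.finite(as.numeric(u))
  }
  t1 <- approx(sv, tv, xout = uin, rule = 1)$y
  t1[invalid] <- NA_real_
  dim(t1) <- dim(u)
  inv <- invalid
  dim(inv) <- dim(u)
  structure(t1, invalid = inv)
}

#' T1 mapping with per-voxel B1+ correction
#'
#' Two-dimensional lookup in intensity-by-B1+: a table is built at each node
#' of \code{b1_grid}, each voxel is inverted under its two bracketing tables,
#' and the results are linearly interpolated in B1+. Provided for protocols
#' where a measured transmit map is available; the default pipeline uses the
#' plain [t1FromUniform()].
#'
#' @inheritParams t1FromUniform
#' @param b1plus per-voxel transmit scales, same shape as \code{u}.
#' @param protocol an [AcquisitionProtocol-class].
#' @param t1_grid,b1_grid grids for the tables.
#' @return As [t1FromUniform()].
#' @export
t1FromUniformB1 <- function(u, b1plus, protocol,
                            t1_grid = seq(0.1, 6, by = 0.005),
                            b1_grid = seq(0.6, 1.4, by = 0.1)) {
  stopifnot(length(b1plus) == length(u), length(b1_grid) >= 2L,
            all(diff(b1_grid) > 0))
  luts <- lapply(b1_grid, function(b) buildLookupTable(protocol, t1_grid, b))
  t1s <- vapply(luts, function(l) {
    r <- t1FromUniform(u, l)
    as.numeric(r)
  }, numeric(length(u)))
  t1s <- matrix(t1s, nrow = length(u))
  b <- pmin(pmax(as.numeric(b1plus), b1_grid[1]), b1_grid[length(b1_grid)])
  iu <- findInterval(b, b1_grid, rightmost.closed = TRUE)
  w <- (b - b1_grid[iu]) / (b1_grid[iu + 1L] - b1_grid[iu])
  w[!is.finite(w)] <- 0
  n <- length(u)
  lowv <- t1s[cbind(seq_len(n), iu)]
  hiv <- t1s[cbind(seq_len(n), pmin(iu + 1L, length(b1_grid)))]
  out <- (1 - w) * lowv + w * hiv
  # a voxel invalid under one bracketing table but not the other: use the valid one
  out[is.na(lowv) & !is.na(hiv)] <- hiv[is.na(lowv) & !is.na(hiv)]
  out[is.na(hiv) & !is.na(lowv)] <- lowv[is.na(hiv) & !is.na(lowv)]
  inv <- is.na(out)
  dim(out) <- dim(u); dim(inv) <- dim(u)
  structure(out, invalid = inv)
}
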