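#' @include grid-model.R
NULL

.symmetrize <- function(M) (M + t(M)) / 2

#' Sample covariance and mean of the spectra
#'
#' The ordinary sample covariance of the spot spectra over the selected
#' channels, with the `1/(n-1)` divisor, and the channel mean spectrum.
#' The matrix is explicitly symmetrised (`(A + t(A)) / 2`).
#'
#' @param grid a `SpectrumGrid` with `n >= 2` spots.
#' @param channels optional 1-based channel indices (default all).
#' @return list with `SZ` (`p' x p'` matrix) and `mean` (length `p'`).
#' @export
sampleCovariance <- function(grid, channels = NULL) {
    stopifnot(is(grid, "SpectrumGrid"))
    m <- spectraMatrix(grid)
    if (!is.null(channels)) m <- m[, channels, drop = FALSE]
    n <- nrow(m)
    if (n < 2L) stop("sample covariance needs at least 2 spots, got ", n)
    mu <- colMeans(m)
    mc <- sweep(m, 2L, mu)
    SZ <- .symmetrize(crossprod(mc) / (n - 1))
    list(SZ = SZ, mean = mu)
}

#' @rdname pseudoResiduals
#' @details
#' Each spot's local-linear prediction is the average of its available
#' axial neighbours (left, right, up, down at grid distance 1); on a full
#' grid that average is exactly the local linear fit at the centre, so any
#' exact linear field in `(col, row)` has zero interior residual. Edge
#' spots — and spots bordering empty positions of an irregular tissue
#' outline, which are treated identically — average over however many of
#' the up-to-4 neighbours exist. Spots with no axial neighbour at all are
#' flagged invalid and excluded from noise covariance estimation.
#' @export
setMethod("pseudoResiduals", "SpectrumGrid", function(x, channels = NULL) {
    m <- spectraMatrix(x)
    if (!is.null(channels)) m <- m[, channels, drop = FALSE]
    n <- nrow(m)
    if (n < 2L) stop("pseudo-residuals need at least 2 spots")
    occ <- occupancyIndex(x)
    cc <- gridCoords(x)
    r <- cc$row + 1L; c <- cc$col + 1L
    nr <- nrow(occ); nc <- ncol(occ)
    nb <- function(dr, dc) {
        rr <- r + dr; ccol <- c + dc
        idx <- rep(NA_integer_, n)
        ok <- rr >= 1L & rr <= nr & ccol >= 1L & ccol <= nc
        idx[ok] <- occ[cbind(rr[ok], ccol[ok])]
        idx
    }
    nbs <- cbind(nb(0L, -1L), nb(0L, 1L), nb(-1L, 0L), nb(1L, 0L))
    counts <- rowSums(!is.na(nbs))
    acc <- matrix(0, n, ncol(m))
    for (j in 1:4) {
        idx <- nbs[, j]
        ok <- !is.na(idx)
        acc[ok, ] <- acc[ok, ] + m[idx[ok], , drop = FALSE]
    }
    valid <- counts >= 1L
    res <- matrix(0, n, ncol(m))
    res[valid, ] <- m[valid, , drop = FALSE] -
        acc[valid, , drop = FALSE] / counts[valid]
    new("ResidualGrid", residuals = res, valid = valid,
        neighbourCounts = as.integer(counts),
        channels = if (is.null(channels)) seq_len(nChannels(x))
                   else as.integer(channels))
})

#' Noise covariance from pseudo-residuals
#'
#' Sample covariance (centred, `1/(m-1)` divisor) of the valid
#' pseudo-residual rows — the estimate of the noise covariance the MNF
#' transform divides by. Optionally rescales each residual row by
#' `(1 + 1/m_i)^{-1/2}` (`m_i` = neighbour count) to equalise the residual
#' variance of edge and interior spots; off by default, matching the plain
#' pseudo-residual covariance.
#'
#' @param res a [ResidualGrid-class] with at least 2 valid rows.
#' @param equalizeEdgeVariance logical (default `FALSE`).
#' @return symmetric `p' x p'` noise covariance matrix.
#' @export
noiseCovariance <- function(res, equalizeEdgeVariance = FALSE) {
    stopifnot(is(res, "ResidualGrid"))
    R <- res@residuals[res@valid, , drop = FALSE]
    m <- nrow(R)
    if (m < 2L)
        stop("noise covariance needs at least 2 valid residual rows, got ", m)
    if (equalizeEdgeVariance) {
        cnt <- res@neighbourCounts[res@valid]
        R <- R / sqrt(1 + 1 / cnt)
    }
    Rc <- sweep(R, 2L, colMeans(R))
    .symmetrize(crossprod(Rc) / (m - 1))
}

#' Spectrum and noise covariance in one pass
#'
#' @param grid a `SpectrumGrid`.
#' @param channels optional channel indices.
#' @param equalizeEdgeVariance passed to [noiseCovariance()].
#' @return a [CovariancePair-class].
#' @export
covariancePair <- function(grid, channels = NULL,
                           equalizeEdgeVariance = FALSE) {
    sz <- sampleCovariance(grid, channels)
    res <- pseudoResiduals(grid, channels)
    SN <- noiseCovariance(res, equalizeEdgeVariance)
    new("CovariancePair", SZ = sz$SZ, SN = SN, mean = sz$mean,
        nSpots = nSpots(grid), nValidResiduals = sum(res@valid))
}
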