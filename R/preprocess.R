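#' @include grid-model.R
#' @importFrom splines bs
#' @importFrom stats mad
NULL

#' Log-transform intensities
#'
#' Replaces every intensity `x` by `ln(x + offset)`. Raw MALDI counts
#' include zeros, so the default offset 1 gives the familiar `log1p`
#' transform; pass `offset = 0` only for data known to be strictly
#' positive.
#'
#' @param grid a `SpectrumGrid` with non-negative intensities.
#' @param offset non-negative value added before logging (default 1).
#' @return the transformed `SpectrumGrid`; m/z axis and coordinates are
#'   unchanged.
#' @export
logTransform <- function(grid, offset = 1) {
    stopifnot(is(grid, "SpectrumGrid"))
    m <- spectraMatrix(grid)
    if (!all(is.finite(m)))
        stop("non-finite intensities cannot be log-transformed")
    if (any(m < 0))
        stop("negative intensity found (min = ", min(m),
             "); log transform requires non-negative intensities")
    if (offset < 0)
        stop("offset must be non-negative")
    if (offset == 0 && any(m == 0))
        stop("offset = 0 with zero intensities present; ",
             "use a positive offset (e.g. 1)")
    spectraMatrix(grid) <- log(m + offset)
    grid
}

## Cubic regression-spline basis with nKnots interior knots equally spaced
## over the mz range (boundary knots at the range ends), intercept included.
.baselineBasis <- function(mz, nKnots) {
    if (nKnots < 2L) stop("nKnots must be >= 2")
    r <- range(mz)
    knots <- seq(r[1L], r[2L], length.out = nKnots + 2L)[-c(1L, nKnots + 2L)]
    splines::bs(mz, knots = knots, degree = 3L, intercept = TRUE,
                Boundary.knots = r)
}

## One robust spline fit: IRLS with Tukey-bisquare weights. With
## oneSided = TRUE only positive residuals (candidate peaks) are
## down-weighted, so the fitted curve tracks the baseline under the peaks.
.robustSplineFit <- function(y, B, robustIterations, oneSided, tuning = 4.685) {
    w <- rep(1, length(y))
    fit <- NULL
    for (it in seq_len(robustIterations + 1L)) {
        A <- crossprod(B, w * B)
        b <- crossprod(B, w * y)
        coef <- tryCatch(solve(A, b), error = function(e)
            qr.solve(A + diag(1e-10 * mean(diag(A)), ncol(A)), b))
        fit <- drop(B %*% coef)
        if (it > robustIterations) break
        r <- y - fit
        s <- stats::mad(r, center = 0)
        if (!is.finite(s) || s <= .Machine$double.eps * max(abs(y), 1)) break
        u <- r / (tuning * s)
        w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
        if (oneSided) w[r <= 0] <- 1
        if (all(w == 0)) w <- rep(1, length(y))
    }
    fit
}

#' Robust-spline baseline correction
#'
#' Estimates a smooth spectral baseline with a cubic regression spline
#' (`nKnots` interior knots equally spaced in m/z) fitted by iteratively
#' reweighted least squares with a redescending (Tukey bisquare) weight
#' function, so that peaks — large positive residuals — are down-weighted
#' and the curve settles under them. By default the down-weighting is
#' one-sided (negative residuals keep weight 1), because a baseline must
#' underestimate peaks, not split them.
#'
#' @param spectrum numeric intensity vector.
#' @param mz m/z axis, same length as `spectrum`.
#' @param nKnots interior knot count (default 5).
#' @param robustIterations IRLS iterations (default 10).
#' @param oneSided down-weight only positive residuals (default `TRUE`).
#' @return list with `corrected = spectrum - baseline` and `baseline`.
#' @examples
#' mz <- seq(1000, 2000, length.out = 400)
#' y <- 2 + 0.001 * mz + exp(-((mz - 1500) / 5)^2) * 10
#' out <- baselineCorrect(y, mz)
#' max(out$corrected)   # close to the peak height 10
#' @export
baselineCorrect <- function(spectrum, mz, nKnots = 5L,
                            robustIterations = 10L, oneSided = TRUE) {
    spectrum <- as.numeric(spectrum)
    mz <- as.numeric(mz)
    if (length(spectrum) != length(mz))
        stop("spectrum and mz must have equal length")
    if (!all(is.finite(spectrum)) || !all(is.finite(mz)))
        stop("non-finite values in spectrum or mz")
    nBasis <- nKnots + 4L   # cubic + intercept
    if (length(spectrum) < nBasis)
        stop("too few channels (", length(spectrum), ") for ", nKnots,
             " knots; need at least ", nBasis)
    B <- .baselineBasis(mz, nKnots)
    baseline <- .robustSplineFit(spectrum, B, robustIterations, oneSided)
    list(corrected = spectrum - baseline, baseline = baseline)
}

#' Baseline-correct every spectrum of a grid
#'
#' Applies [baselineCorrect()] spot by spot (the spline basis over the
#' shared m/z axis is built once).
#'
#' @inheritParams baselineCorrect
#' @param grid a `SpectrumGrid`.
#' @return the corrected `SpectrumGrid` (intensities may now be negative).
#' @export
baselineCorrectGrid <- function(grid, nKnots = 5L, robustIterations = 10L,
                                oneSided = TRUE) {
    stopifnot(is(grid, "SpectrumGrid"))
    m <- spectraMatrix(grid)
    if (!all(is.finite(m))) stop("non-finite intensities")
    nBasis <- nKnots + 4L
    if (ncol(m) < nBasis)
        stop("too few channels (", ncol(m), ") for ", nKnots, " knots")
    B <- .baselineBasis(mzAxis(grid), nKnots)
    for (i in seq_len(nrow(m))) {
        bl <- .robustSplineFit(m[i, ], B, robustIterations, oneSided)
        m[i, ] <- m[i, ] - bl
    }
    spectraMatrix(grid) <- m
    grid
}

#' Pre-filter channels by SNR or mean intensity
#'
#' Ranks channels and keeps the best `retainK`, the primitive behind the
#' "keep the top 650" style filtering that keeps covariance matrices at a
#' manageable size. For MNF the ranking statistic is the per-channel SNR —
#' the ratio of the diagonal entries of the spectrum covariance and the
#' noise covariance; for PCA it is the mean intensity.
#'
#' @param SZdiag per-channel spectrum variances (diagonal of `SZ`).
#' @param SNdiag per-channel noise variances (diagonal of `SN`); required
#'   for `mode = "snr"`. A zero entry is a degenerate noise estimate: that
#'   channel's SNR is treated as `+Inf` (retained first) with a warning.
#' @param means per-channel mean intensities; required for
#'   `mode = "intensity"`.
#' @param mode `"snr"` or `"intensity"`.
#' @param retainK number of channels to keep (default 650).
#' @return ascending integer vector of `retainK` 1-based channel indices.
#' @export
prefilterChannels <- function(SZdiag, SNdiag = NULL, means = NULL,
                              mode = c("snr", "intensity"), retainK = 650L) {
    mode <- match.arg(mode)
    p <- length(SZdiag)
    retainK <- as.integer(retainK)
    if (retainK < 1L || retainK > p)
        stop("retainK must be in 1..", p)
    stat <- if (mode == "snr") {
        if (is.null(SNdiag) || length(SNdiag) != p)
            stop("mode='snr' needs SNdiag of length ", p)
        if (any(SNdiag == 0))
            warning(sum(SNdiag == 0), " channel(s) have zero noise variance; ",
                    "their SNR is treated as +Inf (degenerate noise estimate)")
        ifelse(SNdiag == 0, Inf, SZdiag / SNdiag)
    } else {
        if (is.null(means) || length(means) != p)
            stop("mode='intensity' needs means of length ", p)
        means
    }
    sort(order(stat, decreasing = TRUE)[seq_len(retainK)])
}

#' Per-channel variance and noise-variance summaries of a grid
#'
#' Diagonal-only passes over the data: per-channel mean, variance
#' (`1/(n-1)` divisor) and pseudo-residual noise variance, without ever
#' materialising a `p x p` matrix — this is what makes pre-filtering at
#' `p ~ 10^4` cheap.
#'
#' @param grid a `SpectrumGrid`.
#' @return list with `mean`, `varZ`, `varN` (length-`p` vectors) and
#'   `nValidResiduals`.
#' @export
channelStats <- function(grid) {
    stopifnot(is(grid, "SpectrumGrid"))
    m <- spectraMatrix(grid)
    n <- nrow(m)
    if (n < 2L) stop("need at least 2 spots")
    mu <- colMeans(m)
    varZ <- colSums(m^2) / (n - 1) - n / (n - 1) * mu^2
    varZ[varZ < 0] <- 0
    res <- pseudoResiduals(grid)
    R <- res@residuals[res@valid, , drop = FALSE]
    nv <- nrow(R)
    if (nv < 2L) stop("fewer than 2 valid residual rows")
    rmu <- colMeans(R)
    varN <- colSums(R^2) / (nv - 1) - nv / (nv - 1) * rmu^2
    varN[varN < 0] <- 0
    list(mean = mu, varZ = varZ, varN = varN, nValidResiduals = nv)
}

#' Pre-filter a grid's channels in one call
#'
#' Convenience wrapper: computes [channelStats()] and applies
#' [prefilterChannels()].
#'
#' @inheritParams prefilterChannels
#' @param grid a `SpectrumGrid`.
#' @return ascending integer vector of retained channel indices.
#' @export
prefilterGrid <- function(grid, mode = c("snr", "intensity"),
                          retainK = 650L) {
    mode <- match.arg(mode)
    st <- channelStats(grid)
    prefilterChannels(st$varZ, SNdiag = st$varN, means = st$mean,
                      mode = mode, retainK = retainK)
}
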