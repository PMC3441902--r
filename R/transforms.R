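#' @include covariance.R
NULL

## Deterministic sign convention: the largest-magnitude entry of every
## loading vector is made positive (ties broken by lowest index, which is
## what which.max does). Keeps outputs reproducible across LAPACK builds.
.fixSigns <- function(V) {
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    V
}

.checkSymmetric <- function(M, name) {
    if (nrow(M) != ncol(M))
        stop(name, " must be square")
    sc <- max(abs(M), 1e-300)
    if (max(abs(M - t(M))) > 1e-8 * sc)
        stop(name, " is not symmetric within tolerance")
    .symmetrize(M)
}

.pcaCore <- function(SZ, K) {
    SZ <- .checkSymmetric(SZ, "SZ")
    p <- nrow(SZ)
    if (K < 1L || K > p) stop("K must be in 1..", p)
    e <- eigen(SZ, symmetric = TRUE)
    list(vectors = .fixSigns(e$vectors[, seq_len(K), drop = FALSE]),
         eigenvalues = e$values[seq_len(K)])
}

.mnfCore <- function(SZ, SN, K, ridge = 0) {
    SZ <- .checkSymmetric(SZ, "SZ")
    SN <- .checkSymmetric(SN, "SN")
    p <- nrow(SZ)
    if (nrow(SN) != p) stop("SZ and SN dimensions differ")
    if (K < 1L || K > p) stop("K must be in 1..", p)
    if (ridge < 0) stop("ridge must be non-negative")
    SNr <- if (ridge > 0) SN + diag(ridge * mean(diag(SN)), p) else SN
    R <- tryCatch(chol(SNr), error = function(e) NULL)
    if (is.null(R)) {
        ev <- eigen(SNr, symmetric = TRUE, only.values = TRUE)$values
        rk <- sum(ev > p * .Machine$double.eps * max(ev, 0))
        stop("noise covariance is not positive definite (numerical rank ",
             rk, " of ", p, "); supply a positive ridge ",
             "(e.g. ridge = 1e-8) to regularise")
    }
    ## whiten: A = R^{-T} SZ R^{-1}; eigenvectors u map back via a = R^{-1} u,
    ## giving a' SN a = u'u = 1
    A <- forwardsolve(t(R), t(forwardsolve(t(R), SZ)))
    A <- .symmetrize(A)
    e <- eigen(A, symmetric = TRUE)
    lam <- e$values[seq_len(K)]
    tol <- 1e-10 * max(abs(e$values), 1)
    lam[lam < 0 & lam > -tol] <- 0
    a <- backsolve(R, e$vectors[, seq_len(K), drop = FALSE])
    list(vectors = .fixSigns(a), eigenvalues = lam)
}

.bandScores <- function(grid, channels, vectors) {
    m <- spectraMatrix(grid)
    if (!is.null(channels)) m <- m[, channels, drop = FALSE]
    mc <- sweep(m, 2L, colMeans(m))
    mc %*% vectors
}

#' @describeIn pcaBands eigendecomposition of a covariance matrix. Returns
#'   the top-`K` eigenpairs of the symmetric matrix `object`, eigenvalues
#'   descending, unit-norm vectors (`t(a) %*% a = 1`), deterministic sign
#'   convention (largest-magnitude loading positive). The scores slot is
#'   empty — no data were seen.
#' @export
setMethod("pcaBands", "matrix", function(object, K, ...) {
    core <- .pcaCore(object, K)
    new("BandDecomposition", vectors = core$vectors,
        eigenvalues = core$eigenvalues,
        scores = matrix(0, 0L, K), method = "pca",
        channels = seq_len(nrow(core$vectors)))
})

#' @describeIn pcaBands PCA of a grid: computes the sample covariance over
#'   `channels`, decomposes it, and fills per-spot scores `t(a) %*% Z`
#'   computed on mean-centred spectra.
#' @param channels optional 1-based channel indices (default all).
#' @export
setMethod("pcaBands", "SpectrumGrid", function(object, K, channels = NULL,
                                               ...) {
    sz <- sampleCovariance(object, channels)
    core <- .pcaCore(sz$SZ, K)
    new("BandDecomposition", vectors = core$vectors,
        eigenvalues = core$eigenvalues,
        scores = .bandScores(object, channels, core$vectors),
        method = "pca",
        channels = if (is.null(channels)) seq_len(nrow(core$vectors))
                   else as.integer(channels))
})

#' @describeIn mnfBands solve `SZ a = lambda SN a` for covariance matrices
#'   `object` (=`SZ`) and `SN`. Solved by the symmetric reduction: Cholesky
#'   factor of `SN` (plus `ridge * mean(diag(SN)) * I` when `ridge > 0`),
#'   whitening, ordinary symmetric eigendecomposition, back-transformation.
#'   Vectors are normalised so `t(a) %*% SN %*% a = 1` (each band has unit
#'   noise variance) with the deterministic sign convention. Errors if `SN`
#'   is not positive definite and `ridge = 0`, naming the numerical rank.
#' @param SN symmetric positive (semi-)definite noise covariance.
#' @param ridge non-negative ridge multiplier (of `mean(diag(SN))`),
#'   default 0.
#' @export
setMethod("mnfBands", "matrix", function(object, K, SN, ridge = 0, ...) {
    core <- .mnfCore(object, SN, K, ridge)
    new("BandDecomposition", vectors = core$vectors,
        eigenvalues = core$eigenvalues,
        scores = matrix(0, 0L, K), method = "mnf",
        channels = seq_len(nrow(core$vectors)))
})

#' @describeIn mnfBands MNF of a grid: estimates `SZ` (sample covariance)
#'   and `SN` (pseudo-residual covariance) over `channels`, solves the
#'   generalised eigenproblem and fills per-spot scores on mean-centred
#'   spectra. If the Cholesky factorisation of `SN` fails with `ridge = 0`
#'   and `autoRidge = TRUE` (default), a fallback ridge of `1e-8` is
#'   applied with a warning.
#' @param autoRidge apply a fallback ridge automatically (grid method only).
#' @param equalizeEdgeVariance passed to [noiseCovariance()].
#' @export
setMethod("mnfBands", "SpectrumGrid", function(object, K, channels = NULL,
                                               ridge = 0, autoRidge = TRUE,
                                               equalizeEdgeVariance = FALSE,
                                               ...) {
    cp <- covariancePair(object, channels, equalizeEdgeVariance)
    core <- tryCatch(.mnfCore(cp@SZ, cp@SN, K, ridge), error = function(e) e)
    if (inherits(core, "error")) {
        if (!autoRidge || ridge > 0) stop(core)
        warning("noise covariance factorisation failed; retrying with ",
                "ridge = 1e-8 * mean(diag(SN))")
        core <- .mnfCore(cp@SZ, cp@SN, K, ridge = 1e-8)
    }
    new("BandDecomposition", vectors = core$vectors,
        eigenvalues = core$eigenvalues,
        scores = .bandScores(object, channels, core$vectors),
        method = "mnf",
        channels = if (is.null(channels)) seq_len(nrow(core$vectors))
                   else as.integer(channels))
})

#' Choose how many bands to keep
#'
#' PCA: the smallest `K` whose cumulative eigenvalue share reaches
#' `pctThreshold` (percent total variance explained). MNF: eigenvalue
#' ratios are not additive, so the count of bands whose signal-to-noise
#' ratio exceeds a threshold is used instead. Under the generalised
#' eigenproblem parameterisation `lambda = (signal + noise) / noise`, so
#' "signal roughly equals noise" is `lambda = 2`, i.e. `lambda - 1 = 1`.
#' The default compares `lambda - 1 > snrThreshold` with
#' `snrThreshold = 1`; set `snrScale = "lambda"` to threshold the raw
#' eigenvalue instead.
#'
#' @param eigenvalues descending eigenvalue vector.
#' @param method `"pca"` or `"mnf"`.
#' @param pctThreshold cumulative-variance fraction for PCA (default 0.9).
#' @param snrThreshold threshold for MNF (default 1).
#' @param snrScale `"snr"` (compare `lambda - 1`) or `"lambda"`.
#' @return integer band count `K`.
#' @examples
#' selectBands(c(8, 1, 1), "pca", pctThreshold = 0.8)      # 1
#' selectBands(c(5, 2.5, 1.9, 1.2), "mnf")                 # 3
#' @export
selectBands <- function(eigenvalues, method = c("pca", "mnf"),
                        pctThreshold = 0.9, snrThreshold = 1,
                        snrScale = c("snr", "lambda")) {
    method <- match.arg(method)
    snrScale <- match.arg(snrScale)
    ev <- as.numeric(eigenvalues)
    if (length(ev) > 1L && any(diff(ev) > 1e-12 * max(abs(ev), 1)))
        stop("eigenvalues must be sorted in descending order")
    if (method == "pca") {
        tot <- sum(ev)
        if (tot <= 0) stop("total variance must be positive")
        frac <- cumsum(ev) / tot
        K <- which(frac >= pctThreshold - 1e-12)[1L]
        if (is.na(K)) K <- length(ev)
        as.integer(K)
    } else {
        x <- if (snrScale == "snr") ev - 1 else ev
        as.integer(sum(x > snrThreshold))
    }
}

#' @rdname bandVectors
#' @export
setMethod("bandVectors", "BandDecomposition", function(x) x@vectors)

#' @rdname bandEigenvalues
#' @export
setMethod("bandEigenvalues", "BandDecomposition", function(x) x@eigenvalues)

#' @rdname bandScores
#' @export
setMethod("bandScores", "BandDecomposition", function(x) x@scores)

#' @rdname bandSNR
#' @export
setMethod("bandSNR", "BandDecomposition", function(x) {
    if (x@method != "mnf")
        stop("band SNR is defined for MNF decompositions only; ",
             "PCA eigenvalues are variances")
    x@eigenvalues - 1
})

#' Write an eigenvalue table
#'
#' Delimited text with columns `band`, `lambda` and, for MNF, `snr`
#' (`lambda - 1`); 17 significant digits.
#'
#' @param bands a `BandDecomposition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEigenvalueTable <- function(bands, path) {
    stopifnot(is(bands, "BandDecomposition"))
    ev <- bandEigenvalues(bands)
    lines <- if (bands@method == "mnf")
        c("band,lambda,snr",
          sprintf("%d,%.17g,%.17g", seq_along(ev), ev, ev - 1))
    else
        c("band,lambda",
          sprintf("%d,%.17g", seq_along(ev), ev))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
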