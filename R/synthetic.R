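#' @include grid-model.R
#' @importFrom stats rnorm runif dnorm cor
NULL

#' Configuration for the synthetic spot-grid generator
#'
#' Describes a synthetic imaging-MS dataset under the additive model
#' `Z(x) = M(x) + N(x)`: a small number `q` of spatially smooth signal
#' components with sparse non-negative channel loadings, plus Gaussian
#' noise that is independent across spots (spatially white) but correlated
#' across channels — exactly the separation the MNF transform exploits.
#'
#' @param nCols,nRows grid dimensions (default 50 x 40, i.e. 2000 spots).
#' @param p channel count (default 200).
#' @param q number of planted signal components (default 4).
#' @param patternKinds character vector recycled over components; each of
#'   `"disk"`, `"stripe"`, `"gradient"`, `"smooth-noise"`.
#' @param loadingsSparsity fraction of channels carrying each component
#'   (default 0.1).
#' @param noiseSd stationary per-channel noise standard deviation
#'   (default 0.5; patterns have unit spatial variance).
#' @param noiseChannelCorr AR(1) correlation of the noise across adjacent
#'   channels (default 0.3); this is what makes the noise covariance
#'   non-diagonal and the generalised eigenproblem non-trivial.
#' @param baselineAmp amplitude of a smooth per-spectrum baseline
#'   (default 1).
#' @param smoothBandwidth spatial Gaussian smoothing bandwidth, in spots,
#'   for `"smooth-noise"` patterns and the baseline's spatial modulation
#'   (default 3).
#' @param componentAmpRatio geometric ladder of component amplitudes
#'   (component `j` has amplitude `ratio^(1-j)`; default 1.4 — components
#'   of differing abundance, as in real tissue).
#' @param peakMeanHeight mean elevation of active (peak) channels, in
#'   units of the spatial-modulation standard deviation (default 2): a
#'   real peak channel has a high mean intensity that is modulated
#'   spatially, which is what intensity-threshold pre-filtering relies on.
#'   Adds a per-channel constant, so covariances are unaffected.
#' @param occupancyMask optional `nRows x nCols` logical matrix marking
#'   occupied grid positions (tissue outline); default all occupied.
#' @param mzRange numeric length-2 m/z range (default 1000–26000 Da/e, a
#'   typical linear-mode MALDI protein range).
#' @param seed integer RNG seed; a fixed seed makes the output
#'   bit-reproducible.
#' @return a `SynthConfig` object.
#' @seealso [generateGrid()], [tissueScaleFixture()]
#' @export
synthConfig <- function(nCols = 50L, nRows = 40L, p = 200L, q = 4L,
                        patternKinds = c("disk", "stripe", "gradient",
                                         "smooth-noise"),
                        loadingsSparsity = 0.1, noiseSd = 0.5,
                        noiseChannelCorr = 0.3, baselineAmp = 1,
                        smoothBandwidth = 3, componentAmpRatio = 1.4,
                        peakMeanHeight = 2, occupancyMask = NULL,
                        mzRange = c(1000, 26000), seed = 1L) {
    new("SynthConfig", nCols = as.integer(nCols), nRows = as.integer(nRows),
        p = as.integer(p), q = as.integer(q),
        patternKinds = as.character(patternKinds),
        loadingsSparsity = loadingsSparsity, noiseSd = noiseSd,
        noiseChannelCorr = noiseChannelCorr, baselineAmp = baselineAmp,
        smoothBandwidth = smoothBandwidth,
        componentAmpRatio = componentAmpRatio,
        peakMeanHeight = peakMeanHeight,
        occupancyMask = if (is.null(occupancyMask)) matrix(TRUE, 0L, 0L)
                        else occupancyMask,
        mzRange = as.numeric(mzRange), seed = as.integer(seed))
}

#' @rdname synthConfig
#' @export
setClass("SynthConfig",
    representation(nCols = "integer", nRows = "integer", p = "integer",
                   q = "integer", patternKinds = "character",
                   loadingsSparsity = "numeric", noiseSd = "numeric",
                   noiseChannelCorr = "numeric", baselineAmp = "numeric",
                   smoothBandwidth = "numeric", componentAmpRatio = "numeric",
                   peakMeanHeight = "numeric", occupancyMask = "matrix",
                   mzRange = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@q > min(object@p, object@nCols * object@nRows))
        msg <- c(msg, "q must not exceed min(p, nCols * nRows)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (abs(object@noiseChannelCorr) >= 1)
        msg <- c(msg, "noiseChannelCorr must lie in (-1, 1)")
    if (object@loadingsSparsity <= 0 || object@loadingsSparsity > 1)
        msg <- c(msg, "loadingsSparsity must lie in (0, 1]")
    if (nrow(object@occupancyMask) &&
        !identical(dim(object@occupancyMask),
                   c(object@nRows, object@nCols)))
        msg <- c(msg, "occupancyMask must be nRows x nCols")
    if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
        msg <- c(msg, "mzRange must be an increasing length-2 vector")
    if (length(msg)) msg else TRUE
})

## Row-normalised Gaussian smoothing matrix for one axis.
.smoothMat <- function(n, bw) {
    S <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = bw)
    S / rowSums(S)
}

## One spatial pattern on the full bounding box (nRows x nCols).
.makePattern <- function(kind, nr, nc, bw) {
    switch(kind,
        gradient = {
            beta <- stats::runif(1, -1, 1); gamma <- stats::runif(1, -1, 1)
            if (abs(beta) + abs(gamma) < 0.2) beta <- 1
            outer(seq_len(nr) - 1L, seq_len(nc) - 1L,
                  function(r, c) beta * c + gamma * r)
        },
        disk = {
            cx <- stats::runif(1, 0.25, 0.75) * (nc - 1)
            cy <- stats::runif(1, 0.25, 0.75) * (nr - 1)
            rad <- 0.2 * min(nr, nc)
            outer(seq_len(nr) - 1L, seq_len(nc) - 1L,
                  function(r, c) exp(-((c - cx)^2 + (r - cy)^2) /
                                     (2 * rad^2)))
        },
        stripe = {
            th <- stats::runif(1, 0, pi)
            proj <- outer(seq_len(nr) - 1L, seq_len(nc) - 1L,
                          function(r, c) cos(th) * c + sin(th) * r)
            ctr <- stats::runif(1, 0.3, 0.7) * (max(proj) + min(proj))
            w <- 0.15 * (max(proj) - min(proj))
            exp(-(proj - ctr)^2 / (2 * w^2))
        },
        `smooth-noise` = {
            W <- matrix(stats::rnorm(nr * nc), nr, nc)
            .smoothMat(nr, bw) %*% W %*% t(.smoothMat(nc, bw))
        },
        stop("unknown pattern kind: ", kind))
}

#' Generate a synthetic spot-grid dataset with known truth
#'
#' Draws `intensities = (patterns + peakMeanHeight) %*% t(loadings) +
#' baseline + noise`:
#' spatially smooth patterns (centred, unit spatial variance over the
#' occupied spots), sparse non-negative channel loadings scaled by a
#' geometric amplitude ladder, a smooth per-spectrum baseline with gentle
#' spatial modulation, and Gaussian noise drawn independently per spot
#' with AR(1) correlation across channels. The whole matrix is shifted so
#' its minimum is zero (intensities are counts-like, non-negative).
#'
#' @param config a [synthConfig()] object.
#' @return list with `grid` (a [SpectrumGrid-class]) and `truth`
#'   (list: `patterns` `n x q`, `loadings` `p x q` including amplitude
#'   scaling, `noiseSd`, `shift` — the constant added to make intensities
#'   non-negative).
#' @examples
#' out <- generateGrid(synthConfig(nCols = 12, nRows = 10, p = 40, q = 2,
#'                                 seed = 7))
#' out$grid
#' @export
generateGrid <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    set.seed(config@seed)
    nr <- config@nRows; nc <- config@nCols; p <- config@p; q <- config@q
    mask <- if (nrow(config@occupancyMask)) config@occupancyMask
            else matrix(TRUE, nr, nc)
    coords <- which(mask, arr.ind = TRUE)          # (row, col), 1-based
    coords <- coords[order(coords[, 1L], coords[, 2L]), , drop = FALSE]
    n <- nrow(coords)
    if (n < 1L) stop("occupancy mask selects no spots")
    occIdx <- cbind(coords[, 1L], coords[, 2L])

    kinds <- rep_len(config@patternKinds, q)
    patterns <- matrix(0, n, q)
    for (j in seq_len(q)) {
        P <- .makePattern(kinds[j], nr, nc, config@smoothBandwidth)
        v <- P[occIdx]
        v <- v - mean(v)
        ## decorrelate from earlier patterns: recovery of individual
        ## components is only identifiable when the planted maps are
        ## mutually uncorrelated over the spots
        if (j > 1L)
            v <- v - patterns[, seq_len(j - 1L), drop = FALSE] %*%
                crossprod(patterns[, seq_len(j - 1L), drop = FALSE], v) /
                (n - 1)
        s <- stats::sd(v)
        if (s < 1e-8)
            stop("degenerate pattern (constant or collinear over spots)")
        patterns[, j] <- v / s
    }

    loadings <- matrix(0, p, q)
    mAct <- max(1L, ceiling(config@loadingsSparsity * p))
    for (j in seq_len(q)) {
        act <- sample.int(p, mAct)
        amp <- config@componentAmpRatio^(1 - j)
        loadings[act, j] <- stats::runif(mAct, 0.5, 1.5) * amp
    }

    X <- (patterns + config@peakMeanHeight) %*% t(loadings)

    if (config@baselineAmp > 0) {
        shape <- exp(-3 * (seq_len(p) - 1L) / max(p - 1L, 1L))
        W <- matrix(stats::rnorm(nr * nc), nr, nc)
        sm <- (.smoothMat(nr, config@smoothBandwidth) %*% W %*%
               t(.smoothMat(nc, config@smoothBandwidth)))[occIdx]
        sm <- if (stats::sd(sm) > 0) (sm - mean(sm)) / stats::sd(sm) else sm * 0
        ampSpot <- config@baselineAmp * (1 + 0.2 * sm)
        X <- X + outer(ampSpot, shape)
    }

    if (config@noiseSd > 0) {
        rho <- config@noiseChannelCorr
        E <- matrix(stats::rnorm(n * p), n, p)
        if (rho != 0 && p > 1L) {
            fac <- sqrt(1 - rho^2)
            for (k in 2:p) E[, k] <- rho * E[, k - 1L] + fac * E[, k]
        }
        X <- X + config@noiseSd * E
    }

    shift <- if (min(X) < 0) -min(X) else 0
    X <- X + shift

    mz <- seq(config@mzRange[1L], config@mzRange[2L], length.out = p)
    grid <- SpectrumGrid(X,
                         coords = data.frame(col = coords[, 2L] - 1L,
                                             row = coords[, 1L] - 1L),
                         mz = mz)
    list(grid = grid,
         truth = list(patterns = patterns, loadings = loadings,
                      peakMeanHeight = config@peakMeanHeight,
                      noiseSd = config@noiseSd, shift = shift))
}

#' Theoretical noise covariance of a generator configuration
#'
#' The stationary AR(1) channel covariance the generator draws noise from:
#' `noiseSd^2 * rho^|k1 - k2|`.
#'
#' @param config a `SynthConfig`.
#' @param channels optional channel subset.
#' @return `p' x p'` covariance matrix.
#' @export
noiseCovarianceModel <- function(config, channels = NULL) {
    stopifnot(is(config, "SynthConfig"))
    idx <- if (is.null(channels)) seq_len(config@p) else as.integer(channels)
    config@noiseSd^2 *
        config@noiseChannelCorr^abs(outer(idx, idx, "-"))
}

#' Elliptical tissue outline mask
#'
#' @param nRows,nCols bounding-box dimensions.
#' @param a,b semi-axes in columns and rows (defaults fill most of the box).
#' @return logical `nRows x nCols` matrix.
#' @export
ellipseMask <- function(nRows, nCols, a = 0.47 * nCols, b = 0.47 * nRows) {
    cx <- (nCols - 1) / 2; cy <- (nRows - 1) / 2
    outer(seq_len(nRows) - 1L, seq_len(nCols) - 1L,
          function(r, c) ((c - cx) / a)^2 + ((r - cy) / b)^2 <= 1)
}

#' Paper-scale synthetic fixture
#'
#' A synthetic dataset emulating the scale of a typical MALDI imaging run
#' of a coronal murine midbrain section: roughly 2000 occupied spots
#' inside an elliptical tissue outline on a 60 x 45 grid, 11280 m/z
#' channels spanning 1000–26000 Da/e, and 4 planted spatial components.
#' Intended for end-to-end pipeline and performance sanity checks; channel
#' pre-filtering (e.g. the top 650 by SNR) is expected downstream.
#'
#' @param seed integer RNG seed.
#' @return a [SpectrumGrid-class]; the generator truth is stored in
#'   `S4Vectors::metadata(grid)$truth`.
#' @export
tissueScaleFixture <- function(seed = 1L) {
    mask <- ellipseMask(45L, 60L, a = 28.35, b = 22.35)
    cfg <- synthConfig(nCols = 60L, nRows = 45L, p = 11280L, q = 4L,
                       loadingsSparsity = 0.02, occupancyMask = mask,
                       seed = seed)
    out <- generateGrid(cfg)
    g <- out$grid
    metadata(g)$truth <- out$truth
    metadata(g)$config <- cfg
    g
}

#' Adversarial fixture: variance is not signal
#'
#' A designed dataset on which PCA and MNF must disagree: a group of
#' channels carries high-variance but spatially white (iid across spots)
#' intensity — large variance, no spatial signal — while a disjoint group
#' carries a low-amplitude spatially smooth component. PCA's first band
#' chases the variance; MNF's first band recovers the smooth map.
#'
#' @param seed integer RNG seed.
#' @return list with `grid` and `pattern` (the planted smooth spatial map,
#'   one value per spot).
#' @export
adversarialFixture <- function(seed = 1L) {
    set.seed(seed)
    nr <- 30L; nc <- 30L; p <- 100L
    n <- nr * nc
    coords <- expand.grid(col = 0:(nc - 1L), row = 0:(nr - 1L))
    ## smooth component: Gaussian disk, unit spatial variance
    cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
    v <- exp(-((coords$col - cx)^2 + (coords$row - cy)^2) / (2 * 6^2))
    v <- (v - mean(v)) / stats::sd(v)
    loadSmooth <- numeric(p)
    loadSmooth[21:50] <- stats::runif(30, 0.5, 1.5)
    X <- outer(v, loadSmooth)
    ## high-variance, channel-coherent but spatially white block: a common
    ## iid-across-spots field drives 20 channels, so its variance is large
    ## and concentrated in one direction — exactly what PCA chases
    w <- stats::rnorm(n, sd = 5)
    X[, 1:20] <- X[, 1:20] + outer(w, stats::runif(20, 0.8, 1.2))
    ## mild global noise
    X <- X + matrix(stats::rnorm(n * p, sd = 0.2), n, p)
    X <- X - min(X)
    grid <- SpectrumGrid(X, coords = coords,
                         mz = seq(1000, 26000, length.out = p))
    list(grid = grid, pattern = v[order(coords$row, coords$col)])
}

#' Match band score maps to planted patterns
#'
#' Greedy assignment of decomposition bands to planted spatial patterns by
#' absolute Pearson correlation: the best-correlated (pattern, band) pair
#' is matched first, then removed, and so on.
#'
#' @param scores `n x K` band-score matrix.
#' @param patterns `n x q` planted pattern matrix.
#' @return numeric vector of length `q`: `|r|` of each pattern with its
#'   matched band.
#' @export
matchPatternCorrelations <- function(scores, patterns) {
    scores <- as.matrix(scores); patterns <- as.matrix(patterns)
    q <- ncol(patterns)
    C <- abs(stats::cor(patterns, scores))
    out <- numeric(q)
    for (step in seq_len(min(q, ncol(scores)))) {
        ij <- arrayInd(which.max(C), dim(C))
        out[ij[1L]] <- C[ij[1L], ij[2L]]
        C[ij[1L], ] <- -1
        C[, ij[2L]] <- -1
    }
    out
}
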