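#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpectrumGrid: a spot-grid of mass spectra
#'
#' An imaging mass spectrometry dataset: one mass spectrum per spot of a
#' (possibly partially occupied) rectangular grid over a tissue section, all
#' spectra sharing a common m/z axis. Implemented as a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with channels (m/z values) as rows and spots as columns: `rowData` holds
#' the `mz` axis, `colData` holds the 0-based integer grid coordinates
#' `col` and `row` (row increases downward in rendered images), and the
#' single assay `"intensity"` is the `p x n` intensity matrix.
#'
#' Spots are kept in row-major grid order (by `row`, then `col`). Grid
#' positions need not fill the bounding rectangle — tissue outlines are
#' irregular — and empty positions are simply absent from `colData`.
#'
#' @section Validity:
#' * no two spots share a `(col, row)` position;
#' * `mz` is strictly increasing and matches the assay row count;
#' * coordinates are non-negative integers.
#'
#' @seealso [SpectrumGrid()] to construct, [readSpectrumGrid()] to read
#'   imzML or delimited matrix files, [spectraMatrix()], [mzAxis()],
#'   [gridCoords()].
#' @export
setClass("SpectrumGrid", contains = "SummarizedExperiment")

setValidity("SpectrumGrid", function(object) {
    cd <- colData(object)
    rd <- rowData(object)
    msg <- character()
    if (!all(c("col", "row") %in% colnames(cd)))
        msg <- c(msg, "colData must contain integer columns 'col' and 'row'")
    if (!("mz" %in% colnames(rd)))
        msg <- c(msg, "rowData must contain an 'mz' column")
    if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'intensity' is required")
    if (length(msg))
        return(msg)
    mz <- rd$mz
    if (length(mz) > 1L && any(diff(mz) <= 0))
        msg <- c(msg, "mz axis must be strictly increasing")
    if (any(cd$col < 0L) || any(cd$row < 0L))
        msg <- c(msg, "grid coordinates must be non-negative integers")
    key <- paste(cd$col, cd$row)
    if (anyDuplicated(key)) {
        d <- key[duplicated(key)][1L]
        msg <- c(msg, paste0("duplicate spot at (col,row) = (",
                             sub(" ", ",", d), ")"))
    }
    if (length(msg)) msg else TRUE
})

#' BandDecomposition: PCA or MNF bands of a spectrum grid
#'
#' Holds the result of a linear band decomposition: the `p x K` matrix of
#' loading vectors (columns `a_1..a_K`), the descending eigenvalues
#' (variances for PCA; (signal+noise)/noise ratios for MNF), the `n x K`
#' per-spot band scores computed on mean-centred spectra (the band images in
#' vector form; a 0-row matrix when the decomposition was computed from
#' covariance matrices alone), the method tag, and the channel indices of
#' the original grid the decomposition was computed on.
#'
#' @slot vectors `p x K` numeric matrix of loadings.
#' @slot eigenvalues descending numeric vector of length `K`.
#' @slot scores `n x K` (or `0 x K`) numeric matrix of per-spot scores.
#' @slot method `"pca"` or `"mnf"`.
#' @slot channels integer vector of 1-based channel indices used.
#' @seealso [pcaBands()], [mnfBands()], [selectBands()], [writeBands()].
#' @export
setClass("BandDecomposition",
    representation(vectors = "matrix", eigenvalues = "numeric",
                   scores = "matrix", method = "character",
                   channels = "integer"))

setValidity("BandDecomposition", function(object) {
    msg <- character()
    K <- length(object@eigenvalues)
    if (ncol(object@vectors) != K)
        msg <- c(msg, "ncol(vectors) must equal length(eigenvalues)")
    if (ncol(object@scores) != K && nrow(object@scores) > 0L)
        msg <- c(msg, "ncol(scores) must equal length(eigenvalues)")
    if (!(object@method %in% c("pca", "mnf")))
        msg <- c(msg, "method must be 'pca' or 'mnf'")
    ev <- object@eigenvalues
    if (K > 1L && any(diff(ev) > 1e-12 * max(abs(ev), 1)))
        msg <- c(msg, "eigenvalues must be sorted in descending order")
    if (object@method == "mnf" && K > 0L &&
        min(ev) < -1e-10 * max(abs(ev), 1))
        msg <- c(msg, "MNF eigenvalues must be non-negative (up to slack)")
    if (length(object@channels) && length(object@channels) != nrow(object@vectors))
        msg <- c(msg, "length(channels) must equal nrow(vectors)")
    if (length(msg)) msg else TRUE
})

#' ResidualGrid: local-linear pseudo-residuals per spot and channel
#'
#' The pseudo-residual at a spot is the observed intensity minus the mean of
#' its available axial (distance-1 horizontal/vertical) neighbours — the
#' prediction of a local linear fit on a regular grid. Spots with no
#' neighbour at all carry no noise information and are flagged invalid;
#' covariance estimation skips them.
#'
#' @slot residuals `n x p'` numeric matrix of pseudo-residuals (rows for
#'   invalid spots are zero-filled and must be ignored).
#' @slot valid logical, per spot: at least one axial neighbour existed.
#' @slot neighbourCounts integer 0–4 per spot.
#' @slot channels integer channel indices of the parent grid.
#' @seealso [pseudoResiduals()], [noiseCovariance()].
#' @export
setClass("ResidualGrid",
    representation(residuals = "matrix", valid = "logical",
                   neighbourCounts = "integer", channels = "integer"))

setValidity("ResidualGrid", function(object) {
    msg <- character()
    n <- nrow(object@residuals)
    if (length(object@valid) != n || length(object@neighbourCounts) != n)
        msg <- c(msg, "valid and neighbourCounts must have one entry per spot")
    if (any(object@neighbourCounts > 4L) || any(object@neighbourCounts < 0L))
        msg <- c(msg, "neighbourCounts must be in 0..4")
    if (any(object@valid & object@neighbourCounts == 0L))
        msg <- c(msg, "spots with 0 neighbours cannot be valid")
    if (length(msg)) msg else TRUE
})

#' CovariancePair: spectrum and noise covariance estimates
#'
#' The two `p x p` sample covariance matrices the MNF transform needs:
#' `SZ`, the ordinary sample covariance of the spectra, and `SN`, the sample
#' covariance of the local-linear pseudo-residuals (the spatial noise
#' covariance estimate), plus the channel mean spectrum.
#'
#' @slot SZ `p x p` symmetric spectrum covariance.
#' @slot SN `p x p` symmetric noise covariance.
#' @slot mean length-`p` channel mean vector.
#' @slot nSpots number of spots entering `SZ`.
#' @slot nValidResiduals number of residual rows entering `SN`.
#' @seealso [covariancePair()], [sampleCovariance()], [noiseCovariance()].
#' @export
setClass("CovariancePair",
    representation(SZ = "matrix", SN = "matrix", mean = "numeric",
                   nSpots = "integer", nValidResiduals = "integer"))

setValidity("CovariancePair", function(object) {
    msg <- character()
    for (nm in c("SZ", "SN")) {
        M <- slot(object, nm)
        if (nrow(M) != ncol(M))
            msg <- c(msg, paste(nm, "must be square"))
        else {
            sc <- max(abs(M), 1e-300)
            if (max(abs(M - t(M))) > 1e-12 * sc)
                msg <- c(msg, paste(nm, "must be symmetric to 1e-12 relative"))
            if (min(diag(M)) < -1e-12 * sc)
                msg <- c(msg, paste(nm, "diagonal must be non-negative"))
        }
    }
    if (length(object@mean) != nrow(object@SZ))
        msg <- c(msg, "mean length must match SZ dimension")
    if (length(msg)) msg else TRUE
})

#' ClusterResult: hierarchical clustering of spots in band space
#'
#' @slot labels integer cluster id per spot, canonically relabelled so that
#'   label 1 is the largest cluster (ties broken by smallest member index).
#' @slot k number of clusters.
#' @slot linkageMethod linkage used (`"ward"`, `"complete"`, `"average"`).
#' @slot meanSpectra `k x p` matrix of per-cluster mean spectra of the grid
#'   the clustering was paired with (background-corrected when clustering a
#'   preprocessed grid).
#' @seealso [clusterSpots()], [hclusterSpots()], [clusterMeanSpectra()].
#' @export
setClass("ClusterResult",
    representation(labels = "integer", k = "integer",
                   linkageMethod = "character", meanSpectra = "matrix"))

setValidity("ClusterResult", function(object) {
    msg <- character()
    k <- object@k
    if (length(object@labels) &&
        !identical(sort(unique(object@labels)), seq_len(k)))
        msg <- c(msg, "label set must be exactly {1..k}")
    if (nrow(object@meanSpectra) && nrow(object@meanSpectra) != k)
        msg <- c(msg, "meanSpectra must have one row per cluster")
    if (length(msg)) msg else TRUE
})

#' @describeIn SpectrumGrid-class compact display.
#' @param object a `SpectrumGrid`.
#' @export
setMethod("show", "SpectrumGrid", function(object) {
    cd <- colData(object)
    mz <- rowData(object)$mz
    nc <- if (nrow(cd)) max(cd$col) + 1L else 0L
    nr <- if (nrow(cd)) max(cd$row) + 1L else 0L
    cat(sprintf("SpectrumGrid: %d spots x %d channels\n", ncol(object),
                nrow(object)))
    cat(sprintf("  grid bounding box %d cols x %d rows (%.0f%% occupied)\n",
                nc, nr, if (nc * nr > 0) 100 * ncol(object) / (nc * nr) else 0))
    if (length(mz))
        cat(sprintf("  m/z range %.6g .. %.6g\n", mz[1L], mz[length(mz)]))
    invisible(NULL)
})

#' @describeIn BandDecomposition-class compact display.
#' @param object a `BandDecomposition`.
#' @export
setMethod("show", "BandDecomposition", function(object) {
    K <- length(object@eigenvalues)
    cat(sprintf("BandDecomposition (%s): %d band%s over %d channels\n",
                object@method, K, if (K == 1L) "" else "s",
                nrow(object@vectors)))
    ev <- signif(object@eigenvalues, 5)
    cat("  eigenvalues:", paste(utils::head(ev, 6L), collapse = ", "),
        if (K > 6L) "..." else "", "\n")
    if (object@method == "mnf" && K)
        cat("  SNR (lambda - 1):",
            paste(utils::head(signif(object@eigenvalues - 1, 5), 6L),
                  collapse = ", "),
            if (K > 6L) "..." else "", "\n")
    cat(sprintf("  scores: %d spots\n", nrow(object@scores)))
    invisible(NULL)
})

#' @describeIn ResidualGrid-class compact display.
#' @param object a `ResidualGrid`.
#' @export
setMethod("show", "ResidualGrid", function(object) {
    cat(sprintf("ResidualGrid: %d spots x %d channels (%d valid spots)\n",
                nrow(object@residuals), ncol(object@residuals),
                sum(object@valid)))
    invisible(NULL)
})

#' @describeIn CovariancePair-class compact display.
#' @param object a `CovariancePair`.
#' @export
setMethod("show", "CovariancePair", function(object) {
    cat(sprintf(
        "CovariancePair: %d channels; SZ from %d spots, SN from %d residuals\n",
        nrow(object@SZ), object@nSpots, object@nValidResiduals))
    invisible(NULL)
})

#' @describeIn ClusterResult-class compact display.
#' @param object a `ClusterResult`.
#' @export
setMethod("show", "ClusterResult", function(object) {
    sz <- tabulate(object@labels, object@k)
    cat(sprintf("ClusterResult: %d spots in %d clusters (%s linkage)\n",
                length(object@labels), object@k, object@linkageMethod))
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
    invisible(NULL)
})
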