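#' @include AllClasses.R
NULL

#' Spot-by-channel intensity matrix
#'
#' Returns the intensities of a [SpectrumGrid] as a dense numeric matrix with
#' one row per spot (in row-major grid order) and one column per m/z channel.
#'
#' @param x a `SpectrumGrid`.
#' @return an `n x p` numeric matrix.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Replace the intensity matrix of a grid
#'
#' @param x a `SpectrumGrid`.
#' @param value an `n x p` numeric matrix (spots by channels).
#' @return the modified `SpectrumGrid`.
#' @export
setGeneric("spectraMatrix<-", function(x, value) standardGeneric("spectraMatrix<-"))

#' m/z axis of a grid
#'
#' @param x a `SpectrumGrid`.
#' @return ascending numeric vector of mass-to-charge values (Da/e).
#' @export
setGeneric("mzAxis", function(x) standardGeneric("mzAxis"))

#' Spot grid coordinates
#'
#' @param x a `SpectrumGrid`.
#' @return a `data.frame` with integer columns `col` and `row` (0-based),
#'   one row per spot, in row-major grid order.
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))

#' Number of spots / channels
#'
#' @param x a `SpectrumGrid`.
#' @return integer count.
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname nSpots
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Principal component bands
#'
#' Computes the top-`K` eigenpairs of the spectrum covariance; see the
#' method documentation.
#'
#' @param object a symmetric covariance matrix or a `SpectrumGrid`.
#' @param K number of bands.
#' @param ... passed to methods.
#' @return a [BandDecomposition-class].
#' @export
setGeneric("pcaBands", function(object, K, ...) standardGeneric("pcaBands"))

#' Minimum noise fraction bands
#'
#' Solves the generalised eigenproblem `SZ a = lambda SN a`; see the method
#' documentation.
#'
#' @param object a symmetric covariance matrix `SZ` or a `SpectrumGrid`.
#' @param K number of bands.
#' @param ... passed to methods.
#' @return a [BandDecomposition-class].
#' @export
setGeneric("mnfBands", function(object, K, ...) standardGeneric("mnfBands"))

#' Local-linear pseudo-residuals on the spot grid
#'
#' @param x a `SpectrumGrid`.
#' @param channels optional integer channel indices (default all).
#' @return a [ResidualGrid-class].
#' @export
setGeneric("pseudoResiduals", function(x, channels = NULL)
    standardGeneric("pseudoResiduals"))

#' Band loading vectors
#' @param x a `BandDecomposition`.
#' @return `p x K` matrix, one column per band.
#' @export
setGeneric("bandVectors", function(x) standardGeneric("bandVectors"))

#' Band eigenvalues
#'
#' For PCA bands these are variances; for MNF bands they are
#' (signal + noise) / noise ratios of the generalised eigenproblem.
#'
#' @param x a `BandDecomposition`.
#' @return descending numeric vector of length `K`.
#' @export
setGeneric("bandEigenvalues", function(x) standardGeneric("bandEigenvalues"))

#' Per-spot band scores
#' @param x a `BandDecomposition`.
#' @return `n x K` matrix of band scores (band images in vector form).
#' @export
setGeneric("bandScores", function(x) standardGeneric("bandScores"))

#' Band signal-to-noise ratios
#'
#' For MNF bands, the eigenvalue parameterisation of the generalised
#' eigenproblem is `lambda = (signal + noise) / noise`, so the
#' signal-to-noise ratio proper is `lambda - 1`. For PCA bands an error is
#' raised: PCA eigenvalues are variances and carry no noise information.
#'
#' @param x a `BandDecomposition` with method `"mnf"`.
#' @return numeric vector `lambda - 1`.
#' @export
setGeneric("bandSNR", function(x) standardGeneric("bandSNR"))

#' Cluster labels
#' @param x a `ClusterResult`.
#' @return integer vector of labels in `1..k`.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Per-cluster mean spectra
#' @param x a `ClusterResult`.
#' @return `k x p` matrix, row `j` the mean spectrum of cluster `j`.
#' @export
setGeneric("meanSpectra", function(x) standardGeneric("meanSpectra"))
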