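#' @include transforms.R
#' @importFrom stats hclust dist cutree
NULL

## Canonical relabelling: label 1 = largest cluster, ties broken by the
## smallest member spot index. Makes labels invariant to input spot order.
.canonicalLabels <- function(raw) {
    ids <- sort(unique(raw))
    size <- vapply(ids, function(i) sum(raw == i), integer(1L))
    first <- vapply(ids, function(i) which(raw == i)[1L], integer(1L))
    ord <- order(-size, first)
    map <- integer(max(ids))
    map[ids[ord]] <- seq_along(ids)
    map[raw]
}

#' Hierarchical clustering of spots in band space
#'
#' Agglomerative clustering of the spots using Euclidean distance on their
#' band scores, with the tree cut at `k` clusters. `"ward"` linkage uses
#' the Ward criterion on Euclidean distances (`stats::hclust` method
#' `"ward.D2"`). Labels are relabelled canonically by decreasing cluster
#' size (ties by smallest member spot index).
#'
#' @param scores `n x K` band-score matrix (rows = spots).
#' @param k number of clusters, `1 <= k <= n`.
#' @param linkage `"ward"` (default), `"complete"` or `"average"`.
#' @return integer label vector of length `n` with values in `1..k`.
#' @export
hclusterSpots <- function(scores, k, linkage = c("ward", "complete",
                                                 "average")) {
    linkage <- match.arg(linkage)
    scores <- as.matrix(scores)
    n <- nrow(scores)
    k <- as.integer(k)
    if (k < 1L) stop("k must be at least 1")
    if (k > n) stop("k = ", k, " exceeds the number of spots (", n, ")")
    if (k == n) return(seq_len(n))
    method <- c(ward = "ward.D2", complete = "complete",
                average = "average")[[linkage]]
    hc <- stats::hclust(stats::dist(scores), method = method)
    .canonicalLabels(stats::cutree(hc, k = k))
}

#' Per-cluster mean spectra
#'
#' Channel-wise arithmetic mean of the spectra belonging to each cluster,
#' computed on whatever grid is passed in (pass the background-corrected
#' grid to reproduce "average background-corrected spectrum per cluster"
#' summaries).
#'
#' @param grid a `SpectrumGrid` with `n` spots.
#' @param labels integer labels in `1..k`, one per spot; every label in
#'   the range must occur.
#' @return `k x p` matrix, row `j` the mean spectrum of cluster `j`.
#' @export
clusterMeanSpectra <- function(grid, labels) {
    stopifnot(is(grid, "SpectrumGrid"))
    labels <- as.integer(labels)
    n <- nSpots(grid)
    if (length(labels) != n)
        stop("labels length (", length(labels), ") must equal spot count (",
             n, ")")
    k <- max(labels)
    if (min(labels) < 1L)
        stop("labels must be positive integers in 1..k")
    cnt <- tabulate(labels, k)
    if (any(cnt == 0L))
        stop("label ", which(cnt == 0L)[1L], " is absent from 1..", k)
    m <- spectraMatrix(grid)
    out <- matrix(0, k, ncol(m))
    for (j in seq_len(k))
        out[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    out
}

#' Cluster spots on MNF/PCA bands and summarise clusters
#'
#' Convenience wrapper around [hclusterSpots()] and
#' [clusterMeanSpectra()]: clusters the spots on the first `nBands` band
#' scores of `bands` and attaches per-cluster mean spectra of `grid`.
#'
#' @param bands a `BandDecomposition` with per-spot scores.
#' @param grid the (typically background-corrected) `SpectrumGrid` to
#'   average per cluster.
#' @param k number of clusters.
#' @param nBands how many leading bands to cluster on (default all).
#' @param linkage passed to [hclusterSpots()].
#' @return a [ClusterResult-class].
#' @export
clusterSpots <- function(bands, grid, k, nBands = NULL,
                         linkage = c("ward", "complete", "average")) {
    stopifnot(is(bands, "BandDecomposition"), is(grid, "SpectrumGrid"))
    linkage <- match.arg(linkage)
    sc <- bandScores(bands)
    if (nrow(sc) != nSpots(grid))
        stop("band scores and grid disagree on the number of spots")
    if (!is.null(nBands)) {
        nBands <- as.integer(nBands)
        if (nBands < 1L || nBands > ncol(sc))
            stop("nBands must be in 1..", ncol(sc))
        sc <- sc[, seq_len(nBands), drop = FALSE]
    }
    labels <- hclusterSpots(sc, k, linkage)
    new("ClusterResult", labels = labels, k = as.integer(k),
        linkageMethod = linkage,
        meanSpectra = clusterMeanSpectra(grid, labels))
}

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname meanSpectra
#' @export
setMethod("meanSpectra", "ClusterResult", function(x) x@meanSpectra)

#' Write cluster outputs
#'
#' Emits `<prefix>_labels.csv` (`col, row, cluster`), a cluster map PNG
#' `<prefix>_clusters.png` (one colour per cluster, empty grid positions
#' transparent) and `<prefix>_mean_spectra.csv` (`cluster, <mz...>`).
#'
#' @param result a `ClusterResult`.
#' @param grid the matching `SpectrumGrid`.
#' @param prefix output path prefix.
#' @return files written, invisibly.
#' @export
writeClusterResult <- function(result, grid, prefix) {
    stopifnot(is(result, "ClusterResult"), is(grid, "SpectrumGrid"))
    labels <- clusterLabels(result)
    if (length(labels) != nSpots(grid))
        stop("cluster result and grid disagree on the number of spots")
    cc <- gridCoords(grid)
    labFile <- paste0(prefix, "_labels.csv")
    writeLines(c("col,row,cluster",
                 sprintf("%d,%d,%d", cc$col, cc$row, labels)),
               labFile, useBytes = TRUE)
    ms <- meanSpectra(result)
    msFile <- paste0(prefix, "_mean_spectra.csv")
    header <- paste(c("cluster", sprintf("%.17g", mzAxis(grid))),
                    collapse = ",")
    body <- vapply(seq_len(nrow(ms)), function(j)
        paste(c(sprintf("%d", j), sprintf("%.17g", ms[j, ])), collapse = ","),
        character(1L))
    writeLines(c(header, body), msFile, useBytes = TRUE)
    occ <- occupancyIndex(grid)
    k <- result@k
    pal <- grDevices::hcl(h = seq(15, 375, length.out = k + 1L)[-(k + 1L)],
                          c = 100, l = 65)
    rgbCols <- grDevices::col2rgb(pal) / 255
    img <- array(0, dim = c(nrow(occ), ncol(occ), 4L))
    ok <- !is.na(occ)
    lab <- matrix(NA_integer_, nrow(occ), ncol(occ))
    lab[ok] <- labels[occ[ok]]
    for (ch in 1:3) {
        plane <- matrix(0, nrow(occ), ncol(occ))
        plane[ok] <- rgbCols[ch, lab[ok]]
        img[, , ch] <- plane
    }
    img[, , 4L] <- ifelse(ok, 1, 0)
    mapFile <- paste0(prefix, "_clusters.png")
    png::writePNG(img, mapFile)
    invisible(c(labFile, msFile, mapFile))
}
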