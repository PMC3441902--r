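#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SpectrumGrid
#'
#' @param intensities `n x p` numeric matrix, one row per spot, one column
#'   per m/z channel.
#' @param coords data.frame (or two-column matrix) of 0-based integer grid
#'   positions `col`, `row`, one row per spot.
#' @param mz strictly increasing numeric vector of length `p`.
#' @return a [SpectrumGrid-class] with spots in canonical row-major grid
#'   order (sorted by `row`, then `col`) regardless of input order.
#' @examples
#' g <- SpectrumGrid(matrix(1:12, 4, 3),
#'                   coords = data.frame(col = c(0, 1, 0, 1),
#'                                       row = c(0, 0, 1, 1)),
#'                   mz = c(100, 200, 300))
#' nSpots(g)
#' @export
SpectrumGrid <- function(intensities, coords, mz) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    dimnames(intensities) <- NULL
    coords <- as.data.frame(coords)
    if (!all(c("col", "row") %in% names(coords)))
        names(coords)[1:2] <- c("col", "row")
    if (any(coords$col != round(coords$col)) ||
        any(coords$row != round(coords$row)))
        stop("grid coordinates must be integers")
    coords$col <- as.integer(coords$col)
    coords$row <- as.integer(coords$row)
    if (nrow(coords) != nrow(intensities))
        stop("one coordinate pair per spot is required: ", nrow(coords),
             " coords vs ", nrow(intensities), " spectra")
    mz <- as.numeric(mz)
    if (length(mz) != ncol(intensities))
        stop("length(mz) must equal the number of channels: ", length(mz),
             " vs ", ncol(intensities))
    key <- paste(coords$col, coords$row)
    if (anyDuplicated(key)) {
        d <- coords[duplicated(key), , drop = FALSE][1L, ]
        stop("duplicate spot at (col,row) = (", d$col, ",", d$row, ")")
    }
    ord <- order(coords$row, coords$col)
    se <- SummarizedExperiment(
        assays = list(intensity = t(intensities[ord, , drop = FALSE])),
        rowData = DataFrame(mz = mz),
        colData = DataFrame(col = coords$col[ord], row = coords$row[ord]))
    new("SpectrumGrid", se)
}

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectrumGrid", function(x)
    t(assay(x, "intensity")))

#' @rdname spectraMatrix-set
#' @name spectraMatrix<-
#' @aliases spectraMatrix<-,SpectrumGrid-method
#' @export
setReplaceMethod("spectraMatrix", "SpectrumGrid", function(x, value) {
    value <- as.matrix(value)
    if (!identical(dim(value), dim(spectraMatrix(x))))
        stop("replacement matrix must be ", ncol(x), " x ", nrow(x))
    SummarizedExperiment::assay(x, "intensity") <- t(value)
    x
})

#' @rdname mzAxis
#' @export
setMethod("mzAxis", "SpectrumGrid", function(x) rowData(x)$mz)

#' @rdname gridCoords
#' @export
setMethod("gridCoords", "SpectrumGrid", function(x) {
    cd <- colData(x)
    data.frame(col = cd$col, row = cd$row)
})

#' @rdname nSpots
#' @export
setMethod("nSpots", "SpectrumGrid", function(x) ncol(x))

#' @rdname nSpots
#' @export
setMethod("nChannels", "SpectrumGrid", function(x) nrow(x))

#' Select channels of a grid
#'
#' @param x a `SpectrumGrid`.
#' @param channels integer vector of 1-based channel indices to keep.
#' @return a `SpectrumGrid` restricted to those channels.
#' @export
selectChannels <- function(x, channels) {
    stopifnot(is(x, "SpectrumGrid"))
    channels <- as.integer(channels)
    if (any(channels < 1L) || any(channels > nChannels(x)))
        stop("channel indices out of range 1..", nChannels(x))
    x[channels, ]
}

#' Occupancy index of the grid bounding box
#'
#' @param x a `SpectrumGrid`.
#' @return an integer matrix of dimensions (max row + 1) x (max col + 1);
#'   entry `[r+1, c+1]` is the spot index at grid position `(c, r)`, or
#'   `NA` for an empty position.
#' @export
occupancyIndex <- function(x) {
    cc <- gridCoords(x)
    m <- matrix(NA_integer_, nrow = max(cc$row) + 1L, ncol = max(cc$col) + 1L)
    m[cbind(cc$row + 1L, cc$col + 1L)] <- seq_len(nrow(cc))
    m
}

## ---- delimited matrix format -------------------------------------------

#' Read a spot-grid of spectra
#'
#' Reads an imaging MS dataset into a [SpectrumGrid-class]. Two formats are
#' supported:
#' * `"matrix"` — UTF-8, comma-delimited text, header
#'   `col,row,<mz1>,...,<mzp>` carrying the m/z axis, one data row per spot
#'   (`col`, `row`, then `p` intensities);
#' * `"imzml"` — continuous-mode imzML 1.1 (shared m/z axis; the binary
#'   `.ibd` companion must sit next to the XML file). Processed-mode files
#'   are rejected: binning spectra onto a common axis is a preprocessing
#'   decision this package does not take silently.
#'
#' Spots are returned in canonical row-major grid order whatever the file
#' order, so reader output is independent of input row order.
#'
#' @param path file path.
#' @param format `"matrix"` or `"imzml"` (default guessed from the
#'   extension: `.imzml` vs anything else).
#' @return a [SpectrumGrid-class].
#' @seealso [writeSpectrumGrid()], [writeBands()]
#' @export
readSpectrumGrid <- function(path, format = c("auto", "matrix", "imzml")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("input file does not exist: ", path)
    if (format == "auto")
        format <- if (grepl("\\.imzml$", path, ignore.case = TRUE))
            "imzml" else "matrix"
    switch(format,
        matrix = .readMatrixGrid(path),
        imzml = .readImzML(path))
}

.readMatrixGrid <- function(path) {
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
    if (length(header) < 3L || tolower(header[1L]) != "col" ||
        tolower(header[2L]) != "row")
        stop("matrix format requires header 'col,row,<mz values>': ", path)
    mz <- suppressWarnings(as.numeric(header[-(1:2)]))
    if (anyNA(mz))
        stop("non-numeric m/z value in header of ", path)
    if (length(mz) > 1L && any(diff(mz) <= 0))
        stop("m/z axis in header must be strictly increasing")
    dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = ",",
                            colClasses = "numeric", showProgress = FALSE)
    if (ncol(dt) != length(mz) + 2L)
        stop("row width does not match header: expected ", length(mz) + 2L,
             " fields, found ", ncol(dt))
    m <- as.matrix(dt)
    SpectrumGrid(m[, -(1:2), drop = FALSE],
                 coords = data.frame(col = m[, 1L], row = m[, 2L]),
                 mz = mz)
}

#' Write a grid in the delimited matrix format
#'
#' Emits the comma-delimited text format read by
#' `readSpectrumGrid(format = "matrix")`. Floats are serialised with 17
#' significant digits so that a write/read round trip reproduces
#' coordinates, m/z axis and intensities bit-exactly.
#'
#' @param x a `SpectrumGrid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrumGrid <- function(x, path) {
    stopifnot(is(x, "SpectrumGrid"))
    cc <- gridCoords(x)
    header <- paste(c("col", "row", sprintf("%.17g", mzAxis(x))),
                    collapse = ",")
    m <- spectraMatrix(x)
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(sprintf("%d", cc$col[i]), sprintf("%d", cc$row[i]),
                sprintf("%.17g", m[i, ])), collapse = ","),
        character(1L))
    writeLines(c(header, body), path, useBytes = TRUE)
    invisible(path)
}

## ---- band output -------------------------------------------------------

#' Write band-score tables and band images
#'
#' Emits (a) a per-spot delimited table `<prefix>_scores.csv` with columns
#' `col, row, band1..bandK` and (b) one greyscale PNG per band,
#' `<prefix>_band<k>.png`, rendering each band's per-spot scores on the
#' grid bounding box. Empty grid positions are rendered as transparent
#' background, not as zero score. Scores are written with 17 significant
#' digits.
#'
#' @param bands a [BandDecomposition-class] with per-spot scores.
#' @param grid the `SpectrumGrid` the scores belong to (row count must
#'   match).
#' @param prefix output path prefix (directory must exist).
#' @return character vector of the files written, invisibly.
#' @export
writeBands <- function(bands, grid, prefix) {
    stopifnot(is(bands, "BandDecomposition"), is(grid, "SpectrumGrid"))
    sc <- bandScores(bands)
    if (nrow(sc) != nSpots(grid))
        stop("band scores have ", nrow(sc), " rows but the grid has ",
             nSpots(grid), " spots")
    cc <- gridCoords(grid)
    K <- ncol(sc)
    tab <- file.path(paste0(prefix, "_scores.csv"))
    header <- paste(c("col", "row", paste0("band", seq_len(K))),
                    collapse = ",")
    body <- vapply(seq_len(nrow(sc)), function(i)
        paste(c(sprintf("%d", cc$col[i]), sprintf("%d", cc$row[i]),
                sprintf("%.17g", sc[i, ])), collapse = ","),
        character(1L))
    writeLines(c(header, body), tab, useBytes = TRUE)
    occ <- occupancyIndex(grid)
    files <- tab
    for (k in seq_len(K)) {
        img <- .scoresToRaster(sc[, k], occ)
        f <- paste0(prefix, "_band", k, ".png")
        png::writePNG(img, f)
        files <- c(files, f)
    }
    invisible(files)
}

## Greyscale + alpha raster: occupied pixels span [0,1] by min-max scaling,
## empty positions are fully transparent.
.scoresToRaster <- function(scores, occ) {
    v <- matrix(NA_real_, nrow(occ), ncol(occ))
    ok <- !is.na(occ)
    v[ok] <- scores[occ[ok]]
    rng <- range(v, na.rm = TRUE)
    g <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0 + 0.5
    img <- array(0, dim = c(nrow(occ), ncol(occ), 2L))
    img[, , 1L] <- ifelse(ok, g, 0)
    img[, , 2L] <- ifelse(ok, 1, 0)
    img
}
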