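test_that("construction enforces the grid invariants", {
    g <- makeFullGrid(matrix(1:12, 4, 3), nCols = 2, nRows = 2,
                      mz = c(100, 200, 300))
    expect_s4_class(g, "SpectrumGrid")
    expect_equal(nSpots(g), 4L)
    expect_equal(nChannels(g), 3L)
    expect_equal(mzAxis(g), c(100, 200, 300))

    # partial occupancy: 3 of 4 positions of a 2x2 box
    gp <- SpectrumGrid(matrix(rnorm(9), 3, 3),
                       coords = data.frame(col = c(0, 1, 0),
                                           row = c(0, 0, 1)),
                       mz = 1:3)
    expect_equal(nSpots(gp), 3L)
    occ <- occupancyIndex(gp)
    expect_true(is.na(occ[2, 2]))
    expect_equal(sum(!is.na(occ)), 3L)

    expect_error(
        SpectrumGrid(matrix(0, 2, 2),
                     coords = data.frame(col = c(1, 1), row = c(1, 1)),
                     mz = 1:2),
        "duplicate spot")
    expect_error(
        SpectrumGrid(matrix(0, 2, 2),
                     coords = data.frame(col = 0:1, row = c(0, 0)),
                     mz = c(2, 1)),
        "increasing")
    expect_error(
        SpectrumGrid(matrix(0, 2, 3),
                     coords = data.frame(col = 0:1, row = c(0, 0)),
                     mz = 1:2),
        "length")
})

test_that("spots are canonicalised to row-major order regardless of input order", {
    X <- matrix(rnorm(12), 4, 3)
    coords <- data.frame(col = c(1, 0, 1, 0), row = c(1, 1, 0, 0))
    g <- SpectrumGrid(X, coords, mz = 1:3)
    cc <- gridCoords(g)
    expect_equal(cc$row, c(0, 0, 1, 1))
    expect_equal(cc$col, c(0, 1, 0, 1))
    # spectrum follows its coordinate: spot (0,0) was input row 4
    expect_equal(spectraMatrix(g)[1, ], X[4, ])
})

test_that("matrix format round-trips bit-exactly and ignores row order", {
    set.seed(1)
    g <- makeFullGrid(matrix(rnorm(15) * 1e3, 5, 3)[, ],
                      nCols = 5, nRows = 1,
                      mz = c(1000.123456789012, 2000.5, 26000))
    f <- tempfile(fileext = ".csv")
    writeSpectrumGrid(g, f)
    g2 <- readSpectrumGrid(f, format = "matrix")
    expect_identical(spectraMatrix(g2), spectraMatrix(g))
    expect_identical(mzAxis(g2), mzAxis(g))
    expect_identical(gridCoords(g2), gridCoords(g))

    # permute the data rows on disk: reader output must not change
    lines <- readLines(f)
    writeLines(c(lines[1], rev(lines[-1])), f)
    g3 <- readSpectrumGrid(f)
    expect_identical(spectraMatrix(g3), spectraMatrix(g))

    # malformed inputs
    f2 <- tempfile(fileext = ".csv")
    writeLines(c("col,row,2,1", "0,0,5,6"), f2)
    expect_error(readSpectrumGrid(f2), "increasing")
    writeLines(c("x,y,1,2", "0,0,5,6"), f2)
    expect_error(readSpectrumGrid(f2), "header")
    expect_error(readSpectrumGrid(tempfile()), "does not exist")
})

test_that("writeBands emits a score table and one raster per band", {
    set.seed(2)
    gp <- SpectrumGrid(matrix(rnorm(30), 3, 10),
                       coords = data.frame(col = c(0, 1, 0),
                                           row = c(0, 0, 1)),
                       mz = 1:10)
    b <- pcaBands(gp, K = 2)
    pre <- file.path(tempdir(), "bands_test")
    files <- writeBands(b, gp, pre)
    expect_length(files, 3L)
    expect_true(all(file.exists(files)))
    tab <- read.csv(files[1])
    expect_equal(dim(tab), c(3L, 4L))
    expect_equal(names(tab), c("col", "row", "band1", "band2"))
    expect_equal(unname(as.matrix(tab[, 3:4])), unname(bandScores(b)),
                 tolerance = 1e-15)
    # empty grid position is transparent background, not a zero score
    img <- png::readPNG(files[2])
    expect_equal(dim(img)[1:2], c(2L, 2L))
    expect_equal(img[2, 2, 2], 0)        # alpha 0 at the empty position
    expect_true(all(img[, , 2][!is.na(occupancyIndex(gp))] == 1))

    # K = 6 bands -> 6 deterministically named images
    b6 <- pcaBands(gp, K = 6)
    f6 <- writeBands(b6, gp, file.path(tempdir(), "bands6"))
    expect_equal(basename(f6[-1]), paste0("bands6_band", 1:6, ".png"))

    expect_error(writeBands(b, makeFullGrid(matrix(0, 4, 10), 2, 2), pre),
                 "spots")
})
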