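test_that("sample covariance matches hand values and the brute-force oracle", {
    # two spots with values {0, 1} at a channel: variance 0.5
    g2 <- makeFullGrid(cbind(c(0, 1)), 2, 1, mz = 1)
    expect_equal(sampleCovariance(g2)$SZ[1, 1], 0.5)

    # identical spots: zero matrix
    gz <- makeFullGrid(matrix(3, 4, 2), 2, 2)
    expect_equal(sampleCovariance(gz)$SZ, matrix(0, 2, 2))

    # random 5 x 3: equals the double loop to 1e-12 relative
    set.seed(20)
    X <- matrix(rnorm(15, sd = 4), 5, 3)
    g <- makeFullGrid(X, 5, 1)
    sz <- sampleCovariance(g)
    oracle <- bruteCovariance(X)
    expect_lt(max(abs(sz$SZ - oracle)) / max(abs(oracle)), 1e-12)
    expect_equal(sz$mean, colMeans(X))

    g1 <- SpectrumGrid(matrix(1, 1, 2), data.frame(col = 0, row = 0), 1:2)
    expect_error(sampleCovariance(g1), "at least 2")
})

test_that("pseudo-residuals implement the 4-neighbour local-linear fit", {
    # interior spot value 5 with neighbours 1,2,3,4 -> residual 2.5
    X <- matrix(0, 9, 1)
    # 3x3 grid row-major: centre index 5, neighbours are indices 4,6,2,8
    X[c(4, 6, 2, 8)] <- c(1, 2, 3, 4)
    X[5] <- 5
    g <- makeFullGrid(X, 3, 3)
    r <- pseudoResiduals(g)
    expect_equal(r@residuals[5, 1], 5 - 2.5)
    expect_equal(r@neighbourCounts[5], 4L)

    # corner spot with 2 neighbours (2, 4), value 3 -> residual 0
    Y <- matrix(0, 4, 1)
    Y[1] <- 3; Y[2] <- 2; Y[3] <- 4
    gc <- makeFullGrid(Y, 2, 2)
    rc <- pseudoResiduals(gc)
    expect_equal(rc@residuals[1, 1], 0)
    expect_equal(rc@neighbourCounts[1], 2L)
})

test_that("exact linear fields have zero interior residuals", {
    g <- makeLinearFieldGrid(9, 7)
    r <- pseudoResiduals(g)
    interior <- r@neighbourCounts == 4L
    expect_gt(sum(interior), 0)
    expect_lt(max(abs(r@residuals[interior, ])), 1e-10)
})

test_that("empty grid positions are treated like edges", {
    # remove the centre of a 3x3: its former neighbours lose a neighbour
    coords <- expand.grid(col = 0:2, row = 0:2)[-5, ]
    g <- SpectrumGrid(matrix(rnorm(8), 8, 1), coords, mz = 1)
    r <- pseudoResiduals(g)
    expect_true(all(r@neighbourCounts <= 2L))

    # an isolated spot is invalid and excluded
    gi <- SpectrumGrid(matrix(rnorm(3), 3, 1),
                       data.frame(col = c(0, 1, 5), row = c(0, 0, 5)), mz = 1)
    ri <- pseudoResiduals(gi)
    expect_equal(ri@valid, c(TRUE, TRUE, FALSE))
    expect_equal(ri@neighbourCounts[3], 0L)
})

test_that("pseudo-residuals are translation-equivariant per channel", {
    set.seed(21)
    g <- makeFullGrid(matrix(rnorm(40), 20, 2), 5, 4)
    r1 <- pseudoResiduals(g)
    shifted <- spectraMatrix(g)
    shifted[, 1] <- shifted[, 1] + 42
    g2 <- makeFullGrid(shifted, 5, 4)
    r2 <- pseudoResiduals(g2)
    expect_equal(r2@residuals, r1@residuals, tolerance = 1e-12)
})

test_that("noise covariance matches the brute-force oracle and is symmetric PSD", {
    set.seed(22)
    g <- makeFullGrid(matrix(rnorm(50), 10, 5), 5, 2)
    r <- pseudoResiduals(g)
    SN <- noiseCovariance(r)
    oracle <- bruteCovariance(r@residuals[r@valid, ])
    expect_lt(max(abs(SN - oracle)) / max(abs(oracle)), 1e-12)
    expect_identical(SN, t(SN))
    ev <- eigen(SN, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * sum(diag(SN)))

    # a constant field leaves nothing for the noise estimate (edge spots
    # included: averaging any number of identical neighbours is exact)
    SNconst <- noiseCovariance(pseudoResiduals(makeFullGrid(
        matrix(5, 36, 2), 6, 6)))
    expect_equal(SNconst, matrix(0, 2, 2))
})

test_that("edge-variance equalisation rescales residual rows by (1 + 1/m)^-1/2", {
    set.seed(23)
    g <- makeFullGrid(matrix(rnorm(18), 9, 2), 3, 3)
    r <- pseudoResiduals(g)
    R <- r@residuals / sqrt(1 + 1 / r@neighbourCounts)
    Rc <- sweep(R, 2, colMeans(R))
    expect_equal(noiseCovariance(r, equalizeEdgeVariance = TRUE),
                 (crossprod(Rc) + t(crossprod(Rc))) / 2 / (nrow(R) - 1),
                 tolerance = 1e-12)
})

test_that("smooth fields put far less mass in SN than in SZ", {
    # the separation the MNF exploits: a smooth field has high sample
    # variance but tiny pseudo-residual variance
    coords <- expand.grid(col = 0:19, row = 0:19)
    f <- sin(coords$col / 6) + cos(coords$row / 5)
    g <- SpectrumGrid(cbind(f, 2 * f), coords, mz = 1:2)
    SZ <- sampleCovariance(g)$SZ
    SN <- noiseCovariance(pseudoResiduals(g))
    expect_lt(sum(diag(SN)) / sum(diag(SZ)), 0.02)
})

test_that("covariancePair bundles consistent pieces", {
    set.seed(24)
    g <- makeFullGrid(matrix(rnorm(60), 12, 5), 4, 3)
    cp <- covariancePair(g, channels = c(1L, 3L, 5L))
    expect_s4_class(cp, "CovariancePair")
    expect_equal(dim(cp@SZ), c(3L, 3L))
    expect_equal(cp@SZ, sampleCovariance(g, c(1L, 3L, 5L))$SZ)
    expect_equal(cp@SN,
                 noiseCovariance(pseudoResiduals(g, c(1L, 3L, 5L))))
    expect_equal(cp@nSpots, 12L)
})
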