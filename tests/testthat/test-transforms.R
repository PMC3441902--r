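test_that("PCA of a covariance matrix returns descending orthonormal eigenpairs", {
    b <- pcaBands(diag(c(3, 1)), K = 2)
    expect_equal(bandEigenvalues(b), c(3, 1))
    expect_equal(bandVectors(b)[, 1], c(1, 0))

    # degenerate spectrum: only the eigenvalues are determined
    bi <- pcaBands(diag(4), K = 4)
    expect_equal(bandEigenvalues(bi), rep(1, 4))

    set.seed(30)
    S <- randomSPD(6)
    b6 <- pcaBands(S, K = 6)
    V <- bandVectors(b6); ev <- bandEigenvalues(b6)
    expect_equal(crossprod(V), diag(6), tolerance = 1e-8)
    for (j in 1:6)
        expect_lt(sqrt(sum((S %*% V[, j] - ev[j] * V[, j])^2)),
                  1e-10 * norm(S, "2"))
    # deterministic sign convention
    expect_true(all(apply(V, 2, function(v) v[which.max(abs(v))] > 0)))

    expect_error(pcaBands(matrix(c(1, 2, 3, 4), 2), K = 1), "symmetric")
    expect_error(pcaBands(diag(2), K = 3), "K must be")
})

test_that("MNF with identity noise reduces to PCA", {
    set.seed(31)
    S <- randomSPD(7)
    bp <- pcaBands(S, K = 7)
    bm <- mnfBands(S, K = 7, SN = diag(7))
    expect_equal(bandEigenvalues(bm), bandEigenvalues(bp), tolerance = 1e-8)
    expect_equal(abs(bandVectors(bm)), abs(bandVectors(bp)),
                 tolerance = 1e-8)
})

test_that("MNF demotes high-variance low-SNR channels", {
    # SZ = diag(4,9), SN = diag(1,9): ratios 4 and 1 — the high-variance
    # channel 2 carries no extra signal and goes last
    b <- mnfBands(diag(c(4, 9)), K = 2, SN = diag(c(1, 9)))
    expect_equal(bandEigenvalues(b), c(4, 1))
    expect_equal(bandVectors(b)[, 1], c(1, 0))
})

test_that("MNF eigenpairs satisfy the generalised eigenproblem and SN-orthonormality", {
    set.seed(32)
    SZ <- randomSPD(8); SN <- randomSPD(8)
    b <- mnfBands(SZ, K = 8, SN = SN)
    V <- bandVectors(b); ev <- bandEigenvalues(b)
    expect_equal(diff(ev) <= 1e-12, rep(TRUE, 7))
    for (j in 1:8)
        expect_lt(sqrt(sum((SZ %*% V[, j] - ev[j] * (SN %*% V[, j]))^2)),
                  1e-8 * norm(SZ, "2"))
    G <- t(V) %*% SN %*% V
    expect_equal(G, diag(8), tolerance = 1e-6)
})

test_that("a singular noise covariance errors with the rank unless ridged", {
    SZ <- diag(3)
    SN <- diag(c(1, 1, 0))
    expect_error(mnfBands(SZ, K = 2, SN = SN), "rank 2 of 3")
    expect_error(mnfBands(SZ, K = 2, SN = SN), "ridge")
    b <- mnfBands(SZ, K = 2, SN = SN, ridge = 1e-8)
    expect_s4_class(b, "BandDecomposition")
})

test_that("eigenvalues are non-increasing in the ridge parameter", {
    set.seed(33)
    SZ <- randomSPD(6); SN <- randomSPD(6, jitter = 0.1)
    ridges <- c(0, 1e-6, 1e-3, 1e-1, 1)
    lams <- sapply(ridges, function(r)
        bandEigenvalues(mnfBands(SZ, K = 6, SN = SN, ridge = r)))
    for (j in 1:6)
        expect_true(all(diff(lams[j, ]) <= 1e-10 * lams[j, 1]))
})

test_that("MNF is invariant to invertible channel transforms of the covariances", {
    set.seed(34)
    SZ <- randomSPD(5); SN <- randomSPD(5)
    T <- matrix(rnorm(25), 5)
    b0 <- mnfBands(SZ, K = 5, SN = SN)
    b1 <- mnfBands(t(T) %*% SZ %*% T, K = 5, SN = t(T) %*% SN %*% T)
    expect_equal(bandEigenvalues(b1), bandEigenvalues(b0),
                 tolerance = 1e-8)
})

test_that("grid-level decompositions carry scores on centred spectra", {
    set.seed(35)
    out <- generateGrid(synthConfig(nCols = 15, nRows = 12, p = 30, q = 2,
                                    seed = 35))
    g <- out$grid
    b <- mnfBands(g, K = 3)
    m <- spectraMatrix(g)
    mc <- sweep(m, 2, colMeans(m))
    expect_equal(bandScores(b), mc %*% bandVectors(b))
    expect_equal(colMeans(bandScores(b)), rep(0, 3), tolerance = 1e-10)
    # channel subset decompositions record their channels
    ch <- 1:10
    bs <- mnfBands(g, K = 2, channels = ch)
    expect_equal(bs@channels, ch)
    expect_equal(nrow(bandVectors(bs)), 10L)
})

test_that("top MNF bands span the planted component maps", {
    # parameter recovery: band scores are planted map plus band noise, so
    # a per-pattern correlation of at least 0.95 bounds the principal
    # angle between the two spans by acos(0.95); in the noise-free limit
    # the spans coincide
    out <- generateGrid(synthConfig(q = 2, seed = 36))
    b <- mnfBands(out$grid, K = 2)
    expect_lt(principalAngleDeg(bandScores(b), out$truth$patterns),
              acos(0.95) * 180 / pi)
    out0 <- generateGrid(synthConfig(q = 2, seed = 36, noiseSd = 1e-4,
                                     baselineAmp = 0))
    b0 <- mnfBands(out0$grid, K = 2)
    expect_lt(principalAngleDeg(bandScores(b0), out0$truth$patterns), 0.1)
})

test_that("band selection follows the variance-share and SNR-threshold rules", {
    expect_equal(selectBands(c(8, 1, 1), "pca", pctThreshold = 0.8), 1L)
    expect_equal(selectBands(c(8, 1, 1), "pca", pctThreshold = 0.81), 2L)
    expect_equal(selectBands(c(8, 1, 1), "pca", pctThreshold = 1.0), 3L)
    # lambda - 1 = 4, 1.5, 0.9, 0.2 -> 2 bands with SNR above 1
    expect_equal(selectBands(c(5, 2.5, 1.9, 1.2), "mnf",
                             snrThreshold = 1), 2L)
    # lowering the threshold below 0.9 admits the third band
    expect_equal(selectBands(c(5, 2.5, 1.9, 1.2), "mnf",
                             snrThreshold = 0.85), 3L)
    # raw-lambda scale: lambda > 1 keeps all four
    expect_equal(selectBands(c(5, 2.5, 1.9, 1.2), "mnf", snrThreshold = 1,
                             snrScale = "lambda"), 4L)
    expect_error(selectBands(c(1, 2), "pca"), "descending")
})

test_that("band accessors expose the eigenvalue parameterisation explicitly", {
    b <- mnfBands(diag(c(4, 9)), K = 2, SN = diag(c(1, 9)))
    expect_equal(bandSNR(b), c(3, 0))
    bp <- pcaBands(diag(2), K = 1)
    expect_error(bandSNR(bp), "MNF")
    f <- tempfile(fileext = ".csv")
    writeEigenvalueTable(b, f)
    tab <- read.csv(f)
    expect_equal(tab$lambda, c(4, 1))
    expect_equal(tab$snr, c(3, 0))
})
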