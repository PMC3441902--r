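test_that("log transform maps x to ln(x + offset) and validates input", {
    g <- makeFullGrid(cbind(c(0, exp(1) - 1), c(1, 3)), 2, 1, mz = 1:2)
    lt <- logTransform(g, offset = 1)
    expect_equal(spectraMatrix(lt)[1, 1], 0)           # ln(1)
    expect_equal(spectraMatrix(lt)[2, 1], 1)           # ln(e)
    expect_equal(mzAxis(lt), mzAxis(g))
    expect_identical(gridCoords(lt), gridCoords(g))

    gneg <- makeFullGrid(cbind(c(-0.5, 1), c(1, 1)), 2, 1, mz = 1:2)
    expect_error(logTransform(gneg), "negative")
    expect_error(logTransform(g, offset = 0), "positive offset")
})

test_that("log transform preserves per-channel intensity ordering", {
    set.seed(10)
    X <- matrix(rexp(60), 20, 3)
    g <- makeFullGrid(X, 4, 5)
    Y <- spectraMatrix(logTransform(g, offset = 0.5))
    for (k in 1:3)
        expect_identical(order(Y[, k]), order(X[, k]))
})

test_that("baseline correction recovers trends exactly and peaks approximately", {
    mz <- seq(1000, 26000, length.out = 500)

    # constant spectrum: the constant lies in the spline span
    out <- baselineCorrect(rep(7, 500), mz)
    expect_lt(max(abs(out$corrected)), 1e-6 * 7)
    expect_equal(out$baseline, rep(7, 500), tolerance = 1e-9)

    # linear trend plus one narrow peak (<2% of channels): oracle fits the
    # spline basis to the peak-free trend directly
    trend <- 3 + 2e-4 * mz
    h <- 5
    peak <- h * exp(-((mz - 12000) / 120)^2)   # ~9 channels wide
    y <- trend + peak
    out <- baselineCorrect(y, mz)
    oracleBaseline <- {
        B <- splines::bs(mz, knots = seq(1000, 26000,
                                         length.out = 7)[-c(1, 7)],
                         degree = 3, intercept = TRUE,
                         Boundary.knots = range(mz))
        drop(B %*% qr.solve(B, trend))
    }
    apex <- which.max(peak)
    expect_lt(abs(out$corrected[apex] - h), 0.05 * h)
    expect_lt(max(abs(out$baseline - oracleBaseline)), 0.05 * h)

    expect_error(baselineCorrect(c(1, 2, 3), c(1, 2, 3), nKnots = 5),
                 "too few channels")
    expect_error(baselineCorrect(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10),
                                 1:10, nKnots = 2), "non-finite")
})

test_that("baseline correction of a peak-free spectrum is idempotent to first order", {
    mz <- seq(1000, 26000, length.out = 400)
    y <- 2 + 1e-4 * mz + sin(mz / 8000)
    once <- baselineCorrect(y, mz)$corrected
    twice <- baselineCorrect(once, mz)$corrected
    expect_lt(max(abs(twice - once)), 1e-6 * diff(range(once)))
})

test_that("grid-level baseline correction matches the per-spectrum routine", {
    set.seed(11)
    mz <- seq(1000, 5000, length.out = 60)
    X <- matrix(rexp(5 * 60, rate = 0.5), 5, 60) + outer(rep(1, 5), mz) * 1e-4
    g <- makeFullGrid(X, 5, 1, mz = mz)
    gc <- baselineCorrectGrid(g)
    for (i in 1:5)
        expect_equal(spectraMatrix(gc)[i, ],
                     baselineCorrect(X[i, ], mz)$corrected)
})

test_that("channel pre-filtering is top-k on the stated statistic", {
    # SNRs 4, 1, 3 -> keep channels 1 and 3 (ascending indices)
    expect_equal(prefilterChannels(c(4, 2, 9), SNdiag = c(1, 2, 3),
                                   mode = "snr", retainK = 2), c(1L, 3L))
    # retainK = p is the identity
    expect_equal(prefilterChannels(c(4, 2, 9), SNdiag = c(1, 2, 3),
                                   mode = "snr", retainK = 3), 1:3)
    # intensity mode ranks the means
    expect_equal(prefilterChannels(c(1, 1, 1), means = c(5, 1, 3),
                                   mode = "intensity", retainK = 2), c(1L, 3L))
    # degenerate zero noise variance: +Inf SNR, retained first, warned
    expect_warning(
        idx <- prefilterChannels(c(1, 2, 3), SNdiag = c(1, 0, 2),
                                 mode = "snr", retainK = 1),
        "zero noise")
    expect_equal(idx, 2L)
    expect_error(prefilterChannels(c(1, 2), SNdiag = c(1, 1),
                                   mode = "snr", retainK = 5), "retainK")
})

test_that("diagonal-only channel stats match the full covariance diagonals", {
    set.seed(12)
    g <- makeFullGrid(matrix(rnorm(24 * 6, mean = 5), 24, 6), 6, 4)
    st <- channelStats(g)
    full <- sampleCovariance(g)
    expect_equal(st$varZ, unname(diag(full$SZ)), tolerance = 1e-10)
    expect_equal(st$mean, full$mean, tolerance = 1e-12)
    SN <- noiseCovariance(pseudoResiduals(g))
    expect_equal(st$varN, unname(diag(SN)), tolerance = 1e-10)
    expect_equal(prefilterGrid(g, "snr", 3L),
                 prefilterChannels(diag(full$SZ), SNdiag = diag(SN),
                                   mode = "snr", retainK = 3L))
})
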