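# Fixture builders and independent brute-force oracles shared across tests.

# Fully occupied grid with given intensity matrix (spots in row-major order).
makeFullGrid <- function(intensities, nCols, nRows, mz = NULL) {
    coords <- expand.grid(col = 0:(nCols - 1L), row = 0:(nRows - 1L))
    if (is.null(mz)) mz <- seq_len(ncol(intensities))
    SpectrumGrid(intensities, coords = coords, mz = mz)
}

# Grid whose channel values are an exact linear field a + b*col + c*row,
# identical across channels up to per-channel offsets.
makeLinearFieldGrid <- function(nCols, nRows, a = 2, b = 0.7, c = -1.3,
                                p = 3L) {
    coords <- expand.grid(col = 0:(nCols - 1L), row = 0:(nRows - 1L))
    field <- a + b * coords$col + c * coords$row
    intens <- outer(field, seq_len(p), function(f, k) f + 10 * k)
    SpectrumGrid(intens, coords = coords, mz = seq_len(p))
}

# Naive double-loop sample covariance (1/(n-1), centred) — the oracle.
bruteCovariance <- function(X) {
    n <- nrow(X); p <- ncol(X)
    mu <- colMeans(X)
    S <- matrix(0, p, p)
    for (k1 in seq_len(p))
        for (k2 in seq_len(p))
            S[k1, k2] <- sum((X[, k1] - mu[k1]) * (X[, k2] - mu[k2])) / (n - 1)
    S
}

# Naive per-group channel means — the oracle for cluster mean spectra.
bruteGroupMeans <- function(X, labels) {
    k <- max(labels)
    out <- matrix(0, k, ncol(X))
    for (j in seq_len(k)) {
        idx <- which(labels == j)
        for (ch in seq_len(ncol(X)))
            out[j, ch] <- mean(X[idx, ch])
    }
    out
}

# Random symmetric positive definite matrix.
randomSPD <- function(p, jitter = 0.5) {
    A <- matrix(rnorm(p * p), p)
    crossprod(A) + diag(jitter, p)
}

# Largest principal angle (degrees) between the column spans of A and B.
principalAngleDeg <- function(A, B) {
    qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
    sv <- svd(crossprod(qa, qb))$d
    acos(min(1, min(sv))) * 180 / pi
}
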