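---
title: "Minimum noise fraction transforms for spot-grid imaging mass spectrometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNF methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsmnf)
```

## The model

An imaging MS dataset is a matrix `Z` of `n` spot spectra over `p` m/z
channels, acquired on a (possibly partially occupied) integer grid. The
working model is additive:

> `Z(x) = M(x) + N(x)`

with `M` a spatially smooth signal component and `N` noise that is
independent of `M`, (approximately) independent across spots, but freely
correlated *across channels*. Both components have channel covariances,
`Σ_M` and `Σ_N`, and independence gives `Σ_Z = Σ_M + Σ_N`.

PCA maximises `Var(aᵗZ) = aᵗΣ_Z a` and therefore ranks directions by
total variance — signal plus noise. The MNF transform instead maximises
the signal-to-noise ratio `aᵗΣ_M a / aᵗΣ_N a`. Because `Σ_M` is never
observed, the ratio is maximised in the equivalent form
`aᵗΣ_Z a / aᵗΣ_N a` (they share maximisers: the numerators differ by the
denominator), so only `Σ_N` needs estimating. Stationary points of the
sample version solve the generalised eigenproblem

> `S_Z a = λ S_N a`,

and the eigenvalue is `λ = 1 + SNR`. This parameterisation matters:
"signal equals noise" is `λ = 2`, not `λ = 1`. The package exposes both
scales explicitly (`bandEigenvalues()` returns `λ`, `bandSNR()` returns
`λ − 1`) and `selectBands()` thresholds `λ − 1` by default, precisely to
avoid the eigenvalue/SNR conflation.

## Estimators

**Spectrum covariance.** `sampleCovariance()` is the ordinary centred
sample covariance with the `1/(n − 1)` divisor, explicitly symmetrised.

**Noise covariance.** Spots on a regular grid have up to four axial
neighbours at distance one. The average of those neighbours is the
prediction of a local *linear* fit at the centre spot (the linear terms
cancel by symmetry), so the **pseudo-residual**

> `r(x) = z(x) − mean(available axial neighbours)`

annihilates any locally linear signal and retains the spatially white
noise. `noiseCovariance()` is the centred sample covariance of the valid
residual rows. A local-linear residual was preferred over shift
differences or a 3×3 local-quadratic fit because IMS spots are
physically farther apart than hyperspectral pixels; the 4-neighbour
average leans least on distant spots.

Two consequences are worth stating precisely:

* **Variance inflation.** For iid noise of variance σ², the interior
  residual has variance `σ²(1 + 1/4)` (`Var(z − mean of 4 independent
  neighbours)`). `S_N` is therefore a *scaled* noise covariance estimate.
  The scale cancels in the eigenvectors and rescales all eigenvalues by a
  common factor, so band ordering and images are unaffected; only the
  absolute SNR scale shifts. The 5/4 factor is asserted by the test suite
  on a 100×100 grid.
* **Edge handling.** Spots next to grid edges or to empty positions of an
  irregular tissue outline (treated identically) average over however
  many of the ≤4 neighbours exist. This is exact for constant fields but
  *not* for linear ones — a corner residual of the field
  `a + b·col + c·row` is `−(b + c)/2` — and edge residuals have variance
  `σ²(1 + 1/m)` for `m` neighbours, a known heteroscedasticity. The
  default follows the plain pseudo-residual definition;
  `noiseCovariance(..., equalizeEdgeVariance = TRUE)` rescales rows by
  `(1 + 1/m)^{-1/2}` for users who want edge and interior residuals on an
  equal footing. Spots with zero neighbours carry no noise information
  and are dropped from `S_N` (flagged in `ResidualGrid`).

## Solving the generalised eigenproblem

`mnfBands()` uses the standard symmetric reduction: Cholesky-factor
`S_N = RᵗR`, form the whitened matrix `R^{-T} S_Z R^{-1}`, run an
ordinary symmetric eigendecomposition, and back-transform. Numerical
policies:

* **Normalisation** `aᵗ S_N a = 1`: every band has unit noise variance,
  so band images are directly comparable and clustering in band space
  needs no rescaling. (PCA uses the conventional `aᵗa = 1`.) Any other
  scaling changes scores by a per-band constant only — band images are
  identical up to contrast.
* **Sign convention**: the largest-magnitude loading of each vector is
  made positive (ties to the lowest index), making output reproducible
  across LAPACK builds.
* **Singular `S_N`**: the matrix-level method refuses to guess — it
  reports the numerical rank and suggests a ridge. `ridge = r` adds
  `r · mean(diag(S_N)) · I`. Eigenvalues are non-increasing in the ridge
  (tested). The grid-level method and the pipeline, which face real data,
  retry automatically with `ridge = 1e-8` and a warning. Pre-filtering by
  SNR makes rank deficiency rare in practice.
* **Affine invariance**: for any invertible channel transform `T`, the
  pair `(TᵗS_Z T, TᵗS_N T)` has the same eigenvalues and the same
  per-spot scores up to sign. This is the transform's defining advantage
  over PCA (which is not invariant) and is asserted both at the
  covariance level and end-to-end through the residual estimator.

## Preprocessing

The canonical order is log → baseline → pre-filter → covariances →
transform, i.e. the filter ranks exactly the values the transform will
see.

* **Log transform**: `ln(x + offset)`, default `offset = 1` because raw
  counts contain zeros. `offset = 0` with zeros present is an error, not
  a silent `-Inf`.
* **Baseline**: a cubic regression spline with `nKnots = 5` interior
  knots equally spaced over the observed m/z range, fitted by IRLS with
  Tukey-bisquare weights (tuning constant 4.685·MAD, 10 iterations).
  Down-weighting is **one-sided** by default: only positive residuals
  (peak candidates) lose weight, because a baseline must underestimate
  peaks rather than split them. Knot count, iterations and sidedness are
  exposed; degree, placement and loss are deliberately plain defaults —
  the least-assumption reading of "a k-knot robust spline".
* **Pre-filtering**: implemented as **top-k selection** (`retainK`,
  default 650) rather than an absolute threshold, because the count is
  the primitive a practitioner controls ("keep enough channels for a
  manageable covariance") and any threshold is derivable from it. The
  MNF ranking statistic is the per-channel `diag(S_Z)/diag(S_N)` ratio;
  the PCA statistic is the mean intensity. Both are computed by
  diagonal-only passes (`channelStats()`) — no `p × p` matrix is ever
  materialised at full channel count, which is the entire point of
  filtering at `p ≈ 10⁴`. A zero noise-variance channel gets `+Inf` SNR
  and a warning: a degenerate noise estimate should be looked at, not
  silently ranked last.

## Band count selection

For PCA, `selectBands()` applies the percent-total-variance rule
(smallest `K` whose cumulative eigenvalue share reaches `pctThreshold`).
MNF eigenvalues are ratios, not additive variances, so the rule is a
per-band threshold: count bands with `λ − 1 >` `snrThreshold` (default 1,
"more signal than noise"); `snrScale = "lambda"` thresholds raw `λ`
instead. One caveat the test suite quantifies indirectly: at `p/n` ratios
around 1/3 (650 channels, ~2000 spots), sampling variability alone
inflates the leading generalised eigenvalues of pure noise above 2, so on
data of that shape the SNR > 1 rule is generous and a higher threshold
(or a smaller retained channel set) is reasonable.

## Clustering

`hclusterSpots()` is agglomerative clustering on Euclidean distances
between band-score vectors, cut at `k`. The default linkage is Ward
(`ward.D2`), the common choice for clustering on component scores;
complete and average linkage are available. Scores enter **unstandardised**:
under the `aᵗS_N a = 1` normalisation every band already has unit noise
variance, so per-band rescaling would only re-weight by signal strength —
exactly the information worth keeping. `k` is user-supplied; automatic
selection is out of scope. Labels are canonicalised (label 1 = largest
cluster, ties by smallest member index) so results are invariant to spot
order, and `clusterMeanSpectra()` averages whatever grid it is given —
pass the background-corrected grid to get background-corrected cluster
mean spectra.

## The synthetic generator

`generateGrid()` draws

`intensities = (patterns + peakMeanHeight) %*% t(loadings) + baseline + noise`

* **Patterns** (`n × q`): smooth spatial maps — Gaussian disks, oriented
  stripes, linear gradients, or smoothed white noise — centred, scaled to
  unit spatial variance, and **Gram–Schmidt-decorrelated** over the
  spots. Decorrelation is a design decision: the transform's bands
  diagonalise the signal covariance, so recovery of *individual* planted
  maps is only identifiable when the maps are mutually uncorrelated;
  correlated planted maps would be recovered as a rotated pair even
  noise-free.
* **Loadings** (`p × q`): each component occupies a random
  `loadingsSparsity` fraction of channels (default 0.1) with
  non-negative weights `U(0.5, 1.5)`, scaled by a geometric amplitude
  ladder (`componentAmpRatio = 1.4`) — components of differing abundance,
  which keeps the MNF eigenvalues separated the way real tissue
  compartments are. `peakMeanHeight = 2` adds a constant mean elevation
  on active channels: real peak channels have high mean intensity, which
  is what intensity-threshold pre-filtering for PCA relies on; being a
  per-channel constant it changes no covariance.
* **Noise**: Gaussian, independent across spots, AR(1)-correlated across
  channels (`noiseChannelCorr = 0.3`, stationary sd `noiseSd = 0.5`).
  The channel correlation is what makes `Σ_N` non-diagonal and the
  generalised eigenproblem genuinely different from a rescaled PCA.
  `noiseCovarianceModel()` returns the implied `σ² ρ^{|k₁−k₂|}` matrix
  for convergence checks.
* **Baseline**: an exponentially decaying channel profile with gentle
  smooth spatial modulation (`baselineAmp = 1`), so baseline correction
  has something realistic to remove.
* The whole matrix is shifted to be non-negative, and a single seed makes
  the output bit-reproducible.

`tissueScaleFixture()` emulates the scale of a single MALDI-ToF tissue
run: an elliptical outline on a 60 × 45 grid (1992 occupied spots),
11280 channels over m/z 1000–26000, four components at sparsity 0.02.
`adversarialFixture()` is the designed counter-example for PCA: one
common spatially white field drives a 20-channel block at high variance
while a low-amplitude smooth disk sits on a disjoint block — PCA's first
band follows the variance, MNF's first band recovers the disk.

**What the generator does not emulate:** isotope envelopes, peak shapes
and m/z-dependent resolution, detector saturation, matrix crystallisation
artefacts, spatially correlated noise (e.g. scan-line effects), and
intensity-dependent noise. Passing tests therefore demonstrate the
estimators' statistical behaviour under the stated model, not instrument
physics; on real data the pseudo-residual estimator will absorb any
signal that varies at the single-spot scale into "noise", which is a
feature of the definition, not a bug of the implementation.

## Problem sizes and tolerances used in validation

The test suite validates covariance estimators against brute-force
double-loop oracles at 10 × 5 (10⁻¹² relative), the generalised
eigen-solver against a Rayleigh-quotient search at `p = 8` over 10⁶
random unit directions refined by local maximisation (10⁻³ relative, 20
replicates), residual-variance inflation on a 100 × 100 grid (±5%), and
planted-component recovery at the generator defaults over 10 seeds
(matched |r| > 0.95). The end-to-end run uses the tissue-scale fixture —
1992 × 11280, filtered to 650 channels, `K = 6`, `k = 7` — chosen as a
realistic single-section workload that a desk machine handles in about a
minute. The acceptance script (`scripts/acceptance.R`) re-runs that
pipeline plus the inflation experiment from a user-supplied seed and
writes every computed quantity as JSON.

## Known limitations

* The local-linear edge rule biases edge residuals for non-constant
  fields (see above); on convex tissue outlines the affected fraction is
  the boundary ring.
* `S_N` estimates a *scaled* `Σ_N` (5/4 on the interior); reported SNRs
  are correspondingly conservative in absolute terms.
* At small `n/p`, generalised eigenvalues of noise alone exceed the
  `λ = 2` signal≈noise line; band-count thresholds should be read with
  that inflation in mind.
* The log transform is applied before covariance estimation, so strictly
  the model is additive on the log scale; strongly overlapping channel
  loadings of comparable amplitude can mix within the top band subspace
  (the span is still recovered).
* Inverse MNF reconstruction (denoising by projecting onto leading bands
  and back) is a natural extension and is not implemented.
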