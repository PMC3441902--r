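# imsmnf — minimum noise fraction transforms for imaging mass spectrometry

Imaging mass spectrometry (IMS) acquires a complete mass spectrum at every
position of a spot grid laid over a sectioned tissue sample, producing a
*stack* of ion intensity maps: thousands of spots by ~10⁴ m/z channels for a
single MALDI-ToF run. Choosing which maps to look at is the bottleneck —
individual channel images are noisy, and PCA, the usual data-reduction tool,
ranks components by **variance**, which conflates signal with noise.

`imsmnf` implements the **minimum noise fraction (MNF) transform** for spot-grid
IMS data. MNF ranks linear combinations of channels by their **spatial
signal-to-noise ratio** instead. Writing the spectrum at location *x* as
*Z(x) = M(x) + N(x)* — a spatially smooth signal plus spatially uncorrelated
noise, with Σ_Z = Σ_M + Σ_N under independence — the first MNF band is the
vector *a* maximising the Rayleigh quotient

```
aᵗ S_Z a / aᵗ S_N a
```

whose stationary points solve the generalised eigenproblem
**S_Z a = λ S_N a**. Here S_Z is the ordinary sample covariance of the
spectra and S_N is estimated from **4-neighbour local-linear
pseudo-residuals**: each spot's intensity minus the average of its available
axial grid neighbours, which cancels any locally linear signal and leaves
(5/4 of) the spatially white noise. The eigenvalues are
λ = (signal + noise)/noise, so λ − 1 is the band's signal-to-noise ratio;
bands are reported in descending λ, and a band with λ − 1 > 1 carries more
signal than noise.

The package covers the full workflow around the transform:

* `SpectrumGrid` — a `SummarizedExperiment`-based container for spot-grid
  spectra (partial tissue outlines supported), with continuous-mode imzML
  and delimited-matrix readers/writers;
* preprocessing — `logTransform()`, `baselineCorrectGrid()` (cubic
  regression spline, 5 interior knots by default, iteratively reweighted
  with one-sided Tukey-bisquare weights so the curve sits under the peaks),
  and `prefilterGrid()` (top-*k* channels by SNR for MNF, by mean intensity
  for PCA — the "keep the 650 best channels" style of filtering that keeps
  covariance matrices manageable);
* `mnfBands()` / `pcaBands()` — the transforms, with per-spot band scores,
  `selectBands()`, band-image PNG output via `writeBands()`;
* `clusterSpots()` — Ward/complete/average hierarchical clustering of spots
  in band space with per-cluster mean spectra;
* `generateGrid()` / `tissueScaleFixture()` — a synthetic generator with
  planted spatial components and channel-correlated, spatially white noise,
  so every stage is testable without instrument data;
* `runPipeline()` and a thin CLI (`inst/cli/imsmnf.R`) chaining
  synth → preprocess → prefilter → transform → cluster with a JSON run
  manifest.

## Worked example

```r
library(imsmnf)

## synthesise a 50 x 40 spot grid with two planted spatial components
sim  <- generateGrid(synthConfig(q = 2, seed = 1))
grid <- sim$grid
grid
#> SpectrumGrid: 2000 spots x 200 channels
#>   grid bounding box 50 cols x 40 rows (100% occupied)
#>   m/z range 1000 .. 26000

## preprocess: log, 5-knot robust-spline baseline, keep the 100
## highest-SNR channels
grid <- logTransform(grid, offset = 1)
grid <- baselineCorrectGrid(grid, nKnots = 5)
keep <- prefilterGrid(grid, mode = "snr", retainK = 100)

## minimum noise fraction transform
mnf <- mnfBands(grid, K = 6, channels = keep)
mnf
#> BandDecomposition (mnf): 6 bands over 100 channels
#>   eigenvalues: 52.656, 30.113, 1.2047, 1.1738, 1.1582, 1.1466
#>   SNR (lambda - 1): 51.656, 29.113, 0.20468, 0.17381, 0.15819, 0.14659
#>   scores: 2000 spots

## how many bands carry more signal than noise?
selectBands(bandEigenvalues(mnf), "mnf", snrThreshold = 1)
#> [1] 2

## the leading band images recover the planted component maps
round(matchPatternCorrelations(bandScores(mnf)[, 1:2], sim$truth$patterns), 3)
#> [1] 0.985 0.983

## segment the grid in band space
cl <- clusterSpots(mnf, grid, k = 4, nBands = 2)
cl
#> ClusterResult: 2000 spots in 4 clusters (ward linkage)
#>   sizes: 842, 509, 418, 231
```

Reading it: the two planted components surface as the two leading bands
with SNR ≈ 52 and 29, the remaining bands sit near the signal≈noise
boundary, the SNR > 1 rule picks exactly K = 2, and the band-score maps
correlate |r| ≈ 0.98 with the true planted maps. `writeBands(mnf, grid,
"out")` renders each band as a greyscale PNG (empty grid positions
transparent) next to a `col,row,band1..bandK` score table.

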