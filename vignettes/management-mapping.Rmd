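---
title: "Mapping forest management regimes from EVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest management regimes from EVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestmgmt)
```

## The problem

Forest management regimes — production forestry (rotation clearcuts for wood
products), ecological forestry (partial, retention-style harvests), passive
management (largely unmanaged, occasional opportunistic harvest) and
preservation (no harvest) — leave distinct fingerprints in long satellite
vegetation-index records. A clearcut is an abrupt drop in the Enhanced
Vegetation Index (EVI) followed by steady recovery; a retention harvest is a
smaller drop; preservation stands show seasonality and little else.
`forestmgmt` turns a 16-day EVI record (23 composites per year, values scaled
by 10 000) into a per-pixel management classification with calibrated
probability surfaces, and quantifies what is lost when the categorical map is
aggregated to a coarse modelling grid.

The pipeline is: QA masking and gap interpolation, season/trend/break
decomposition, break-summary features, ancillary landscape covariates, a
weighted random forest, confusion-matrix validation, and a Bayesian
aggregation-uncertainty analysis. Every stage is exercisable on synthetic
landscapes with known ground truth, which is how the package tests itself.

## Preprocessing

Observations whose QA usefulness code (0 best to 15 worst) exceeds the
threshold (default 4, i.e. the upper half of the quality range is retained)
are set missing. If strictly more than 75 % of a pixel's observations are
good, interior gaps are linearly interpolated between the two nearest good
observations and edge gaps take the nearest good value; otherwise the pixel
is flagged unusable and excluded downstream. Two choices here were genuinely
open: the usefulness comparison is applied to the integer code (a per-bit
reading is also defensible, so the threshold is configurable), and edge gaps
use constant rather than linear extrapolation to avoid inventing a trend at
the record boundary. The 75 % rule is strict: exactly 270 good observations
out of 360 fails.

## Decomposition and break detection

Each gap-filled series $y_t$ is decomposed additively,

$$y_t = T_t + S_t + e_t,$$

with a piecewise-linear trend $T_t$ and a piecewise-harmonic seasonal
component $S_t$ (order-3 sin/cos pairs on a 23-observation period, no
intercept), each allowed up to 3 structural breaks. Breaks are found by exact
dynamic programming: for every admissible segment the OLS residual sum of
squares is computed in closed form from cumulative cross-products (the
per-window Gram inverses depend only on the design and are shared across all
pixels of a cube, which is what makes whole-cube processing affordable), and
the segmentation minimising total RSS is found for each break count. The
number of breaks is selected by BIC; the trend step runs on the
deseasonalized series, the seasonal step on the detrended series, and the two
alternate until the break sets converge and the fitted components are
stationary to 1e-6 EVI units (at most `max_iter = 5` sweeps; the expensive
scans are skipped for pixels whose break sets have already settled).

Numerical choices worth knowing:

* Minimum segment length is 46 observations (two years), which confines
  break positions to [46, 314] on a 360-step record — matching the observed
  range of break locations in the regional products this design follows.
* BIC compares $n\log(\mathrm{RSS}/n) + p\log n$ across break counts, with
  the RSS floored at a scale-relative epsilon so that numerically-zero
  residuals on noiseless input cannot reward spurious extra breaks. Ties
  resolve to fewer breaks, and RSS ties inside the DP to the earliest break.
* A break index is the 1-based position of the last observation of the
  segment it terminates, so a level shift whose first shifted observation is
  $t_0$ is reported at $t_0 - 1$.
* The reference implementation of this style of decomposition tests breaks
  with an OLS-MOSUM sequence; this package targets equivalence at the level
  of detected break locations on clean signals (verified against an
  exhaustive-scan oracle), not test-statistic replication.

Spectral entropy — the Shannon entropy of the normalized periodogram (zero
frequency excluded) scaled to a maximum of 1 — summarises series complexity:
a pure seasonal cycle scores near 0, noise-like records near 1.

## The 29 break-summary features

For the trend, every break has a fitted-value jump (`*_diff`), a difference
of observed-EVI segment means (`*_mean_diff`), and the observed-EVI
interquartile range of the segment preceding it (`*_inqtrng`). The `bd_*`
family reads these at the break with the most negative jump, `bi_*` at the
most positive, `lb_*` at the break bounding the longest segment. Seasonal
analogues (`bd_sb*`, `bi_sb*`, `lsb_*`) use the per-segment range, spectral
entropy and IQR of the seasonal component, ranked by the range change.
`detected_breaks`, `detected_breaks_seasonal`, `entropy` and
`entropy_seasonal` complete the 29-variable vector.

Three definitions were open and are fixed here as package conventions: the
"longest break" is the break terminating the longest segment (with the final
segment attributed to the last break); ties for biggest increase/decrease go
to the earliest break; and a component with no detected breaks emits
sentinel 0 (locations, counts) / 0.0 (differences) so the classifier input
stays dense — `detected_breaks = 0` carries the information, and the raster
writer adds explicit validity bands.

## Ancillary covariates and training labels

Road density is an exact line-kernel density: total road length inside a
1-km disc around each cell center divided by the disc area. Ownership
integrates multiple source layers through a fixed crosswalk onto ten
categories, with overlaps resolved by a deterministic precedence (protected
> military > other public > private) instead of manual topology editing; the
label "Regional agency", which the sources attach to several public owner
types, is standardised to "state". Fine-resolution vegetation classes are
upscaled to per-pixel conifer and riparian proportions by exact block
counting on integrally nested grids (real grids must be resampled to nest
first). Training pixels must be at least half forest and at least half one
management class (both inclusive); a multi-vintage reconciliation rule
recovers clearcuts that single-date forest masks miss. Training labels come
from multiple annotators under an 80 % consensus rule (4 of 5 suffice);
unresolved points are dropped.

## Classification protocol

The forest itself is the standard `randomForest` engine; the protocol around
it is the contribution: 500 trees, 7 covariates tried per split (or
`tuneRF` when unset), class weights defaulting to inverse class frequency
(the weighting scheme was open; inverse frequency is the common choice for
rare classes such as ecological forestry), covariate columns canonicalized
to name order so results are column-order invariant under a fixed seed,
iterative removal of covariates with negative permutation importance
("negative increase in node purity" is read as negative permutation
importance, since impurity importances are nonnegative by construction),
then retention of at most the 15 covariates with the largest mean decrease
in accuracy. Prediction surfaces are per-class vote fractions (they sum to
1); the class raster is their argmax with ties to the lowest class code
(ecological = 1, ..., production = 4, an implementation convention).

## Accuracy and aggregation uncertainty

Validation uses stratified 10-fold cross-validation, the OOB confusion
matrix, and an external hold-out (about 20 % of points). Confusion matrices
are stored rows = predicted; producers accuracy is diagonal over row total
and users accuracy diagonal over column total, which matches the printed
layout of the published regional tables (whose captions state the reverse —
the implementation follows the printed numbers and records the orientation
on the object). `regional_confusion_matrices()` ships those published
matrices; the SEUS external overall accuracy is quoted inconsistently at its
source, and the package reports the matrix-derived value (124/178 ≈ 0.70).

Aggregation uncertainty follows the categorical-map upscaling analysis: for
each coarse cell (default 40 × 40 pixels, 250 m to 10 km) with $n$ forest
pixels and observed mapped-class counts $c$, the true class proportions
$\theta$ get a flat Dirichlet prior, the mapping channel
$M_{ij} = P(\text{mapped } j \mid \text{true } i)$ is estimated from a
confusion matrix (external by default, falling back to OOB if the hold-out
misses a class), and $c \sim \text{Multinomial}(n, M^\top\theta)$. The
source procedure gives no equations, so this model — and its sampler, an
independence Metropolis chain with a Dirichlet proposal centred on the
linear unmixing $M^{-\top}p_{obs}$ (overdispersed twofold), 10 000 draws
after 1 000 burn-in — is specified here and fully configurable. The
per-class posterior standard deviation is the reported uncertainty. The
sampler is validated against 1-D grid integration in the 2-class case and
against the analytic identity-channel limit, and its posterior sd shrinks
monotonically as the cell pixel count grows.

## The synthetic landscape generator

The generator is first-class, tested code: it defines the study conditions
under which the package demonstrates recovery. A landscape is a grid of
square stands (default 5 × 5 pixels, i.e. 1.25 km parcels) allocated to the
four classes by exact largest-remainder quota from the class mixture
(default: the southeastern training distribution, 3.5 / 28.75 / 9.5 /
58.25 %), so realized frequencies match the mixture to within one stand.
Pixel series are a first-order harmonic (amplitude 1500, baseline 4500,
both EVI × 10000) plus class-specific disturbances and iid noise
(sd 150): production stands are clearcut (drop 3000) on an 18–20-year
rotation (19 by default) with uniform random phase and linear recovery
(16 EVI/step, roughly eight years to full recovery, consistent with fast
southeastern pine regrowth); ecological stands follow the same schedule at
40 % magnitude as a proxy for variable-retention harvesting; passive stands
suffer rare Poisson disturbances (0.02/year) at 60 % magnitude;
preservation stands none. QA dropout (10 %) corrupts values downward and
assigns poor usefulness codes. Ownership is drawn per stand from a fixed
conditional table (corporate ownership production-heavy, protected
categories preservation-only — the association is stated only qualitatively
by the sources, so the table is a package convention), roads are Poisson
per stand with production the densest, and a nested fine vegetation raster
drives forest masks and conifer/riparian proportions.

What the generator does *not* emulate: real MODIS radiometry, geolocation or
compositing artifacts, spatially correlated noise, mixed-class pixels,
gradual degradation, or drought/fire signals. Passing recovery tests
therefore demonstrates internal consistency of the method, not performance
on real imagery; the per-class EVI statistics of the mapped regions are not
published, so simulator realism is checked only through these internal
recovery tests. One bookkeeping note: 16 years × 23 composites is 368
observations, while the canonical regional record is 360 (a February start
truncates the first year); `simulate_series(n_obs = 360)` produces
canonical-length records, and all break-location bounds scale as
[46, N − 46].

## Problem sizes and runtime

The shipped tests and the acceptance script run, by design, at desk scale:
break-recovery batches of 200 series of length 360, oracle comparisons at
N = 150 with up to 2 breaks, and an end-to-end landscape of 100 × 100 pixels
with 1000 training points, which completes in about a minute on one core.
The published regional maps (millions of pixels) are orders of magnitude
larger; their accuracy figures are reproduced here through the published
confusion matrices rather than by re-running the full-region analysis.

## Known limitations

* Passive and preservation stands are phenologically similar by
  construction; their separation leans on ownership and road covariates, as
  it does in the real maps.
* The decomposition assumes an additive model with at most three breaks per
  component; slow continuous degradation is absorbed into segment slopes.
* Coarse cells are treated as independent in the uncertainty analysis; no
  spatial autocorrelation between cells is modelled.
* Raster I/O uses plain-text ASCII grids with full double precision; there
  is no GeoTIFF reader/writer, and projection strings are metadata passed
  through untouched.
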