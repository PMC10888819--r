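---
title: "Models and methods in fetalcortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fetalcortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
behind each analysis stage, what the tunable parameters mean and why
their defaults are what they are, what the synthetic generators emulate
(and deliberately do not), and the numerical choices that matter when
reading results.

## 1. Histology artifact repair

Serial Nissl-stained sections of the fetal brain carry preparation
artifacts — tears (missing tissue exposing the white mounting medium),
folds (duplicated, darkened tissue) and local staining shifts. The
repair model treats the anatomical annotation of a section as a
sufficient predictor of its appearance: a per-label Gaussian appearance
model (mean RGB and 3×3 covariance per label, `fitLabelAppearance()`)
synthesizes the section that *should* have been observed, and
disagreement between observation and prediction localises damage.

Detection operates in HSV space, mirroring how stain variation is
perceived: both images are box-blurred (5×5) and per-pixel absolute
differences in hue and saturation are scored with a robust z
(`|d − median(d)| / MAD(d)`), flagged when the score exceeds `theta`
(default 2.5). Both channels must agree, and the joint mask is
despeckled by an iterated morphological opening (3 erosions then 3
dilations with a 3-px elliptical element — the iterated form, since a
single opening is idempotent). Numerical guards that matter:

* **Hue is circular** in `[0, 1)`; distances use
  `min(|Δ|, 1 − |Δ|)` so reds near the wrap point are not false
  positives.
* **Hue is undefined at zero saturation.** Pixels unsaturated in *both*
  images (mounting medium, most of any section) carry no colour
  evidence; they are excluded from the robust statistics and can never
  be flagged (`satEps`, default 0.05). Without this, the background
  dilutes the MAD and detection collapses.
* **The MAD is floored** at `1e-6`; a perfectly flat difference map
  yields an empty mask and a warning rather than division by zero.
* The wording of the outlier rule admits two readings; both are
  implemented (`outlierRule = "robust_z"` (default) or
  `"raw_gt_theta_mad"`, which thresholds raw differences at
  `theta · MAD`). Lowering `theta` can only grow the pre-opening
  outlier set under either rule.

Repair is Poisson image editing: inside each mask component and per
channel, the discrete Laplacian of the output is matched to that of the
synthetic image with Dirichlet boundary values from the original, via a
sparse symmetric solve (`Matrix`). Outside the mask the original is
untouched; the solution is clipped to the valid intensity range. Mask
components are solved independently for conditioning, and a singular
component falls back to direct replacement with a warning. On instances
up to 32×32 the solver matches a dense-matrix oracle to well below
1e-6.

Whole sections are processed in 256×256 patches with an 8-px overlap
(`tileAndStitch()`); overlaps are blended by normalised linear
feathering, so an identity patch operator reproduces the input exactly,
seams included.

## 2. Stack reconstruction

Rigid slice-to-slice registration maximises normalised
cross-correlation over the fixed section's tissue mask, with a
coarse-to-fine search: an exhaustive rotation (±15°, 1° steps) ×
translation grid at 4× block-averaged resolution, followed by a greedy
full-resolution refinement with step halving down to 0.25° and 1 px.
The returned transform is the one that, applied to the moving image,
aligns it to the fixed image (counterclockwise rotation about the image
centre in 0-based (x, y) pixel coordinates).

Sections become nodes of a directed graph with edges from each section
toward sections nearer the middle reference (neighbourhood radius
`k = 2` by default — the radius is a free choice; 2 gives the
shortest-path search a genuine alternative to single steps), weighted
by registration cost `1 − NCC`. Dijkstra's algorithm selects the
cheapest path per section and the edge transforms are composed along
it. Images are resampled bilinearly, label maps with nearest-neighbour
(the vocabulary is preserved exactly).

Because consecutive pairwise alignment propagates small errors into a
global "z-shift", a 3-D shape reference can be imposed: each section is
affinely registered (6 parameters, NCC objective, Nelder–Mead
refinement seeded by a rigid + scale search, images mildly blurred so
shape rather than uncorrelated texture drives the objective) to the
corresponding reference slice, the six parameters are smoothed along
the stack axis with a moving median (window 5), and the smoothed
transforms are composed with the accumulated state, for 5 iterations.
The per-slice-affine + parameter-median scheme is this package's
formulation of the iterative refinement; the median window is what
suppresses single-slice excursions while letting the stack drift
toward the reference. Mean cost is non-increasing across iterations up
to a small resampling tolerance.

ISH sections are reduced to their red channel (the high-expression end
of the false-colour map), affinely registered to their nearest
Nissl-stained section, carried through that section's composed
transform, and stacked with missing planes encoded as `NA` (zero is a
valid intensity). Regional means are computed only over planes where
ISH exists, with per-structure section counts reported; a structure
with no present voxels is missing, not zero. Volumes export at a
configurable isotropic voxel size (default 150 µm) with the voxel size
carried in the NIfTI header.

## 3. Expression processing

Probe filtering drops multi-gene probes, probes without a gene
assignment and probes flagged absent. Differential stability (DS) of a
probe is the average, over specimen pairs, of the Pearson correlation
of its expression across the (region, zone) cells sampled in both
specimens — a reproducibility score insensitive to affine differences
in per-specimen scaling. Pairs sharing fewer than 4 cells are excluded
(correlation on fewer points is unstable); a probe with no qualifying
pair has undefined DS, which counts as below threshold. Per gene, the
highest-DS probe wins (ties broken by lexicographically smaller probe
id, making the pipeline order-stable), and genes whose best probe has
DS < 0.2 are removed. DS is computed after absent-probe filtering; the
audit attribute records counts at every step. Aggregation averages
replicate samples per (specimen, region, zone) cell and removes genes
missing in more than 10% of the cells actually sampled in the design —
the ceiling is read at the aggregated level where the analysis
happens, not at raw sample level.

## 4. The zone–region–time screen

Each gene's expression over the tensor cells is modelled by OLS with
dummy-coded main effects of zone (5 levels), region, and timepoint
(early = specimens ≤ 16 PCW pooled, mid = 21 PCW). Interactions and
specimen effects are deliberately excluded: with two specimens per
timepoint, specimen and timepoint are confounded, and the screen is a
main-effects triage, not a final model. Per factor, a partial (type II)
F statistic `((RSS_reduced − RSS_full)/Δdf) / (RSS_full/df_resid)` is
computed; with near-balanced designs this is order-invariant. Missing
cells are dropped listwise; a gene whose design collapses to one level
on a factor is flagged unevaluable. A numerically zero full-model
residual (noiseless fixtures) is resolved explicitly — F = ∞ (p = 0)
when the factor carries signal, F = 0 when it does not — rather than
left to floating-point noise.

Benjamini–Hochberg FDR is applied across genes separately within each
factor, and the ZRT set is the triple intersection at q < 0.01. One
property worth stating plainly: BH controls the false discovery rate
*per factor*; the FDR of the three-way intersection is not separately
controlled (a gene with two true effects needs only one false rejection
to enter the set). On planted data the per-factor empirical FDR sits
at or below the nominal level and the intersection's sensitivity is
high; the tests measure exactly these quantities.

Zone-wise fold change is the log2 ratio of the mid- to early-gestation
mean within a zone (means over specimens × regions), flagged at
|log2FC| > 0.3; non-positive means leave it undefined.

## 5. Vertexwise allometric scaling

Total cortical surface area grows log-linearly with gestational age
(`log10 A ≈ intercept + 0.054 · age`), so the per-vertex model

  log10 a_v = b_v + β_v · log10 A + ε

reads directly against 1: β_v > 1 means the vertex's area grows
proportionally faster than the cortex as a whole (hyperallometric),
β_v < 1 slower (hypoallometric). The printed form of this model writes
an explicit intercept; it is fit here by ordinary least squares per
vertex, with optional sex and sex-by-size covariates behind a flag.
β is invariant to global rescaling of all areas (intercept absorbs it).

Before fitting: (i) vertex areas are corrected for folding bias by
regressing `log10` area on curvature across subjects at each vertex and
removing the fitted curvature component. The correction controls for
`log10` total area: without that, chance correlation between curvature
fluctuations and the age-driven size signal leaks part of the signal of
interest into the removed component, and the "correction" can hurt more
than it helps. Vertices with zero-variance curvature are skipped. (ii)
Corrected areas are smoothed on the mesh by iterated one-ring neighbour
averaging calibrated so the accumulated kernel variance matches
`(FWHM/2.355)^2` given the mean edge length — an approximation to a
geodesic Gaussian that is accurate to ~20% in kernel width on
icosphere meshes, which is adequate for a 10-mm kernel on a ~2-mm edge
mesh. (iii) Outliers are screened by a sliding window over age-sorted
scans (window ≤ 25), flagging a (scan, vertex) pair beyond 2.5 SD of
the window's leave-one-out mean — leave-one-out so an extreme scan
cannot mask itself — and dropping entirely any scan flagged at more
than 5% of vertices. Vertices with fewer than 10 usable scans have
undefined β; parcel summaries are unweighted means over defined,
non-medial-wall vertices.

**An identifiability note.** The fitted predictor is the *realized*
total (the sum of the subject's vertex areas), as it must be with real
data. If the whole β field were a single constant c, every vertex and
the total would scale together and the fit would return β ≡ 1, not c —
relative allometry is only defined against a heterogeneous field.
Recovery tests therefore either use fields spanning both sides of 1
(where per-vertex recovery against the realized total is accurate:
RMSE ≈ 0.013 at noise sd 0.02, n = 60, 2562 vertices) or validate
uniform fields against the generator's target totals.

## 6. Association and enrichment

Regional expression (averaged over a timepoint's specimens) is
correlated with parcel-mean β across the regions shared by both tables
using Kendall's tau-b (tie-corrected; exact p for small untied
batches). At least 5 shared regions are required; constant expression
leaves tau undefined and out of the FDR batch. BH correction runs over
the whole gene × zone × timepoint batch of a screen — one batch per
screen rather than per zone, with the per-zone alternative available by
subsetting. A region subset argument supports neocortex-only reruns
(excluding allo- and periallocortical structures). Significant records
split by the sign of tau into hyper- and hypoallometric gene sets, with
per-zone counts and a deduplicated pooled set.

Gene-set enrichment uses the hypergeometric upper tail
`p = P(X ≥ x)` — "x or more" — computed with log-gamma arithmetic,
with the enrichment ratio `(x/N)/(K/M)`. A strict variant
`P(X > x)` is available (`strictPrintedFormula`), since the summation
form in which such tests are sometimes printed (`1 − Σ_{i≤x}`)
literally excludes the observed count; the inclusive reading is the
default because it is the stated intent of such tests. Odds ratios are
computed from proportions (`[p1/(1−p1)]/[p2/(1−p2)]`), with a two-sided
Fisher exact p when counts are supplied. Permutation tests compare a
gene set's median annotation score against `nPerm` equal-sized uniform
draws from the scored universe, with
`p = (1 + #{null ≤ observed})/(nPerm + 1)` — never below
`1/(nPerm + 1)`, and uniform on its support under the null. The
implementation accepts `nPerm ≥ 99` (its own calibration checks run at
999) though 10,000 is the default for reported p values.

## 7. What the synthetic generators do and do not emulate

The generators define the study conditions for every test:

* **Histology** (`simulateHistologyStack()`): nested, angularly
  deformed elliptical shells give spatially contiguous labels whose
  geometry drifts smoothly along the cutting axis; a fixed angular
  shading mimics consistent cytoarchitectonic variation and, crucially,
  makes in-plane rotation observable from appearance. Tears (white),
  folds (darkened duplicated patch) and stain shifts (hue rotation) are
  injected at configurable rates with every pixel logged; rigid
  misalignments are uniform within ±5° and ±6 px by default (the middle
  section stays fixed as the natural reference). Not emulated:
  realistic Nissl texture, out-of-plane deformation, scanner physics.
  Passing tests show the pipeline recovers *this* class of geometry and
  artifact; real-tissue texture is both richer (more registration
  signal) and messier (more detection ambiguity).
* **Expression** (`simulateExpressionDataset()`): additive per-gene
  models with independently planted zone/region/time effects (equally
  spaced level shifts of fixed magnitude, so power is uniform across
  flagged genes), optional monotone regional profiles to seed
  association tests, Gaussian noise, and completely-at-random
  missingness (no mechanism is asserted for the real data's gaps). Not
  emulated: specimen-level batch structure, correlated genes,
  mean–variance coupling.
* **Surfaces** (`simulateSurfaceCohort()`): one icosphere topology
  (subdivision 4 = 2562 vertices for full-size runs), log-linear
  total-area growth at 0.054 per week over 21–38 weeks, a β field
  linear in the sphere's z-coordinate spanning [0.7, 1.3], curvature
  with a configurable multiplicative leak into area (static across
  subjects when the leak is off, so the correction is exactly a no-op
  there), planted aberrant areas for outlier screening, and
  latitude-band parcels that stratify the β field. Not emulated: real
  cortical geometry, folding, registration error across subjects.
* **Annotation** (`simulateAnnotationResources()`): gene sets drawn to
  hit a target enrichment ratio against a designated interest set,
  probe tables with multi-probe genes and present/absent flags, and
  score tables with an exactly planted median shift in the noiseless
  configuration.

## 8. Problem sizes and reproducibility

Every generator and every stochastic routine takes an explicit integer
seed and restores the caller's RNG state. The package's own validation
runs at deliberate scales: 5–10 sections of 128–256 px for repair and
alignment, 2000 genes for the ZRT screen and its null calibration,
60 scans × 2562 vertices for scaling recovery, 999–10,000 permutations
for the median tests, and exhaustive enumeration for all hypergeometric
instances with a universe of 12 or fewer genes. `runPipeline()` uses
smaller defaults (64-px sections, 300 genes, 25 scans) tuned for a
quick end-to-end exercise; all of its thresholds are the analysis
defaults (θ = 2.5, DS < 0.2, 10% missingness, α = 0.01, |log2FC| > 0.3,
FWHM 10 mm, window 25, 2.5 SD, 5% scan drop).

## 9. Known limitations

* The appearance model is per-label Gaussian; it cannot synthesise
  spatial texture, so detection relies on colour statistics alone and
  will miss artifacts that preserve hue and saturation (a fold that
  only darkens value is found by its saturation edge, or not at all).
* Registration is rigid + affine only; nonlinear inter-section warping
  and template construction are out of scope, as are surface
  extraction and cross-subject surface registration (surfaces arrive
  already in correspondence).
* The ZRT screen's intersection set has controlled per-factor FDR but
  no separate guarantee on the triple intersection (§4).
* Mesh smoothing approximates a geodesic Gaussian by neighbour
  averaging; kernel anisotropy on irregular meshes is uncorrected.
* Kendall p values for tied regional profiles use the normal
  approximation, as exact enumeration under ties is not attempted.
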