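# fetalcortex

Tools for studying how the human cerebral cortex expands during the
second half of gestation, linking three kinds of evidence: serial
histology of the mid-gestation brain, laser-microdissection (LMD)
microarray expression sampled across cortical regions and transient
tissue zones, and fetal MRI surface reconstructions. The package is
aimed at developmental neuroscientists and imaging-transcriptomics
researchers who need each stage of that analysis chain as tested,
seedable R functions.

Five analysis stages are covered, each with a seeded synthetic-data
generator that produces inputs with known ground truth:

1. **Histology repair.** Serial Nissl-stained sections suffer tears,
   folds and staining artifacts. A per-label appearance model
   synthesizes the section's expected look from its anatomical
   annotations (`fitLabelAppearance()`, `synthesizeSection()`,
   patchwise via `tileAndStitch()`); pixels whose hue and saturation
   deviate robustly from the prediction
   (`|d − median(d)| / MAD(d) > θ`, default θ = 2.5) are flagged
   (`detectArtifacts()`) and repaired by Poisson image editing — a
   sparse solve of `∇²f = ∇²(synthetic)` inside the mask with Dirichlet
   boundary values from the original (`poissonRepair()`,
   `repairSection()`).
2. **Stack reconstruction.** Pairwise rigid registrations (normalised
   cross-correlation, coarse-to-fine search) become edges of a directed
   graph pointing at the middle reference section; Dijkstra's algorithm
   picks the cheapest composition of transforms per section
   (`buildAlignmentGraph()`, `shortestPathTransforms()`,
   `applyTransforms()`). A shape-prior-constrained affine refinement
   (`shapePriorAffine()`) suppresses z-shift, ISH sections are projected
   into the aligned geometry (`projectIsh()`, `regionalIshMeans()`), and
   the stack exports as an isotropic NIfTI volume (`exportVolume()`).
3. **Expression processing.** Probe-level microarray tables are
   filtered (multi-gene, unannotated and absent probes removed), scored
   by differential stability — the mean cross-specimen Pearson
   correlation of each probe's regional profile — and reduced to one
   probe per gene (DS < 0.2 dropped), then aggregated into a gene ×
   specimen × region × zone tensor with a 10% missingness ceiling
   (`filterProbes()`, `differentialStability()`,
   `selectProbePerGene()`, `aggregateSamples()`).
4. **ZRT screening.** Per gene, an OLS model with main effects of
   tissue zone, cortical region and timepoint (early ≤ 16 PCW vs mid
   gestation); partial F tests per factor, Benjamini–Hochberg FDR across
   genes within each factor, and the ZRT set as the triple intersection
   at q < 0.01 (`fitZrtModels()`, `classifyZrt()`,
   `zoneFoldChange()`).
5. **Allometric scaling and enrichment.** At every cortical vertex,
   `log10 a_v = β_v log10 A + b + ε` is fit across a cohort by OLS after
   curvature correction, mesh smoothing (FWHM 10 mm) and sliding-window
   outlier screening; β > 1 marks hyperallometric (preferentially
   expanding) cortex (`scalingAnalysis()` and friends). Regional
   expression is then correlated with parcel-mean β (Kendall tau-b,
   FDR), and gene sets are tested by hypergeometric enrichment
   (`p = P(X ≥ x)`, enrichment ratio `(x/N)/(K/M)`), odds ratios and
   permutation tests against random gene sets
   (`expressionScalingAssociation()`, `hypergeometricEnrichment()`,
   `proportionOddsRatio()`, `permutationMedianTest()`).

`runPipeline()` drives all stages end-to-end from a single (YAML-able)
configuration on synthetic data, writing per-stage tables and a JSON run
report.

## Worked example

Simulate a surface cohort with a known scaling field, recover it, and
relate regional expression to regional expansion:

```r
library(fetalcortex)

s <- simulateSurfaceCohort(nSubjects = 60, subdivisions = 4,
                           betaRange = c(0.7, 1.3), noiseSd = 0.02,
                           curvatureLeak = 0.05, seed = 42)
res <- scalingAnalysis(s@cohort)
ok <- is.finite(res@beta) & !s@cohort@medialWall
sqrt(mean((res@beta[ok] - s@betaField[ok])^2))
#> [1] 0.0147229

round(res@parcelMeans, 2)
#>  R01  R02  R03  R04  R05  R06  R07  R08  R09  R10  R11  R12
#> 0.74 0.79 0.83 0.88 0.93 0.98 1.03 1.07 1.12 1.17 1.22 1.27
```

The per-vertex β is recovered with RMSE ≈ 0.015 (noise sd 0.02, 60
scans), and the parcel means run from clearly hypoallometric (β ≈ 0.74,
slower than whole-cortex growth) to clearly hyperallometric (β ≈ 1.27).
Feeding a tensor with planted monotone regional expression into
`expressionScalingAssociation()` against these parcel means flags the
planted genes at q < 0.01 with tau near 1; and the printed study
proportions reproduce the headline contrast directly:

```r
proportionOddsRatio(p1 = 0.201, p2 = 0.083)$oddsRatio
#> [1] 2.779333
```

i.e. significant expression–scaling associations are ~2.78 times more
likely among ZRT genes than among other genes.

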