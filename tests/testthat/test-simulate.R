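test_that("all generators are deterministic for a fixed seed", {
  h1 <- simulateHistologyStack(nSections = 3, height = 48, width = 48,
                               nLabels = 3, seed = 9)
  h2 <- simulateHistologyStack(nSections = 3, height = 48, width = 48,
                               nLabels = 3, seed = 9)
  expect_identical(h1@corrupted@sections[[2]]@image,
                   h2@corrupted@sections[[2]]@image)
  expect_identical(h1@injectionLog, h2@injectionLog)
  e1 <- simulateExpressionDataset(nGenes = 50, seed = 5)
  e2 <- simulateExpressionDataset(nGenes = 50, seed = 5)
  expect_identical(e1@tensor@values, e2@tensor@values)
  s1 <- simulateSurfaceCohort(nSubjects = 5, subdivisions = 2, seed = 5)
  s2 <- simulateSurfaceCohort(nSubjects = 5, subdivisions = 2, seed = 5)
  expect_identical(s1@cohort@area, s2@cohort@area)
  a1 <- simulateAnnotationResources(nGenes = 200, seed = 5)
  a2 <- simulateAnnotationResources(nGenes = 200, seed = 5)
  expect_identical(a1$geneSets, a2$geneSets)
})

test_that("zero artifact rates corrupt only by rigid misalignment", {
  h <- simulateHistologyStack(nSections = 3, height = 48, width = 48,
                              nLabels = 3, tearsPerSection = 0,
                              foldsPerSection = 0, stainsPerSection = 0,
                              seed = 4)
  expect_true(all(vapply(h@artifactMasks, sum, 1) == 0))
  for (i in 1:3) {
    expected <- resampleRigid(h@clean@sections[[i]]@image,
                              h@trueTransforms[[i]], "bilinear",
                              background = 1)
    expect_equal(h@corrupted@sections[[i]]@image, expected)
  }
  # the middle (reference) section keeps the identity
  mid <- h@trueTransforms[[2]]
  expect_identical(c(mid@rotation, mid@tx, mid@ty), c(0, 0, 0))
})

test_that("artifact masks mark exactly the injected pixels", {
  h <- tearStack()
  for (i in seq_along(h@artifactMasks)) {
    misaligned <- resampleRigid(h@clean@sections[[i]]@image,
                                h@trueTransforms[[i]], "bilinear",
                                background = 1)
    differs <- apply(abs(h@corrupted@sections[[i]]@image - misaligned) >
                       1e-12, c(1, 2), any)
    mask <- h@artifactMasks[[i]]
    expect_identical(sum(differs & !mask), 0L)  # conservative masks
    expect_identical(sum(mask & !differs), 0L)  # no phantom flags
  }
  # conservation against the injection log (tears only, so no overlap
  # between artifact types; overlapping tears can only shrink the union)
  logTotal <- sum(h@injectionLog$nPixels)
  maskTotal <- sum(vapply(h@artifactMasks, sum, 1))
  expect_lte(maskTotal, logTotal)
  expect_gte(maskTotal, 0.9 * logTotal)
})

test_that("expression generator plants the advertised factor structure", {
  # noiseless gene with only a zone effect
  e <- simulateExpressionDataset(nGenes = 30,
                                 effectFractions = c(zone = 1, region = 0,
                                                     time = 0),
                                 noiseSd = 0, seed = 2)
  v <- e@tensor@values[1, , , ]
  zoneMeans <- apply(v, 3, mean)
  expect_gt(max(zoneMeans) - min(zoneMeans), 0.1)
  withinZone <- apply(v, 3, function(m) max(m) - min(m))
  expect_lt(max(withinZone), 1e-12)
  # no effects: per-gene variance matches the noise level in expectation
  e0 <- simulateExpressionDataset(nGenes = 400,
                                  effectFractions = c(zone = 0, region = 0,
                                                      time = 0),
                                  noiseSd = 0.5, seed = 3)
  vars <- apply(e0@tensor@values, 1, var)
  expect_lt(abs(mean(vars) - 0.25), 0.01)
  # planted ZRT count equals the conjunction of flags
  e3 <- simulateExpressionDataset(nGenes = 2000,
                                  effectFractions = c(zone = 0.1,
                                                      region = 0.1,
                                                      time = 0.1), seed = 8)
  f <- e3@flags
  expect_identical(length(plantedZrtGenes(e3)),
                   sum(f$zoneEffect & f$regionEffect & f$timeEffect))
  expect_error(simulateExpressionDataset(
    effectFractions = c(zone = 1.2, region = 0, time = 0)), "fraction")
})

test_that("surface generator realises the log-log area model", {
  # isometry: every vertex is an age-independent fraction of total area
  V <- 162
  si <- simulateSurfaceCohort(nSubjects = 8, subdivisions = 2,
                              betaField = rep(1, V), noiseSd = 0,
                              curvatureLeak = 0, seed = 2)
  frac <- sweep(si@cohort@area, 2, totalArea(si@cohort), "/")
  expect_lt(max(apply(frac, 1, function(r) diff(range(r)))), 1e-12)
  # two-point slope-2 case at a designated vertex
  bf <- rep(1, V); bf[10] <- 2
  s2 <- simulateSurfaceCohort(nSubjects = 2, subdivisions = 2,
                              betaField = bf, totalAreas = c(10, 100),
                              noiseSd = 0, curvatureLeak = 0, seed = 2)
  expect_equal(unname(s2@cohort@area[10, 2] / s2@cohort@area[10, 1]), 100,
               tolerance = 1e-9)
  # refitting the generative regression recovers the beta field
  st <- surfaceTruth()
  # fit against the generative predictor (the target log-total the areas
  # were drawn from), so residuals are pure noise
  x <- st@totalAreaCurve$targetLog10A
  ok <- which(!st@cohort@medialWall)
  resid <- vapply(ok, function(v) {
    fit <- stats::lm.fit(cbind(1, x), log10(st@cohort@area[v, ]))
    fit$coefficients[2] - st@betaField[v]
  }, numeric(1))
  se <- st@config$noiseSd / (stats::sd(x) * sqrt(length(x) - 1))
  expect_lt(mean(abs(resid) > 3 * se), 0.02)
  expect_error(simulateSurfaceCohort(betaRange = c(-2, -1)), "positive")
})

test_that("annotation generator plants enrichment, probes and score shifts", {
  a <- simulateAnnotationResources(nGenes = 500, interestFraction = 0.2,
                                   geneSets = data.frame(
                                     name = c("enriched", "uniform"),
                                     size = c(60, 60),
                                     enrichmentRatio = c(2.5, 1)),
                                   scoreNoiseSd = 0, scoreShift = -0.3,
                                   seed = 7)
  ov <- length(intersect(a$geneSets$enriched, a$interestSet))
  expect_identical(ov, as.integer(round(2.5 * 60 * 100 / 500)))
  # noiseless planted median shift is exact
  sc <- stats::setNames(a$scoreTable$score, a$scoreTable$gene)
  expect_equal(stats::median(sc[a$plantedLowSet]) -
                 stats::median(sc[setdiff(a$universe, a$plantedLowSet)]),
               -0.3)
  expect_error(simulateAnnotationResources(
    nGenes = 100, interestFraction = 0.1,
    geneSets = data.frame(name = "bad", size = 20, enrichmentRatio = 10),
    seed = 1), "exceeds")
  # one probe per gene makes probe selection the identity on genes
  b <- simulateAnnotationResources(nGenes = 50, maxProbesPerGene = 1,
                                   geneSets = data.frame(name = "s",
                                                         size = 10,
                                                         enrichmentRatio = 1),
                                   absentRate = 0, multiGeneRate = 0,
                                   seed = 3)
  expect_identical(sort(b$probeTable$gene), sort(b$universe))
  expect_identical(anyDuplicated(b$probeTable$gene), 0L)
})
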