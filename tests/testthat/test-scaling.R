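test_that("curvature correction removes the folding leak and nothing else", {
  st <- simulateSurfaceCohort(nSubjects = 60, subdivisions = 2,
                              noiseSd = 0.02, curvatureLeak = 0.3, seed = 14)
  corrected <- correctVertexArea(st@cohort, fwhmMm = 0)
  # refit beta on corrected areas: closer to the truth than uncorrected
  fitBeta <- function(cohort) {
    x <- st@totalAreaCurve$targetLog10A
    ok <- which(!cohort@medialWall)
    vapply(ok, function(v)
      stats::lm.fit(cbind(1, x), log10(cohort@area[v, ]))$coefficients[2],
      numeric(1))
  }
  rmseRaw <- sqrt(mean((fitBeta(st@cohort) -
                          st@betaField[!st@cohort@medialWall])^2))
  rmseCor <- sqrt(mean((fitBeta(corrected) -
                          st@betaField[!st@cohort@medialWall])^2))
  expect_lt(rmseCor, rmseRaw)
  # with no leak the curvature channel is static and correction is a no-op
  s0 <- simulateSurfaceCohort(nSubjects = 10, subdivisions = 2,
                              curvatureLeak = 0, noiseSd = 0.02, seed = 5)
  c0 <- correctVertexArea(s0@cohort, fwhmMm = 0)
  expect_lt(max(abs(c0@area - s0@cohort@area)), 1e-6)
  # exact collinearity: log-area = 2 * curvature + const per vertex
  s1 <- simulateSurfaceCohort(nSubjects = 6, subdivisions = 2,
                              curvatureLeak = 0.3, noiseSd = 0.02, seed = 6)
  coh <- s1@cohort
  coh@area <- 10^(2 * coh@curvature + 0.5)
  c1 <- correctVertexArea(coh, fwhmMm = 0)
  expect_lt(max(apply(log10(c1@area), 1, function(r) diff(range(r)))), 1e-9)
})

test_that("mesh smoothing approximates the configured kernel width", {
  s <- simulateSurfaceCohort(nSubjects = 2, subdivisions = 4, seed = 3)
  coh <- s@cohort
  V <- nrow(coh@vertices)
  delta <- numeric(V); src <- which(!coh@medialWall)[100]
  delta[src] <- 1
  fwhm <- 10
  sm <- smoothMeshMetric(delta, coh, fwhmMm = fwhm)
  # geodesic distance on the sphere from the source vertex
  r <- sqrt(sum(coh@vertices[1, ]^2))
  cosang <- pmin(1, pmax(-1, (coh@vertices %*% coh@vertices[src, ]) / r^2))
  gd <- r * acos(cosang)
  half <- max(sm) / 2
  # FWHM measured from the smoothed profile: twice the median distance of
  # profile values nearest the half maximum
  ring <- gd[order(abs(sm - half))[1:12]]
  measured <- 2 * stats::median(ring)
  expect_lt(abs(measured - fwhm) / fwhm, 0.2)
})

test_that("total-area growth model recovers exact and simulated slopes", {
  s <- surfaceTruth()
  coh <- s@cohort
  # exact: A = 10^(0.05 * age)
  cohX <- coh
  ages <- coh@subjects$ageWeeks
  V <- nrow(coh@area)
  cohX@area <- matrix(rep(10^(0.05 * ages) / sum(!coh@medialWall), each = V),
                      V, length(ages))
  tm <- suppressWarnings(totalAreaModel(cohX))
  expect_equal(tm$coefficients$estimate[2], 0.05, tolerance = 1e-9)
  # constant area: zero slope
  cohC <- coh
  cohC@area <- matrix(1, V, length(ages))
  expect_equal(suppressWarnings(totalAreaModel(cohC))$coefficients$estimate[2],
               0, tolerance = 1e-9)
  # simulated growth: recovered within 2 standard errors
  tmS <- totalAreaModel(coh)
  expect_lt(abs(tmS$coefficients$estimate[2] - s@config$growthSlope),
            2 * tmS$coefficients$se[2] + 0.002)
  narrow <- coh
  narrow@subjects$ageWeeks <- rep(30, length(ages))
  expect_error(totalAreaModel(narrow), "age range")
})

test_that("sliding-window screening flags planted outliers and drops bad
           scans", {
  # identical scans: nothing flagged
  s0 <- simulateSurfaceCohort(nSubjects = 10, subdivisions = 2,
                              noiseSd = 0, curvatureLeak = 0, seed = 2)
  om0 <- windowOutlierMask(s0@cohort)
  expect_identical(sum(om0$excluded), 0L)
  expect_identical(length(om0$droppedScans), 0L)
  # one inflated vertex: the (scan, vertex) pair is flagged, scan kept
  s1 <- simulateSurfaceCohort(nSubjects = 30, subdivisions = 2,
                              noiseSd = 0.02, nOutliers = 1,
                              outlierFactor = 10, seed = 9)
  om1 <- windowOutlierMask(s1@cohort)
  inj <- s1@outlierInjections
  expect_true(om1$excluded[inj$vertex[1], inj$scanId[1]])
  expect_false(inj$scanId[1] %in% om1$droppedScans)
  # 10% of vertices inflated on one scan: the whole scan is dropped
  s2 <- simulateSurfaceCohort(nSubjects = 30, subdivisions = 2,
                              noiseSd = 0.02, seed = 9)
  coh <- s2@cohort
  nm <- which(!coh@medialWall)
  bad <- nm[seq_len(ceiling(0.1 * length(nm)))]
  coh@area[bad, 7] <- coh@area[bad, 7] * 10
  om2 <- windowOutlierMask(coh)
  expect_true(coh@subjects$scanId[7] %in% om2$droppedScans)
  expect_error(windowOutlierMask(
    simulateSurfaceCohort(nSubjects = 2, subdivisions = 1, seed = 1)@cohort),
    "at least 3")
})

test_that("vertexwise scaling is exact on constructed cases and invariant
           to global rescaling", {
  s <- simulateSurfaceCohort(nSubjects = 12, subdivisions = 2,
                             betaField = rep(1, 162), noiseSd = 0,
                             curvatureLeak = 0, seed = 4)
  res <- fitVertexScaling(s@cohort)
  ok <- is.finite(res@beta)
  expect_lt(max(abs(res@beta[ok] - 1)), 1e-9)      # a_v = c * A => beta = 1
  # global rescaling shifts intercepts only
  scaled <- s@cohort
  scaled@area <- scaled@area * 3.7
  res2 <- fitVertexScaling(scaled)
  expect_equal(res2@beta[ok], res@beta[ok], tolerance = 1e-9)
  # two-point slope: a designated vertex with log10 a = 2 log10 A against
  # totals of exactly 10 and 100 (the remaining vertices absorb the rest,
  # keeping the realized totals equal to the targets)
  two <- simulateSurfaceCohort(nSubjects = 2, subdivisions = 2, seed = 4)
  coh <- two@cohort
  A <- c(10, 100)
  des <- which(!coh@medialWall)[5]
  nEff <- sum(!coh@medialWall)
  areas <- matrix(0.01, nrow(coh@area), 2)
  aDes <- 1e-4 * A^2                 # slope 2 through (1, -2), (2, 0)
  for (j in 1:2) {
    areas[!coh@medialWall, j] <- (A[j] - aDes[j]) / (nEff - 1)
    areas[des, j] <- aDes[j]
  }
  colnames(areas) <- coh@subjects$scanId
  coh@area <- areas
  expect_equal(unname(totalArea(coh)), A)
  r2 <- fitVertexScaling(coh, scalingConfig(minN = 2))
  expect_lt(abs(r2@beta[des] - 2), 1e-9)
  # insufficient scans leave beta undefined
  r3 <- fitVertexScaling(coh, scalingConfig(minN = 10))
  expect_true(all(!is.finite(r3@beta)))
})

test_that("parcel means agree with a brute-force per-parcel loop", {
  s <- surfaceTruth()
  res <- parcellateScaling(fitVertexScaling(s@cohort), s@cohort)
  coh <- s@cohort
  for (p in names(res@parcelMeans)) {
    sel <- which(coh@parcel == p & !coh@medialWall &
                   is.finite(res@beta))
    expect_equal(unname(res@parcelMeans[p]), mean(res@beta[sel]))
    expect_identical(unname(res@parcelN[p]), length(sel))
  }
  # constant map: every parcel mean equals the constant
  resC <- res
  resC@beta <- rep(0.85, length(res@beta))
  resC <- parcellateScaling(resC, coh)
  expect_true(all(abs(resC@parcelMeans - 0.85) < 1e-12))
})

test_that("beta recovery holds across the plausible coefficient grid", {
  # a spatially uniform beta field rescales the realized total with the
  # vertices, so recovery is measured against the generative predictor
  for (b in c(0.7, 1.0, 1.3)) {
    s <- simulateSurfaceCohort(nSubjects = 60, subdivisions = 2,
                               betaField = rep(b, 162), noiseSd = 0.02,
                               curvatureLeak = 0, seed = round(100 * b))
    x <- s@totalAreaCurve$targetLog10A
    ok <- which(!s@cohort@medialWall)
    betas <- vapply(ok, function(v)
      stats::lm.fit(cbind(1, x),
                    log10(s@cohort@area[v, ]))$coefficients[2], numeric(1))
    expect_lt(abs(mean(betas) - b), 0.02)
  }
})
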