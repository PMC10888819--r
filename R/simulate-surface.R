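# Seeded generator for surface cohorts whose vertex areas follow the
# log-log allometric generative model with a known per-vertex beta field.

#' Triangulated icosphere
#'
#' Icosahedron subdivision; `subdivisions = s` yields `10 * 4^s + 2`
#' vertices on the unit sphere.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius (mm).
#' @return List with `vertices` (V x 3) and `faces` (F x 3, 1-based).
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    getMid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  storage.mode(f) <- "integer"
  list(vertices = v * radius, faces = f)
}

# vertex adjacency (list of integer neighbour vectors) from a face matrix
.meshNeighbors <- function(faces, nVertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(nVertices)))
}

#' Simulate a fetal surface cohort with a known scaling field
#'
#' Generates a cohort of scans sharing one icosphere topology. Target
#' total areas grow log-linearly with age
#' (`log10 A = growthIntercept + growthSlope * (age - mean(age))`) and
#' per-vertex areas follow the allometric generative model
#' `log10 a_v = b0_v + beta_v * (log10 A - mean(log10 A)) + noise`,
#' with `b0_v` calibrated so that the non-medial areas of an average-age
#' subject sum to its total. A per-vertex curvature channel is generated
#' with a configurable multiplicative leak into area, to exercise the
#' curvature correction, and aberrant areas can be planted at random
#' (scan, vertex) pairs to exercise outlier screening.
#'
#' @param nSubjects number of scans.
#' @param subdivisions icosphere subdivision level (4 gives 2562 vertices).
#' @param ageRangeWeeks gestational-age range; ages are uniform over it.
#' @param betaRange range of the true beta field, which varies linearly
#'   with the vertex z-coordinate and must contain positive values.
#' @param betaField optional explicit per-vertex beta vector (overrides
#'   `betaRange`).
#' @param totalAreas optional explicit target total areas (mm^2),
#'   overriding the growth curve (lengths recycled to `nSubjects`).
#' @param noiseSd residual sd of `log10` vertex area.
#' @param curvatureLeak multiplicative leak of the subject-varying
#'   curvature component into `log10` area.
#' @param nOutliers number of planted aberrant (scan, vertex) areas.
#' @param outlierFactor multiplicative factor applied to planted outliers.
#' @param growthSlope,growthIntercept growth model of `log10` total area
#'   per week of age (centred at the mean age).
#' @param nParcels number of parcels (longitude sectors).
#' @param radius mesh radius in mm.
#' @param medialWallZ vertices with unit-sphere z above this form the
#'   medial wall.
#' @param curvatureSd sd of the subject-varying curvature component.
#' @param seed integer seed.
#' @return A [SurfaceSimTruth-class] object.
#' @export
simulateSurfaceCohort <- function(nSubjects = 60, subdivisions = 4,
                                  ageRangeWeeks = c(21, 38),
                                  betaRange = c(0.7, 1.3), betaField = NULL,
                                  totalAreas = NULL, noiseSd = 0.02,
                                  curvatureLeak = 0, nOutliers = 0,
                                  outlierFactor = 8, growthSlope = 0.054,
                                  growthIntercept = 3.4, nParcels = 12,
                                  radius = 30, medialWallZ = 0.92,
                                  curvatureSd = 0.15, seed = 1) {
  stopIfNot(nSubjects >= 2, "need at least 2 subjects")
  if (is.null(betaField))
    stopIfNot(max(betaRange) > 0, "betaRange must contain positive values")
  mesh <- icosphere(subdivisions, radius)
  V <- nrow(mesh$vertices)
  zUnit <- mesh$vertices[, 3] / radius
  if (is.null(betaField))
    betaField <- mean(betaRange) + diff(betaRange) / 2 * zUnit
  stopIfNot(length(betaField) == V, "betaField must have one value per vertex")
  medial <- zUnit > medialWallZ
  if (!any(!medial)) stop("medial wall covers the whole mesh")
  # latitude-band parcels (equal surface area on a sphere): parcel index
  # increases with z, so parcel-mean beta is monotone in R01, R02, ...
  parcel <- sprintf("R%02d", as.integer(cut(pmin(zUnit, medialWallZ),
    breaks = seq(-1, medialWallZ, length.out = nParcels + 1),
    include.lowest = TRUE)))

  withSeed(seed, {
    ages <- sort(stats::runif(nSubjects, ageRangeWeeks[1], ageRangeWeeks[2]))
    sex <- sample(c("F", "M"), nSubjects, replace = TRUE)
    L <- if (is.null(totalAreas))
      growthIntercept + growthSlope * (ages - mean(ages))
    else log10(rep_len(totalAreas, nSubjects))
    Lbar <- mean(L)
    nEff <- sum(!medial)
    b0 <- rep(log10(1 / nEff) + Lbar, V)
    curvMu <- 0.1 + 0.05 * sin(2 * pi * zUnit)          # static component
    # the subject-varying curvature fluctuation exists to drive the
    # folding-bias leak; with no leak the channel is a static map and
    # curvature correction is exactly a no-op (zero-variance regressor)
    eta <- if (curvatureLeak == 0) matrix(0, V, nSubjects) else
      matrix(stats::rnorm(V * nSubjects, 0, curvatureSd), V, nSubjects)
    curvature <- curvMu + eta
    eps <- matrix(stats::rnorm(V * nSubjects, 0, noiseSd), V, nSubjects)
    logA <- b0 + outer(betaField, L - Lbar) + curvatureLeak * eta + eps
    area <- 10^logA
    inj <- data.frame(scanId = character(), vertex = integer(),
                      factor = numeric())
    if (nOutliers > 0) {
      nm <- which(!medial)
      vs <- nm[sample.int(length(nm), nOutliers, replace = TRUE)]
      ss <- sample.int(nSubjects, nOutliers, replace = TRUE)
      for (i in seq_len(nOutliers))
        area[vs[i], ss[i]] <- area[vs[i], ss[i]] * outlierFactor
      inj <- data.frame(scanId = sprintf("scan%03d", ss), vertex = vs,
                        factor = outlierFactor)
    }
    subjects <- data.frame(scanId = sprintf("scan%03d", seq_len(nSubjects)),
                           subjectId = sprintf("sub%03d", seq_len(nSubjects)),
                           ageWeeks = ages, sex = sex,
                           stringsAsFactors = FALSE)
    colnames(area) <- subjects$scanId
    colnames(curvature) <- subjects$scanId
    cohort <- methods::new("SurfaceCohort", vertices = mesh$vertices,
                           faces = mesh$faces, area = area,
                           curvature = curvature, medialWall = medial,
                           parcel = parcel, subjects = subjects)
    methods::new("SurfaceSimTruth", cohort = cohort, betaField = betaField,
                 totalAreaCurve = data.frame(scanId = subjects$scanId,
                                             ageWeeks = ages,
                                             targetLog10A = L,
                                             realizedTotal = totalArea(cohort)),
                 outlierInjections = inj,
                 config = list(noiseSd = noiseSd, curvatureLeak = curvatureLeak,
                               growthSlope = growthSlope,
                               growthIntercept = growthIntercept,
                               radius = radius, seed = seed))
  })
}
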