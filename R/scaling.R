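# Vertexwise allometric scaling of cortical surface area: curvature
# correction and mesh smoothing, cohort growth model, sliding-window
# outlier screening, per-vertex log-log regression and parcel
# aggregation.

#' Scaling configuration
#'
#' @param fwhmMm Gaussian smoothing kernel full width at half maximum
#'   (mm).
#' @param windowSize maximum sliding window size (scans, sorted by age)
#'   for outlier screening.
#' @param outlierZ flag threshold in window standard deviations.
#' @param scanDropFraction scans flagged at more than this fraction of
#'   vertices are dropped entirely.
#' @param minN minimum scans per vertex for a defined beta.
#' @return Validated list of class `ScalingConfig`.
#' @export
scalingConfig <- function(fwhmMm = 10, windowSize = 25, outlierZ = 2.5,
                          scanDropFraction = 0.05, minN = 10) {
  stopIfNot(fwhmMm > 0, "fwhmMm must be > 0")
  stopIfNot(windowSize >= 3, "windowSize must be >= 3")
  structure(list(fwhmMm = fwhmMm, windowSize = windowSize,
                 outlierZ = outlierZ, scanDropFraction = scanDropFraction,
                 minN = minN), class = "ScalingConfig")
}

# mean mesh edge length (mm)
.meanEdgeLength <- function(vertices, faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  mean(sqrt(rowSums((vertices[e[, 1], ] - vertices[e[, 2], ])^2)))
}

# row-normalised one-ring averaging operator (self + neighbours)
.smoothingOperator <- function(faces, nVertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = c(e[, 1], seq_len(nVertices)),
                            j = c(e[, 2], seq_len(nVertices)),
                            x = 1, dims = c(nVertices, nVertices))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
}

#' Smooth a per-vertex metric on the mesh
#'
#' Iterated one-ring neighbour averaging calibrated to approximate a
#' geodesic Gaussian kernel: the iteration count is chosen so that the
#' accumulated kernel variance matches `sigma^2 = (FWHM / 2.355)^2`
#' given the mean edge length.
#'
#' @param values numeric vector (or V x S matrix) of vertex values.
#' @param cohort a [SurfaceCohort-class] supplying the topology.
#' @param fwhmMm target kernel FWHM in mm.
#' @return Smoothed values, same shape.
#' @export
smoothMeshMetric <- function(values, cohort, fwhmMm = 10) {
  V <- nrow(cohort@vertices)
  h <- .meanEdgeLength(cohort@vertices, cohort@faces)
  deg <- 6  # icosphere-like meshes are predominantly 6-regular
  sigmaStep2 <- h^2 * deg / (deg + 1)
  sigma <- fwhmMm / 2.355
  iters <- max(0L, round(sigma^2 / sigmaStep2))
  if (iters == 0L) return(values)
  Wop <- .smoothingOperator(cohort@faces, V)
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  for (i in seq_len(iters)) m <- as.matrix(Wop %*% m)
  if (is.matrix(values)) m else as.numeric(m)
}

#' Correct vertex areas for folding bias and smooth on the mesh
#'
#' At each vertex, regresses `log10` area on curvature across subjects
#' (OLS, controlling for `log10` total area so that size-driven area
#' variation is not absorbed into the curvature term) and removes the
#' fitted curvature component; vertices with zero-variance curvature are
#' left unchanged. Corrected areas are then smoothed per subject on the
#' mesh with a kernel calibrated to `fwhmMm`.
#'
#' @param cohort a [SurfaceCohort-class].
#' @param fwhmMm smoothing kernel FWHM (mm); `0` disables smoothing.
#' @return The cohort with corrected, smoothed areas.
#' @export
correctVertexArea <- function(cohort, fwhmMm = 10) {
  A <- log10(cohort@area)
  C <- cohort@curvature
  x <- log10(totalArea(cohort))
  cm <- rowMeans(C)
  corrected <- A
  for (v in seq_len(nrow(A))) {
    if (stats::var(C[v, ]) < 1e-12) next
    fit <- stats::lm.fit(cbind(1, C[v, ], x), A[v, ])
    bCurv <- fit$coefficients[2]
    if (!is.finite(bCurv)) next
    corrected[v, ] <- A[v, ] - bCurv * (C[v, ] - cm[v])
  }
  area <- 10^corrected
  if (fwhmMm > 0) area <- smoothMeshMetric(area, cohort, fwhmMm)
  out <- cohort
  out@area <- area
  out
}

#' Growth model of total cortical surface area
#'
#' OLS of `log10` total area on age in weeks, optionally with sex and
#' age-by-sex terms; total area is the sum of non-medial-wall vertex
#' areas per scan.
#'
#' @param cohort a [SurfaceCohort-class].
#' @param includeSex add sex and age:sex terms.
#' @return List with `coefficients` (estimate, se, p), the fitted `model`
#'   and, when `includeSex`, an F-test comparison against the
#'   age-only model.
#' @export
totalAreaModel <- function(cohort, includeSex = FALSE) {
  df <- data.frame(logA = log10(totalArea(cohort)),
                   age = cohort@subjects$ageWeeks,
                   sex = factor(cohort@subjects$sex))
  stopIfNot(nrow(df) >= 10, "need >= 10 subjects")
  stopIfNot(diff(range(df$age)) >= 5, "age range too narrow (need >= 5 weeks)")
  base <- stats::lm(logA ~ age, df)
  fit <- if (includeSex) stats::lm(logA ~ age * sex, df) else base
  sm <- summary(fit)$coefficients
  out <- list(coefficients = data.frame(term = rownames(sm),
                                        estimate = sm[, 1], se = sm[, 2],
                                        p = sm[, 4], row.names = NULL),
              model = fit)
  if (includeSex) out$comparison <- stats::anova(base, fit)
  out
}

#' Sliding-window vertexwise outlier screening
#'
#' Scans are sorted by age; for each scan the window holds the up-to-
#' `windowSize` nearest scans in the sorted order (centred, truncated at
#' the ends). A (scan, vertex) pair is flagged when the vertex area
#' deviates from the window mean by more than `outlierZ` standard
#' deviations, both computed leaving the tested scan out. Scans flagged
#' at more than `scanDropFraction` of non-medial vertices are dropped
#' entirely.
#'
#' @param cohort a [SurfaceCohort-class].
#' @param cfg a [scalingConfig()].
#' @return List with `excluded` (V x S logical), `droppedScans`
#'   (character) and `flagFraction` per scan.
#' @export
windowOutlierMask <- function(cohort, cfg = scalingConfig()) {
  S <- nrow(cohort@subjects)
  stopIfNot(S >= 3, "need at least 3 scans")
  V <- nrow(cohort@area)
  ord <- order(cohort@subjects$ageWeeks)
  w <- min(cfg$windowSize, S)
  excluded <- matrix(FALSE, V, S,
                     dimnames = list(NULL, cohort@subjects$scanId))
  half <- (w - 1) %/% 2
  A <- cohort@area
  for (pos in seq_len(S)) {
    lo <- min(max(1, pos - half), max(1, S - w + 1))
    win <- ord[lo:min(S, lo + w - 1)]
    s <- ord[pos]
    others <- setdiff(win, s)
    if (length(others) < 2) next
    sub <- A[, others, drop = FALSE]
    mu <- rowMeans(sub)
    sd_ <- sqrt(rowSums((sub - mu)^2) / (length(others) - 1))
    dev <- abs(A[, s] - mu)
    excluded[, s] <- dev > cfg$outlierZ * sd_
  }
  excluded[cohort@medialWall, ] <- FALSE
  flagFraction <- colSums(excluded[!cohort@medialWall, , drop = FALSE]) /
    sum(!cohort@medialWall)
  dropped <- cohort@subjects$scanId[flagFraction > cfg$scanDropFraction]
  list(excluded = excluded, droppedScans = dropped,
       flagFraction = flagFraction)
}

#' Vertexwise allometric scaling coefficients
#'
#' At each non-medial-wall vertex, OLS of `log10(vertex area)` on
#' `log10(total area)` across scans, after removing dropped scans and
#' excluded (scan, vertex) pairs. The slope beta reads directly against
#' 1: `beta > 1` is hyperallometric (the vertex expands faster than the
#' cortex as a whole), `beta < 1` hypoallometric. Optionally sex and
#' sex-by-area terms can be included as covariates.
#'
#' @param cohort a [SurfaceCohort-class] (typically curvature-corrected).
#' @param cfg a [scalingConfig()].
#' @param exclusions optional V x S logical matrix from
#'   [windowOutlierMask()].
#' @param droppedScans scans to remove entirely.
#' @param covariates if `TRUE`, include sex and sex:log10(total area)
#'   terms.
#' @return A [ScalingResult-class] (parcel slots filled by
#'   [parcellateScaling()]).
#' @export
fitVertexScaling <- function(cohort, cfg = scalingConfig(),
                             exclusions = NULL, droppedScans = character(),
                             covariates = FALSE) {
  keepScan <- !(cohort@subjects$scanId %in% droppedScans)
  A <- cohort@area[, keepScan, drop = FALSE]
  V <- nrow(A); S <- ncol(A)
  excl <- if (is.null(exclusions)) matrix(FALSE, V, S) else
    exclusions[, keepScan, drop = FALSE]
  x <- log10(colSums(A[!cohort@medialWall, , drop = FALSE]))
  Yl <- log10(A)
  beta <- intercept <- residSd <- rep(NA_real_, V)
  nUsed <- integer(V)
  sexF <- factor(cohort@subjects$sex[keepScan])
  useCov <- covariates && nlevels(sexF) > 1
  for (v in seq_len(V)) {
    if (cohort@medialWall[v]) next
    ok <- !excl[v, ] & is.finite(Yl[v, ])
    n <- sum(ok)
    nUsed[v] <- n
    if (n < cfg$minN) next
    xv <- x[ok]; yv <- Yl[v, ok]
    if (useCov) {
      fit <- stats::lm.fit(stats::model.matrix(~ xv * sexF[ok]), yv)
      beta[v] <- fit$coefficients["xv"]
      intercept[v] <- fit$coefficients["(Intercept)"]
      residSd[v] <- sqrt(sum(fit$residuals^2) / fit$df.residual)
    } else {
      mx <- mean(xv); my <- mean(yv)
      vx <- sum((xv - mx)^2)
      if (vx < 1e-12) next
      b <- sum((xv - mx) * (yv - my)) / vx
      beta[v] <- b
      intercept[v] <- my - b * mx
      r <- yv - intercept[v] - b * xv
      residSd[v] <- if (n > 2) sqrt(sum(r^2) / (n - 2)) else NA_real_
    }
  }
  full <- matrix(FALSE, nrow(cohort@area), ncol(cohort@area),
                 dimnames = list(NULL, cohort@subjects$scanId))
  full[, keepScan] <- excl
  methods::new("ScalingResult", beta = beta, intercept = intercept,
               residSd = residSd, nUsed = nUsed,
               parcelMeans = numeric(0), parcelN = integer(0),
               excluded = full, droppedScans = as.character(droppedScans))
}

#' Aggregate vertex scaling to parcels
#'
#' Unweighted mean of defined vertex betas within each parcel, medial
#' wall excluded; parcels without defined vertices are reported missing.
#'
#' @param result a [ScalingResult-class].
#' @param cohort the [SurfaceCohort-class] carrying parcel labels.
#' @return The result with `parcelMeans` and `parcelN` filled.
#' @export
parcellateScaling <- function(result, cohort) {
  ok <- !cohort@medialWall & is.finite(result@beta)
  parcels <- sort(unique(cohort@parcel[!cohort@medialWall]))
  means <- stats::setNames(rep(NA_real_, length(parcels)), parcels)
  ns <- stats::setNames(integer(length(parcels)), parcels)
  for (p in parcels) {
    sel <- ok & cohort@parcel == p
    ns[p] <- sum(sel)
    if (ns[p] > 0) means[p] <- mean(result@beta[sel])
  }
  result@parcelMeans <- means
  result@parcelN <- ns
  result
}

#' End-to-end scaling analysis of a cohort
#'
#' Curvature correction and smoothing, outlier screening, vertexwise
#' log-log fit and parcel aggregation in one call.
#'
#' @param cohort a [SurfaceCohort-class].
#' @param cfg a [scalingConfig()].
#' @param smooth apply curvature correction / smoothing first.
#' @return A [ScalingResult-class] with parcel means.
#' @export
scalingAnalysis <- function(cohort, cfg = scalingConfig(), smooth = TRUE) {
  work <- if (smooth) correctVertexArea(cohort, cfg$fwhmMm) else cohort
  om <- windowOutlierMask(work, cfg)
  res <- fitVertexScaling(work, cfg, exclusions = om$excluded,
                          droppedScans = om$droppedScans)
  parcellateScaling(res, cohort)
}
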