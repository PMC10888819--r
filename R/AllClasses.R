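# Central data containers.

#' Labelled histological section
#'
#' An RGB Nissl-contrast raster paired with an integer anatomical label
#' map on the same pixel grid. Images are stored as H x W x 3 double
#' arrays with channel values in [0, 1]; 8-bit semantics apply only at
#' the file boundary. Label 0 denotes background (mounting medium).
#'
#' @slot image H x W x 3 numeric array in [0, 1].
#' @slot labels integer matrix, same H x W, values in the label vocabulary.
#' @slot sectionIndex integer position along the cutting axis.
#' @slot spacingUm in-plane pixel size in micrometres.
#' @export
setClass("LabeledSection",
  representation(image = "array", labels = "matrix",
                 sectionIndex = "integer", spacingUm = "numeric"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
    if (!all(dim(object@labels) == d[1:2]))
      return("labels must share the image's spatial shape")
    if (min(object@image) < -1e-9 || max(object@image) > 1 + 1e-9)
      return("image channels must lie in [0, 1]")
    if (length(object@spacingUm) != 1L || object@spacingUm <= 0)
      return("spacingUm must be a positive scalar")
    if (any(object@labels < 0)) return("labels must be non-negative integers")
    TRUE
  })

#' @describeIn LabeledSection-class constructor.
#' @param image,labels,sectionIndex,spacingUm see slots.
#' @export
labeledSection <- function(image, labels, sectionIndex = 1L, spacingUm = 20) {
  storage.mode(labels) <- "integer"
  methods::new("LabeledSection", image = image, labels = labels,
               sectionIndex = as.integer(sectionIndex), spacingUm = spacingUm)
}

setMethod("show", "LabeledSection", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledSection %d: %d x %d px at %.1f um, %d labels\n",
              object@sectionIndex, d[1], d[2], object@spacingUm,
              length(setdiff(unique(as.integer(object@labels)), 0L))))
})

#' Ordered stack of labelled sections
#'
#' @slot sections list of [LabeledSection-class], strictly increasing
#'   `sectionIndex`.
#' @slot sliceSpacingUm physical distance between consecutive sections.
#' @slot transforms list of per-section composed [RigidTransform2D-class]
#'   (empty until alignment).
#' @export
setClass("SectionStack",
  representation(sections = "list", sliceSpacingUm = "numeric",
                 transforms = "list"),
  prototype(transforms = list()),
  validity = function(object) {
    if (!length(object@sections)) return("stack must contain sections")
    if (!all(vapply(object@sections, methods::is, TRUE, "LabeledSection")))
      return("sections must be LabeledSection objects")
    idx <- vapply(object@sections, function(s) s@sectionIndex, 1L)
    if (any(diff(idx) <= 0)) return("section order must be strictly increasing")
    if (length(object@transforms) &&
        length(object@transforms) != length(object@sections))
      return("one transform per section, or none")
    TRUE
  })

#' @describeIn SectionStack-class constructor.
#' @param sections,sliceSpacingUm,transforms see slots.
#' @export
sectionStack <- function(sections, sliceSpacingUm = 500, transforms = list()) {
  methods::new("SectionStack", sections = sections,
               sliceSpacingUm = sliceSpacingUm, transforms = transforms)
}

setMethod("show", "SectionStack", function(object) {
  d <- dim(object@sections[[1]]@image)
  cat(sprintf("SectionStack: %d sections of %d x %d px, slice spacing %.0f um%s\n",
              length(object@sections), d[1], d[2], object@sliceSpacingUm,
              if (length(object@transforms)) " (aligned)" else ""))
})

#' @describeIn SectionStack-class number of sections.
#' @param x a `SectionStack`.
#' @export
setMethod("length", "SectionStack", function(x) length(x@sections))

#' Per-label appearance model
#'
#' A parametric synthesizer of Nissl-contrast appearance conditioned on
#' anatomical labels: per-label mean RGB, RGB covariance and the count of
#' pixels used for fitting, plus global fallback statistics for labels
#' that were too sparse to fit.
#'
#' @slot means L x 3 matrix of per-label mean RGB, rownames = label.
#' @slot covs named list of 3 x 3 covariance matrices.
#' @slot pixelCounts named integer vector of pixels used per label.
#' @slot global fallback statistics (list with `mean`, `cov`).
#' @slot errors character vector naming labels that fell back to global
#'   statistics.
#' @export
setClass("AppearanceModel",
  representation(means = "matrix", covs = "list", pixelCounts = "integer",
                 global = "list", errors = "character"),
  validity = function(object) {
    if (ncol(object@means) != 3L) return("means must have 3 columns")
    if (!identical(rownames(object@means), names(object@covs)))
      return("means and covs must name the same labels")
    ok <- vapply(object@covs, function(S) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      all(ev > -1e-8)
    }, TRUE)
    if (!all(ok)) return("covariances must be positive semi-definite")
    TRUE
  })

setMethod("show", "AppearanceModel", function(object) {
  cat(sprintf("AppearanceModel: %d labels (%s fallback)\n",
              nrow(object@means),
              if (length(object@errors)) paste(object@errors, collapse = ", ")
              else "no"))
})

#' Expression tensor over gene x specimen x region x zone
#'
#' Normalised expression values (arbitrary units) on a dense 4-way grid,
#' with missing cells encoded as `NA`. Specimen ages (postconceptional
#' weeks) determine the early (<= 16 PCW) vs mid (21 PCW) timepoint.
#'
#' @slot values 4D array gene x specimen x region x zone, NA = missing.
#' @slot specimenAge named numeric vector of ages (PCW) per specimen.
#' @export
setClass("ExpressionTensor",
  representation(values = "array", specimenAge = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be a 4D array")
    dn <- dimnames(object@values)
    if (is.null(dn) || any(vapply(dn, is.null, TRUE)))
      return("all four axes must be named (gene, specimen, region, zone)")
    if (!identical(sort(names(object@specimenAge)), sort(dn[[2]])))
      return("specimenAge must name every specimen")
    TRUE
  })

#' @describeIn ExpressionTensor-class constructor.
#' @param values,specimenAge see slots.
#' @export
expressionTensor <- function(values, specimenAge) {
  methods::new("ExpressionTensor", values = values, specimenAge = specimenAge)
}

setMethod("show", "ExpressionTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ExpressionTensor: %d genes x %d specimens x %d regions x %d zones (%.1f%% missing)\n",
    d[1], d[2], d[3], d[4], 100 * mean(is.na(object@values))))
})

#' @describeIn ExpressionTensor-class gene identifiers.
#' @param x an `ExpressionTensor`.
#' @export
genes <- function(x) dimnames(x@values)[[1]]

#' @describeIn ExpressionTensor-class specimen identifiers.
#' @export
specimens <- function(x) dimnames(x@values)[[2]]

#' @describeIn ExpressionTensor-class region vocabulary.
#' @export
regions <- function(x) dimnames(x@values)[[3]]

#' @describeIn ExpressionTensor-class tissue-zone vocabulary.
#' @export
zones <- function(x) dimnames(x@values)[[4]]

#' @describeIn ExpressionTensor-class specimen timepoints, derived from
#'   age: early (<= 16 PCW) or mid.
#' @export
timepoints <- function(x) {
  age <- x@specimenAge[specimens(x)]
  ifelse(age <= 16, "early", "mid")
}

#' Surface cohort on a shared mesh topology
#'
#' Per-subject vertex metrics (surface area, curvature) on a common
#' triangulated mesh, with a medial-wall exclusion mask, parcel labels
#' and subject-level covariates.
#'
#' @slot vertices V x 3 coordinates (mm).
#' @slot faces F x 3 integer triangle index matrix (1-based).
#' @slot area V x S matrix of vertex areas (mm^2), scans in columns.
#' @slot curvature V x S matrix of vertex curvature (1/mm).
#' @slot medialWall logical V; `TRUE` vertices are excluded from all
#'   statistics.
#' @slot parcel character V of parcel labels.
#' @slot subjects data.frame with columns scanId, subjectId, ageWeeks, sex.
#' @export
setClass("SurfaceCohort",
  representation(vertices = "matrix", faces = "matrix", area = "matrix",
                 curvature = "matrix", medialWall = "logical",
                 parcel = "character", subjects = "data.frame"),
  validity = function(object) {
    V <- nrow(object@vertices)
    if (nrow(object@area) != V || nrow(object@curvature) != V)
      return("area/curvature must have one row per vertex")
    if (ncol(object@area) != nrow(object@subjects))
      return("one area column per scan")
    if (length(object@medialWall) != V || length(object@parcel) != V)
      return("medialWall and parcel must have one entry per vertex")
    if (any(object@area < 0, na.rm = TRUE)) return("areas must be >= 0")
    if (!all(c("scanId", "subjectId", "ageWeeks", "sex") %in%
             colnames(object@subjects)))
      return("subjects needs scanId, subjectId, ageWeeks, sex")
    TRUE
  })

setMethod("show", "SurfaceCohort", function(object) {
  cat(sprintf(
    "SurfaceCohort: %d scans, %d vertices (%d medial wall), ages %.1f-%.1f weeks\n",
    nrow(object@subjects), nrow(object@vertices), sum(object@medialWall),
    min(object@subjects$ageWeeks), max(object@subjects$ageWeeks)))
})

#' @describeIn SurfaceCohort-class total surface area per scan (mm^2),
#'   summed over non-medial-wall vertices.
#' @param x a `SurfaceCohort`.
#' @export
totalArea <- function(x) colSums(x@area[!x@medialWall, , drop = FALSE])

#' Vertexwise allometric scaling result
#'
#' @slot beta,intercept,residSd numeric V: per-vertex slope, intercept
#'   and residual standard deviation of the log-log area model.
#' @slot nUsed integer V: scans used per vertex.
#' @slot parcelMeans named numeric: mean beta per parcel.
#' @slot parcelN named integer: defined vertices per parcel.
#' @slot excluded logical V x S matrix of excluded (vertex, scan) pairs.
#' @slot droppedScans character: scans dropped entirely.
#' @export
setClass("ScalingResult",
  representation(beta = "numeric", intercept = "numeric", residSd = "numeric",
                 nUsed = "integer", parcelMeans = "numeric",
                 parcelN = "integer", excluded = "matrix",
                 droppedScans = "character"))

setMethod("show", "ScalingResult", function(object) {
  b <- object@beta[is.finite(object@beta)]
  cat(sprintf(
    "ScalingResult: beta defined at %d vertices (range %.3f-%.3f), %d parcels, %d scans dropped\n",
    length(b), min(b), max(b), length(object@parcelMeans),
    length(object@droppedScans)))
})

# ---- synthetic-data ground-truth containers ----

#' Histology simulation ground truth
#'
#' @slot clean artifact-free, aligned [SectionStack-class].
#' @slot corrupted the same stack with injected artifacts and rigid
#'   misalignments.
#' @slot artifactMasks list of logical matrices marking injected artifact
#'   pixels, in the corrupted (misaligned) frame.
#' @slot trueTransforms list of [RigidTransform2D-class] applied during
#'   corruption (the middle section keeps the identity).
#' @slot injectionLog data.frame of injected artifacts (section, type,
#'   nPixels).
#' @export
setClass("HistologySimTruth",
  representation(clean = "SectionStack", corrupted = "SectionStack",
                 artifactMasks = "list", trueTransforms = "list",
                 injectionLog = "data.frame"))

setMethod("show", "HistologySimTruth", function(object) {
  cat(sprintf("HistologySimTruth: %d sections, %d injected artifacts (%d px)\n",
              length(object@clean), nrow(object@injectionLog),
              sum(object@injectionLog$nPixels)))
})

#' Expression simulation ground truth
#'
#' @slot tensor an [ExpressionTensor-class] with planted effects.
#' @slot flags data.frame (gene, zoneEffect, regionEffect, timeEffect,
#'   monotoneRegion); genes with all three effect flags form the planted
#'   ZRT set.
#' @slot effectSize planted effect magnitude (full range of level shifts).
#' @slot noiseSd residual standard deviation.
#' @export
setClass("ExpressionSimTruth",
  representation(tensor = "ExpressionTensor", flags = "data.frame",
                 effectSize = "numeric", noiseSd = "numeric"))

setMethod("show", "ExpressionSimTruth", function(object) {
  z <- object@flags
  cat(sprintf(
    "ExpressionSimTruth: %d genes (Z %d, R %d, T %d, ZRT %d), noise sd %.3f\n",
    nrow(z), sum(z$zoneEffect), sum(z$regionEffect), sum(z$timeEffect),
    sum(z$zoneEffect & z$regionEffect & z$timeEffect), object@noiseSd))
})

#' Surface cohort simulation ground truth
#'
#' @slot cohort a [SurfaceCohort-class].
#' @slot betaField numeric V of true per-vertex scaling coefficients.
#' @slot totalAreaCurve data.frame (scanId, ageWeeks, targetLog10A,
#'   realizedTotal).
#' @slot outlierInjections data.frame (scanId, vertex, factor) of planted
#'   aberrant areas.
#' @slot config list of generator parameters.
#' @export
setClass("SurfaceSimTruth",
  representation(cohort = "SurfaceCohort", betaField = "numeric",
                 totalAreaCurve = "data.frame",
                 outlierInjections = "data.frame", config = "list"))

setMethod("show", "SurfaceSimTruth", function(object) {
  cat(sprintf(
    "SurfaceSimTruth: %d scans, beta field in [%.2f, %.2f], %d planted outliers\n",
    nrow(object@cohort@subjects), min(object@betaField), max(object@betaField),
    nrow(object@outlierInjections)))
})
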