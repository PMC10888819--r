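# Rigid slice-to-slice alignment via graph shortest paths, shape-prior
# constrained affine refinement, ISH projection and volume export.

#' Alignment graph over a section stack
#'
#' Nodes are section positions; directed edges run from each section
#' toward sections nearer the reference (within a neighbourhood radius),
#' weighted by the rigid registration cost `1 - NCC`.
#'
#' @slot nodes integer section positions (1-based within the stack).
#' @slot edges data.frame (from, to, cost).
#' @slot transforms named list of [RigidTransform2D-class], keyed
#'   `"from->to"`.
#' @slot reference integer reference position.
#' @export
setClass("AlignmentGraph",
  representation(nodes = "integer", edges = "data.frame",
                 transforms = "list", reference = "integer"),
  validity = function(object) {
    if (nrow(object@edges) && any(object@edges$cost < 0))
      return("edge costs must be >= 0")
    if (!(object@reference %in% object@nodes))
      return("reference must be one of the nodes")
    TRUE
  })

setMethod("show", "AlignmentGraph", function(object) {
  cat(sprintf("AlignmentGraph: %d sections, %d edges, reference %d\n",
              length(object@nodes), nrow(object@edges), object@reference))
})

# integer block-mean downsampling by factor f
.downsample <- function(m, f) {
  if (f <= 1) return(m)
  H <- nrow(m) %/% f * f; W <- ncol(m) %/% f * f
  m <- m[1:H, 1:W]
  a <- array(m, c(f, H / f, f, W / f))
  apply(a, c(2, 4), mean)
}

# NCC between fixed and moving translated by integer (dx, dy), over the
# fixed-frame mask restricted to the overlap window.
.shiftNcc <- function(fixed, moving, dx, dy, mask) {
  H <- nrow(fixed); W <- ncol(fixed)
  r0 <- max(1, 1 + dy); r1 <- min(H, H + dy)
  c0 <- max(1, 1 + dx); c1 <- min(W, W + dx)
  if (r1 - r0 < 4 || c1 - c0 < 4) return(-1)
  fv <- fixed[r0:r1, c0:c1]
  mv <- moving[(r0:r1) - dy, (c0:c1) - dx]
  ncc(fv, mv, mask[r0:r1, c0:c1])
}

#' Rigid 2D registration by coarse-to-fine NCC search
#'
#' Estimates the rigid transform that, applied to `moving`, aligns it to
#' `fixed`, by maximising normalised cross-correlation over the fixed
#' image's tissue mask. A coarse exhaustive search over rotation
#' (within +/- `maxRotationDeg`) and translation (within +/-
#' `maxTranslationFrac` of the width) on block-averaged images seeds a
#' full-resolution greedy refinement with step halving down to
#' `rotationStepFinal` degrees and 1 pixel.
#'
#' @param moving,fixed images (matrices or RGB arrays; converted to
#'   grayscale internally) of equal shape.
#' @param maxRotationDeg rotation search bound (degrees).
#' @param rotationStepFinal final rotation step (degrees).
#' @param maxTranslationFrac translation search bound as a fraction of
#'   image width.
#' @param coarseFactor block-averaging factor of the coarse level.
#' @return List with `transform` ([RigidTransform2D-class]) and `cost`
#'   (`1 - NCC`, in [0, 2]).
#' @export
registerRigid2d <- function(moving, fixed, maxRotationDeg = 15,
                            rotationStepFinal = 0.25,
                            maxTranslationFrac = 0.1, coarseFactor = 4) {
  gm <- toGray(moving); gf <- toGray(fixed)
  stopIfNot(all(dim(gm) == dim(gf)), "images must share shape")
  maskF <- tissueMask(gf)
  if (!any(maskF)) stop("empty tissue mask in fixed image")
  H <- nrow(gf); W <- ncol(gf)
  cen <- imageCenter(gf)
  bg <- borderBackground(gm)
  f <- max(1L, as.integer(coarseFactor))
  gmC <- .downsample(gm, f); gfC <- .downsample(gf, f)
  maskC <- .downsample(maskF * 1, f) > 0.25
  tMaxC <- max(1L, ceiling(maxTranslationFrac * W / f))
  cenC <- imageCenter(gfC)
  best <- list(cost = Inf, rot = 0, dx = 0, dy = 0)
  for (rot in seq(-maxRotationDeg, maxRotationDeg, by = 1)) {
    rotated <- resampleRigid(gmC, rigidTransform(rot, 0, 0, cenC),
                             "bilinear", background = bg)
    for (dy in -tMaxC:tMaxC) for (dx in -tMaxC:tMaxC) {
      v <- 1 - .shiftNcc(gfC, rotated, dx, dy, maskC)
      if (v < best$cost) best <- list(cost = v, rot = rot, dx = dx, dy = dy)
    }
  }
  # full-resolution greedy refinement with step halving
  cur <- c(best$rot, best$dx * f, best$dy * f)
  evalCost <- function(p) {
    tf <- rigidTransform(p[1], p[2], p[3], cen)
    1 - ncc(gf, resampleRigid(gm, tf, "bilinear", background = bg), maskF)
  }
  curCost <- evalCost(cur)
  rotStep <- 1; tStep <- max(1, f / 2)
  repeat {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (mv in list(c(rotStep, 0, 0), c(-rotStep, 0, 0),
                      c(0, tStep, 0), c(0, -tStep, 0),
                      c(0, 0, tStep), c(0, 0, -tStep))) {
        cand <- cur + mv
        if (abs(cand[1]) > maxRotationDeg + 1 ||
            max(abs(cand[2:3])) > maxTranslationFrac * W + f) next
        cc <- evalCost(cand)
        if (cc < curCost - 1e-9) {
          cur <- cand; curCost <- cc; improved <- TRUE
        }
      }
    }
    if (rotStep <= rotationStepFinal && tStep <= 1) break
    rotStep <- max(rotationStepFinal, rotStep / 2)
    tStep <- max(1, tStep / 2)
  }
  list(transform = rigidTransform(cur[1], cur[2], cur[3], cen),
       cost = max(0, curCost))
}

#' Build the alignment graph of a section stack
#'
#' Registers each section to its neighbours within radius `k` in the
#' direction of the reference section and records the resulting
#' transforms and costs as directed edges.
#'
#' @param stack a [SectionStack-class].
#' @param k neighbourhood radius (>= 1).
#' @param reference `"middle"` or a 1-based section position.
#' @param ... passed to [registerRigid2d()].
#' @return An [AlignmentGraph-class].
#' @export
buildAlignmentGraph <- function(stack, k = 2, reference = "middle", ...) {
  stopIfNot(k >= 1, "k must be >= 1")
  n <- length(stack)
  ref <- if (identical(reference, "middle")) (n + 1L) %/% 2L
    else as.integer(reference)
  stopIfNot(ref >= 1 && ref <= n, "reference outside the stack")
  edges <- list(); transforms <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || abs(i - j) > k) next
      if (abs(j - ref) >= abs(i - ref)) next  # only toward the reference
      reg <- registerRigid2d(stack@sections[[i]]@image,
                             stack@sections[[j]]@image, ...)
      edges[[length(edges) + 1]] <- data.frame(from = i, to = j,
                                               cost = reg$cost)
      transforms[[sprintf("%d->%d", i, j)]] <- reg$transform
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer(), cost = numeric())
  g <- methods::new("AlignmentGraph", nodes = seq_len(n), edges = edges,
                    transforms = transforms, reference = ref)
  unreachable <- .unreachableNodes(g)
  if (length(unreachable))
    stop("sections unreachable from the reference: ",
         paste(unreachable, collapse = ", "))
  g
}

.igraphOf <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(graph@edges$from),
               to = as.character(graph@edges$to),
               weight = graph@edges$cost),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph@nodes)))
}

.unreachableNodes <- function(graph) {
  g <- .igraphOf(graph)
  d <- igraph::distances(g, v = as.character(graph@nodes),
                         to = as.character(graph@reference),
                         mode = "out", weights = igraph::E(g)$weight)
  graph@nodes[!is.finite(d[, 1])]
}

#' Lowest-cost composed transform per section
#'
#' Runs Dijkstra's shortest-path algorithm from every section to the
#' reference on the alignment graph and composes the edge transforms
#' along each path; the reference receives the identity.
#'
#' @param graph an [AlignmentGraph-class].
#' @return Named list of [RigidTransform2D-class], one per section.
#' @export
shortestPathTransforms <- function(graph) {
  g <- .igraphOf(graph)
  n <- length(graph@nodes)
  out <- vector("list", n)
  cen <- if (length(graph@transforms)) graph@transforms[[1]]@center else c(0, 0)
  for (i in graph@nodes) {
    if (i == graph@reference) {
      out[[i]] <- rigidTransform(0, 0, 0, cen)
      next
    }
    sp <- igraph::shortest_paths(g, from = as.character(i),
                                 to = as.character(graph@reference),
                                 mode = "out",
                                 weights = igraph::E(g)$weight,
                                 output = "vpath")
    path <- as.integer(names(sp$vpath[[1]]))
    if (length(path) < 2) stop("no path from section ", i, " to the reference")
    tf <- NULL
    for (s in seq_len(length(path) - 1)) {
      e <- graph@transforms[[sprintf("%d->%d", path[s], path[s + 1])]]
      tf <- if (is.null(tf)) e else composeTransform(e, tf)
    }
    out[[i]] <- tf
  }
  names(out) <- as.character(graph@nodes)
  out
}

#' Apply per-section transforms to a stack
#'
#' Images are resampled with bilinear interpolation and labels with
#' nearest-neighbour interpolation (preserving the label vocabulary
#' exactly); out-of-frame pixels take the background (white image,
#' label 0).
#'
#' @param stack a [SectionStack-class].
#' @param transforms list of [RigidTransform2D-class], one per section.
#' @return The aligned [SectionStack-class] with transforms recorded.
#' @export
applyTransforms <- function(stack, transforms) {
  stopIfNot(length(transforms) == length(stack),
            "one transform per section required")
  sections <- vector("list", length(stack))
  for (i in seq_along(sections)) {
    s <- stack@sections[[i]]
    img <- resampleRigid(s@image, transforms[[i]], "bilinear", background = 1)
    lab <- resampleRigid(s@labels, transforms[[i]], "nearest", background = 0L)
    storage.mode(lab) <- "integer"
    sections[[i]] <- labeledSection(clamp(img), lab, s@sectionIndex,
                                    s@spacingUm)
  }
  sectionStack(sections, stack@sliceSpacingUm, transforms)
}

# Affine registration of `moving` onto `fixed`: rigid + scale seed, then
# Nelder-Mead refinement of the 6 affine parameters under 1 - NCC.
.registerAffinePair <- function(moving, fixed, maxRotationDeg = 10,
                                scales = seq(0.85, 1.18, by = 0.03),
                                maxit = 300) {
  gm <- toGray(moving); gf <- toGray(fixed)
  maskF <- tissueMask(gf)
  # mild blur suppresses uncorrelated per-pixel texture so the objective
  # is driven by shape and shading rather than interpolation residue
  gm <- .boxBlur(gm, 3); gf <- .boxBlur(gf, 3)
  if (!any(maskF)) stop("empty tissue mask in fixed image")
  bg <- borderBackground(gm)
  cen <- imageCenter(gf)
  obj <- function(par) {
    if (abs(par[1] * par[4] - par[2] * par[3]) < 0.1) return(2)
    1 - ncc(gf, resampleAffine(gm, par, cen, "bilinear", bg), maskF)
  }
  rig <- registerRigid2d(gm, gf, maxRotationDeg = maxRotationDeg,
                         coarseFactor = max(2, nrow(gf) %/% 32))
  R <- rotationMatrix(rig$transform@rotation)
  bestPar <- NULL; bestVal <- Inf
  for (s in scales) {
    par <- c(s * R[1, 1], s * R[1, 2], s * R[2, 1], s * R[2, 2],
             rig$transform@tx, rig$transform@ty)
    v <- obj(par)
    if (v < bestVal) { bestVal <- v; bestPar <- par }
  }
  opt <- stats::optim(bestPar, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(rep(0.05, 4), 2, 2)))
  list(par = opt$par, cost = opt$value, center = cen)
}

#' Shape-prior-constrained affine refinement of a stack
#'
#' Iteratively registers each section to the corresponding slice of a 3D
#' shape reference (6-parameter affine, NCC objective, gradient-free
#' refinement seeded by a rigid search), smoothing the six affine
#' parameters along the stack axis with a moving median (window 5) after
#' each iteration to suppress z-shift, and composing the smoothed
#' transforms with the accumulated state.
#'
#' @param stack a [SectionStack-class] (typically already rigidly
#'   aligned).
#' @param prior list of grayscale matrices (one per section) or an
#'   H x W x S array: the reference resampled at the stack's section
#'   positions.
#' @param iterations number of outer iterations.
#' @return List with `stack` (adjusted [SectionStack-class]), `affines`
#'   (per-section accumulated 6-parameter vectors) and `costs` (mean
#'   registration cost after each iteration).
#' @export
shapePriorAffine <- function(stack, prior, iterations = 5) {
  n <- length(stack)
  priorSlices <- if (is.list(prior)) prior else
    lapply(seq_len(dim(prior)[3]), function(i) prior[, , i])
  stopIfNot(length(priorSlices) == n,
            "prior must supply one slice per section")
  acc <- replicate(n, c(1, 0, 0, 1, 0, 0), simplify = FALSE)
  cen <- imageCenter(stack@sections[[1]]@image[, , 1])
  current <- lapply(stack@sections, function(s) toGray(s@image))
  costs <- numeric(0)
  for (it in seq_len(iterations)) {
    pars <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      reg <- .registerAffinePair(current[[i]], priorSlices[[i]])
      pars[i, ] <- reg$par
    }
    if (n >= 3) {
      kmed <- min(5, if (n %% 2 == 1) n else n - 1)
      for (p in 1:6) pars[, p] <- stats::runmed(pars[, p], kmed)
    }
    for (i in seq_len(n)) acc[[i]] <- composeAffinePar(pars[i, ], acc[[i]])
    itCost <- numeric(n)
    for (i in seq_len(n)) {
      g0 <- toGray(stack@sections[[i]]@image)
      current[[i]] <- resampleAffine(g0, acc[[i]], cen, "bilinear",
                                     borderBackground(g0))
      itCost[i] <- 1 - ncc(priorSlices[[i]], current[[i]],
                           tissueMask(priorSlices[[i]]))
    }
    costs <- c(costs, mean(itCost))
  }
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    s <- stack@sections[[i]]
    img <- resampleAffine(s@image, acc[[i]], cen, "bilinear", 1)
    lab <- resampleAffine(s@labels, acc[[i]], cen, "nearest", 0)
    storage.mode(lab) <- "integer"
    sections[[i]] <- labeledSection(clamp(img), lab, s@sectionIndex,
                                    s@spacingUm)
  }
  list(stack = sectionStack(sections, stack@sliceSpacingUm, stack@transforms),
       affines = acc, costs = costs)
}

#' Project ISH sections into the aligned stack geometry
#'
#' Extracts the red channel of each false-colour ISH section (higher
#' expression renders red), affine-registers it to its nearest
#' Nissl-stained section, applies that section's composed rigid
#' transform, and stacks the planes into a partial volume with missing
#' planes flagged (encoded `NA`; zero is a valid intensity).
#'
#' @param ishSections list of `list(index =, image =)` entries, where
#'   `index` names the nearest section position in the stack.
#' @param stack the (unaligned) [SectionStack-class] the ISH sections
#'   refer to.
#' @param transforms per-section composed transforms (defaults to the
#'   transforms recorded in `stack`).
#' @return List with `volume` (H x W x S array, NA where missing) and
#'   `present` (logical per plane).
#' @export
projectIsh <- function(ishSections, stack, transforms = stack@transforms) {
  n <- length(stack)
  stopIfNot(length(transforms) == n, "stack transforms required")
  d <- dim(stack@sections[[1]]@image)
  vol <- array(NA_real_, c(d[1], d[2], n))
  present <- rep(FALSE, n)
  for (item in ishSections) {
    idx <- item$index
    if (!is.numeric(idx) || idx < 1 || idx > n)
      stop("ISH section names index ", idx, " outside the stack")
    red <- if (length(dim(item$image)) == 3L) item$image[, , 1] else item$image
    nissl <- toGray(stack@sections[[idx]]@image)
    reg <- .registerAffinePair(red, nissl)
    aligned <- resampleAffine(red, reg$par, reg$center, "bilinear",
                              borderBackground(red))
    vol[, , idx] <- resampleRigid(aligned, transforms[[idx]], "bilinear",
                                  background = borderBackground(red))
    present[idx] <- TRUE
  }
  list(volume = vol, present = present)
}

#' Regional mean ISH intensity
#'
#' Mean non-missing ISH intensity per labelled structure, computed only
#' over planes where ISH data are present; structures with no present
#' voxels are reported as missing, not zero.
#'
#' @param ishVolume H x W x S array with `NA` missing planes.
#' @param labelVolume integer H x W x S array, co-registered.
#' @param present logical per plane (defaults to planes with any
#'   non-missing voxel).
#' @return data.frame (structure, meanIntensity, nSections).
#' @export
regionalIshMeans <- function(ishVolume, labelVolume,
                             present = apply(!is.na(ishVolume), 3, any)) {
  stopIfNot(identical(dim(ishVolume), dim(labelVolume)),
            "volumes must be co-registered with equal shape")
  labs <- sort(setdiff(unique(as.integer(labelVolume)), 0L))
  out <- data.frame(structure = labs, meanIntensity = NA_real_,
                    nSections = 0L)
  planeIdx <- which(present)
  for (r in seq_along(labs)) {
    l <- labs[r]
    vals <- numeric(0); nsec <- 0L
    for (p in planeIdx) {
      sel <- labelVolume[, , p] == l
      v <- ishVolume[, , p][sel]
      v <- v[!is.na(v)]
      if (length(v)) {
        vals <- c(vals, v)
        nsec <- nsec + 1L
      }
    }
    if (length(vals)) {
      out$meanIntensity[r] <- mean(vals)
      out$nSections[r] <- nsec
    }
  }
  out
}

# resample a matrix to new dimensions (bilinear or nearest)
.rescaleImage <- function(m, newH, newW, interp = "bilinear",
                          background = 0) {
  H <- nrow(m); W <- ncol(m)
  xs <- (rep(0:(newW - 1), each = newH) + 0.5) * W / newW - 0.5
  ys <- (rep(0:(newH - 1), times = newW) + 0.5) * H / newH - 0.5
  matrix(.sampleAt(m, xs, ys, interp, background), newH, newW)
}

#' Physical extent of a voxel axis
#'
#' @param nVoxels number of voxels along the axis.
#' @param voxelUm isotropic voxel size in micrometres.
#' @return Extent in millimetres.
#' @export
volumeExtentMm <- function(nVoxels, voxelUm = 150) nVoxels * voxelUm / 1000

#' Export an aligned stack as an isotropic NIfTI volume
#'
#' Resamples sections in-plane to the requested isotropic voxel size and
#' replicates each section across the voxel planes it spans along the
#' cutting axis. Intensity (grayscale) and label volumes are written with
#' the voxel size carried in the NIfTI header.
#'
#' @param stack an aligned [SectionStack-class].
#' @param voxelUm isotropic voxel size (micrometres).
#' @param fileImage,fileLabels optional output paths (`.nii.gz`).
#' @return List with `image`, `labels` (3D arrays), `dims`, `extentMm`.
#' @export
exportVolume <- function(stack, voxelUm = 150, fileImage = NULL,
                         fileLabels = NULL) {
  s1 <- stack@sections[[1]]
  H <- nrow(s1@labels); W <- ncol(s1@labels)
  scale <- s1@spacingUm / voxelUm
  newH <- max(1L, as.integer(round(H * scale)))
  newW <- max(1L, as.integer(round(W * scale)))
  n <- length(stack)
  nz <- max(1L, as.integer(round(n * stack@sliceSpacingUm / voxelUm)))
  img <- array(0, c(newH, newW, nz))
  lab <- array(0L, c(newH, newW, nz))
  for (z in seq_len(nz)) {
    src <- clamp(ceiling(z * n / nz), 1, n)
    g <- toGray(stack@sections[[src]]@image)
    img[, , z] <- .rescaleImage(g, newH, newW, "bilinear", 1)
    lab[, , z] <- .rescaleImage(stack@sections[[src]]@labels, newH, newW,
                                "nearest", 0)
  }
  mm <- voxelUm / 1000
  if (!is.null(fileImage)) {
    ni <- RNifti::asNifti(img)
    RNifti::pixdim(ni) <- c(mm, mm, mm)
    RNifti::writeNifti(ni, fileImage)
  }
  if (!is.null(fileLabels)) {
    ni <- RNifti::asNifti(lab + 0)
    RNifti::pixdim(ni) <- c(mm, mm, mm)
    RNifti::writeNifti(ni, fileLabels)
  }
  list(image = img, labels = lab, dims = c(newH, newW, nz),
       extentMm = volumeExtentMm(c(newH, newW, nz), voxelUm))
}
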