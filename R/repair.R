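# Artifact detection and repair of labelled histological sections.
#
# The repair pipeline compares a section against a synthetic prediction
# of its appearance conditioned on the anatomical labels, flags pixels
# whose hue/saturation deviate robustly from the prediction, and
# replaces flagged regions by gradient-domain (Poisson) blending of the
# synthetic image into the original.

#' Repair configuration
#'
#' @param theta robust outlier threshold (unitless); lowering `theta`
#'   can only grow the set of pixels marked as outliers.
#' @param blurKernel box-filter width/height in pixels (odd).
#' @param openingWidth width of the elliptical structuring element used
#'   to despeckle the outlier mask.
#' @param openingIterations erosion/dilation iterations of the opening.
#' @param patchSize,patchOverlap tiling geometry for patchwise synthesis.
#' @param satEps saturation below which hue is treated as undefined.
#' @param outlierRule `"robust_z"` flags `|d - median(d)| / MAD(d) >
#'   theta`; `"raw_gt_theta_mad"` flags `d > theta * MAD(d)`.
#' @param madFloor lower bound on the MAD to avoid division by zero on
#'   flat difference maps.
#' @return A validated list of class `RepairConfig`.
#' @export
repairConfig <- function(theta = 2.5, blurKernel = 5, openingWidth = 3,
                         openingIterations = 3, patchSize = 256,
                         patchOverlap = 8,
                         outlierRule = c("robust_z", "raw_gt_theta_mad"),
                         madFloor = 1e-6, satEps = 0.05) {
  outlierRule <- match.arg(outlierRule)
  stopIfNot(theta > 0, "theta must be > 0")
  stopIfNot(blurKernel >= 1 && blurKernel %% 2 == 1,
            "blurKernel must be odd and >= 1")
  stopIfNot(openingWidth >= 1 && openingWidth %% 2 == 1,
            "openingWidth must be odd and >= 1")
  stopIfNot(patchOverlap >= 0 && patchOverlap < patchSize,
            "patchOverlap must be smaller than patchSize")
  structure(list(theta = theta, blurKernel = blurKernel,
                 openingWidth = openingWidth,
                 openingIterations = openingIterations,
                 patchSize = patchSize, patchOverlap = patchOverlap,
                 outlierRule = outlierRule, madFloor = madFloor,
                 satEps = satEps),
            class = "RepairConfig")
}

#' Fit a per-label appearance model
#'
#' Computes per-label RGB mean and covariance from the non-excluded
#' pixels of a stack of labelled sections. Labels observed in fewer than
#' `minPixels` pixels fall back to global statistics and are reported in
#' the model's `errors` slot.
#'
#' @param stack a [SectionStack-class] or list of [LabeledSection-class].
#' @param exclusionMasks optional list of logical matrices; `TRUE` pixels
#'   are excluded from fitting.
#' @param minPixels minimum pixels required to fit a label.
#' @param maxPixelsPerLabel subsampling cap per label (for speed).
#' @param excludeBoundary drop pixels adjacent to a different label;
#'   their colours blend across the anatomical edge and would bias the
#'   per-label statistics.
#' @return An [AppearanceModel-class].
#' @export
fitLabelAppearance <- function(stack, exclusionMasks = NULL, minPixels = 100,
                               maxPixelsPerLabel = 50000,
                               excludeBoundary = TRUE) {
  sections <- if (methods::is(stack, "SectionStack")) stack@sections else stack
  acc <- list()  # per label: accumulated n x 3 pixel samples
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    H <- nrow(sec@labels); W <- ncol(sec@labels)
    keep <- if (is.null(exclusionMasks)) rep(TRUE, H * W) else
      !as.logical(exclusionMasks[[i]])
    if (excludeBoundary) {
      lm <- sec@labels
      interior <- matrix(TRUE, H, W)
      interior[-1, ] <- interior[-1, ] & lm[-1, ] == lm[-H, ]
      interior[-H, ] <- interior[-H, ] & lm[-H, ] == lm[-1, ]
      interior[, -1] <- interior[, -1] & lm[, -1] == lm[, -W]
      interior[, -W] <- interior[, -W] & lm[, -W] == lm[, -1]
      keep <- keep & as.logical(interior)
    }
    labs <- as.integer(sec@labels)
    for (l in setdiff(unique(labs), NA)) {
      px <- which(labs == l & keep)
      if (!length(px)) next
      rgb <- cbind(sec@image[px], sec@image[px + H * W],
                   sec@image[px + 2 * H * W])
      key <- as.character(l)
      acc[[key]] <- rbind(acc[[key]], rgb)
    }
  }
  allPix <- do.call(rbind, acc)
  global <- list(mean = colMeans(allPix), cov = stats::cov(allPix))
  labelsSeen <- sort(as.integer(names(acc)))
  means <- matrix(0, length(labelsSeen), 3,
                  dimnames = list(as.character(labelsSeen), c("r", "g", "b")))
  covs <- vector("list", length(labelsSeen))
  names(covs) <- as.character(labelsSeen)
  counts <- integer(length(labelsSeen))
  names(counts) <- as.character(labelsSeen)
  errors <- character()
  for (key in as.character(labelsSeen)) {
    px <- acc[[key]]
    counts[key] <- nrow(px)
    if (nrow(px) < minPixels) {
      errors <- c(errors, key)
      means[key, ] <- global$mean
      covs[[key]] <- global$cov
      next
    }
    if (nrow(px) > maxPixelsPerLabel)
      px <- px[seq(1, nrow(px), length.out = maxPixelsPerLabel), , drop = FALSE]
    means[key, ] <- colMeans(px)
    covs[[key]] <- stats::cov(px)
  }
  methods::new("AppearanceModel", means = means, covs = covs,
               pixelCounts = counts, global = global, errors = errors)
}

#' Synthesize a section from labels and an appearance model
#'
#' Draws each pixel's RGB from the fitted per-label Gaussian; with zero
#' covariance the output equals the per-label mean colours exactly.
#' Deterministic for a fixed seed.
#'
#' @param labels integer label raster.
#' @param model an [AppearanceModel-class].
#' @param seed integer seed.
#' @param fallback if `TRUE`, labels absent from the model use its global
#'   statistics; otherwise an unknown label is an error.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
synthesizeSection <- function(labels, model, seed = 1, fallback = TRUE) {
  H <- nrow(labels); W <- ncol(labels)
  out <- array(0, c(H, W, 3))
  withSeed(seed, {
    for (l in sort(unique(as.integer(labels)))) {
      key <- as.character(l)
      if (key %in% rownames(model@means)) {
        mu <- model@means[key, ]
        S <- model@covs[[key]]
      } else if (fallback) {
        mu <- model@global$mean
        S <- model@global$cov
      } else stop(sprintf("label %s not present in appearance model", key))
      px <- which(as.integer(labels) == l)
      if (max(abs(S)) < 1e-12) {
        draws <- matrix(mu, length(px), 3, byrow = TRUE)
      } else {
        Ch <- chol(S + diag(1e-10, 3))
        z <- matrix(stats::rnorm(3 * length(px)), length(px), 3)
        draws <- z %*% Ch + matrix(mu, length(px), 3, byrow = TRUE)
      }
      for (ch in 1:3) out[px + (ch - 1) * H * W] <- clamp(draws[, ch])
    }
  })
  out
}

# 1D feathering weight profile for a tile of length `len`: linear ramps
# of `ov` pixels at edges that abut a neighbouring tile.
.featherProfile <- function(len, ov, rampLo, rampHi) {
  w <- rep(1, len)
  if (ov > 0 && rampLo) w[seq_len(ov)] <- seq_len(ov) / (ov + 1)
  if (ov > 0 && rampHi) w[len + 1 - seq_len(ov)] <- seq_len(ov) / (ov + 1)
  w
}

#' Apply an operator patchwise and stitch with feathered blending
#'
#' Splits the image into `patchSize` tiles with `patchOverlap` pixels of
#' overlap, applies `fn` to each tile, and blends overlapping outputs by
#' linear feathering (normalised, so `fn = identity` reproduces the
#' input exactly, seams included). Images no larger than a patch are
#' processed as a single tile. `fn` may change the number of channels
#' (e.g. labels in, RGB out) but not the spatial shape.
#'
#' @param image matrix or H x W x C array.
#' @param cfg a [repairConfig()] list (uses `patchSize`, `patchOverlap`).
#' @param fn function taking and returning a tile.
#' @return Stitched image with the spatial shape of `image`.
#' @export
tileAndStitch <- function(image, cfg, fn) {
  ps <- cfg$patchSize; ov <- cfg$patchOverlap
  stopIfNot(ov < ps, "patchOverlap must be smaller than patchSize")
  d <- dim(image)
  H <- d[1]; W <- d[2]
  starts <- function(n) {
    if (n <= ps) return(1L)
    s <- seq(1L, n - ps + 1L, by = ps - ov)
    if (s[length(s)] != n - ps + 1L) s <- c(s, n - ps + 1L)
    s
  }
  rs <- starts(H); cs <- starts(W)
  getTile <- function(r0, c0, nr, nc) {
    if (length(d) == 2L) image[r0:(r0 + nr - 1), c0:(c0 + nc - 1), drop = FALSE]
    else image[r0:(r0 + nr - 1), c0:(c0 + nc - 1), , drop = FALSE]
  }
  outC <- NULL; accum <- NULL; wsum <- matrix(0, H, W)
  for (r0 in rs) for (c0 in cs) {
    nr <- min(ps, H - r0 + 1); nc <- min(ps, W - c0 + 1)
    tile <- getTile(r0, c0, nr, nc)
    res <- fn(tile)
    rd <- dim(res)
    stopIfNot(rd[1] == nr && rd[2] == nc,
              "patch operator must preserve the spatial shape")
    if (is.null(outC)) {
      outC <- if (length(rd) == 3L) rd[3] else 1L
      accum <- array(0, c(H, W, outC))
    }
    w <- outer(.featherProfile(nr, ov, r0 > 1, r0 + nr - 1 < H),
               .featherProfile(nc, ov, c0 > 1, c0 + nc - 1 < W))
    wsum[r0:(r0 + nr - 1), c0:(c0 + nc - 1)] <-
      wsum[r0:(r0 + nr - 1), c0:(c0 + nc - 1)] + w
    if (length(rd) == 2L) res <- array(res, c(nr, nc, 1))
    for (ch in seq_len(outC))
      accum[r0:(r0 + nr - 1), c0:(c0 + nc - 1), ch] <-
        accum[r0:(r0 + nr - 1), c0:(c0 + nc - 1), ch] + w * res[, , ch]
  }
  for (ch in seq_len(dim(accum)[3])) accum[, , ch] <- accum[, , ch] / wsum
  if (dim(accum)[3] == 1L) accum[, , 1] else accum
}

# robust outlier score of a difference vector: |d - median| / MAD
# (MAD floored), or d / MAD under the raw thresholding rule
.robustScore <- function(d, cfg) {
  madRaw <- stats::mad(d, constant = 1)
  if (madRaw == 0)
    warning("difference map has zero MAD; no outliers flagged")
  m <- max(madRaw, cfg$madFloor)
  if (cfg$outlierRule == "robust_z") abs(d - stats::median(d)) / m
  else d / m
}

# box blur with replicated borders
.boxBlur <- function(m, k) {
  if (k <= 1) return(m)
  EBImage::filter2(m, matrix(1 / (k * k), k, k), boundary = "replicate")
}

#' Detect artifact pixels by robust hue/saturation deviation
#'
#' Converts the original section and its synthetic prediction to HSV,
#' box-blurs both, and computes per-pixel absolute differences in hue
#' (circular distance in [0, 0.5]) and saturation. A pixel is flagged on
#' a channel when its robust score `|d - median(d)| / MAD(d)` exceeds
#' `theta` (MAD floored at `madFloor`); the final binary mask is the
#' intersection of the hue and saturation flags, despeckled by a
#' morphological opening (iterated erosion then dilation with an
#' elliptical element).
#'
#' @param original,synthetic H x W x 3 arrays in [0, 1].
#' @param cfg a [repairConfig()].
#' @return Logical artifact mask; the pre-opening mask is attached as
#'   attribute `"preOpening"`.
#' @export
detectArtifacts <- function(original, synthetic, cfg = repairConfig()) {
  stopIfNot(identical(dim(original), dim(synthetic)),
            "original and synthetic must share shape")
  toHsv <- function(img) {
    v <- grDevices::rgb2hsv(rbind(as.numeric(img[, , 1]),
                                  as.numeric(img[, , 2]),
                                  as.numeric(img[, , 3])) * 255,
                            maxColorValue = 255)
    H <- dim(img)[1]; W <- dim(img)[2]
    list(h = matrix(v[1, ], H, W), s = matrix(v[2, ], H, W))
  }
  ho <- toHsv(original); hs <- toHsv(synthetic)
  bh1 <- .boxBlur(ho$h, cfg$blurKernel); bh2 <- .boxBlur(hs$h, cfg$blurKernel)
  bs1 <- .boxBlur(ho$s, cfg$blurKernel); bs2 <- .boxBlur(hs$s, cfg$blurKernel)
  dh <- abs(bh1 - bh2); dh <- pmin(dh, 1 - dh)  # circular hue distance
  ds <- abs(bs1 - bs2)
  # hue is numerically undefined at near-zero saturation: pixels that are
  # unsaturated in both images carry no colour evidence and would dilute
  # the robust statistics (most of a section is mounting medium)
  evidence <- bs1 >= cfg$satEps | bs2 >= cfg$satEps
  flag <- function(d) {
    sc <- .robustScore(d[evidence], cfg)
    out <- matrix(FALSE, nrow(d), ncol(d))
    out[evidence] <- sc > cfg$theta
    out
  }
  pre <- flag(dh) & flag(ds)
  brush <- EBImage::makeBrush(cfg$openingWidth,
                              if (cfg$openingWidth >= 5) "disc" else "diamond")
  m <- pre * 1
  for (i in seq_len(cfg$openingIterations)) m <- EBImage::erode(m, brush)
  for (i in seq_len(cfg$openingIterations)) m <- EBImage::dilate(m, brush)
  out <- matrix(as.logical(m > 0.5), nrow(m), ncol(m))
  attr(out, "preOpening") <- pre
  out
}

# Solve the discrete Poisson equation on one connected component of the
# mask for one channel: Laplacian(out) = Laplacian(synthetic) inside,
# Dirichlet boundary values from `original` outside.
.poissonSolveComponent <- function(orig, synth, idx, H, W) {
  n <- length(idx)
  pos <- integer(H * W); pos[idx] <- seq_len(n)
  row <- (idx - 1) %% H + 1
  col <- (idx - 1) %/% H + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(n)
  neighOffsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  diagCount <- numeric(n)
  for (off in neighOffsets) {
    nr <- row + off[1]; nc <- col + off[2]
    wInb <- which(nr >= 1 & nr <= H & nc >= 1 & nc <= W)
    nidx <- (nc - 1) * H + nr
    # guidance gradient toward every in-bounds neighbour
    b[wInb] <- b[wInb] + (synth[idx[wInb]] - synth[nidx[wInb]])
    diagCount[wInb] <- diagCount[wInb] + 1
    neighPos <- pos[nidx[wInb]]
    inMask <- wInb[neighPos > 0]
    ii <- c(ii, inMask); jj <- c(jj, neighPos[neighPos > 0])
    xx <- c(xx, rep(-1, length(inMask)))
    onBoundary <- wInb[neighPos == 0]
    b[onBoundary] <- b[onBoundary] + orig[nidx[onBoundary]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(diagCount, xx), dims = c(n, n))
  as.numeric(Matrix::solve(A, b))
}

#' Poisson image editing repair
#'
#' Replaces the masked pixels of `original` by solving, per channel and
#' per mask connected component, the discrete Poisson equation with the
#' synthetic image's Laplacian as guidance and Dirichlet boundary values
#' from the original; outside the mask the original is returned
#' unchanged. A one-pixel image border is cleared from the mask. If a
#' component's linear system fails to solve, its pixels fall back to
#' direct replacement with a warning.
#'
#' @param original,synthetic matrices or H x W x 3 arrays in [0, 1].
#' @param mask logical matrix.
#' @return Repaired image, clipped to [0, 1].
#' @export
poissonRepair <- function(original, synthetic, mask) {
  d <- dim(original)
  H <- d[1]; W <- d[2]
  stopIfNot(identical(dim(synthetic), d), "images must share shape")
  stopIfNot(all(dim(mask) == c(H, W)), "mask must match the image shape")
  mask <- as.logical(mask); dim(mask) <- c(H, W)
  mask[1, ] <- FALSE; mask[H, ] <- FALSE
  mask[, 1] <- FALSE; mask[, W] <- FALSE
  if (!any(mask)) return(original)
  comp <- EBImage::bwlabel(mask * 1)
  out <- original
  nComp <- max(comp)
  channels <- if (length(d) == 3L) seq_len(d[3]) else 1L
  for (k in seq_len(nComp)) {
    idx <- which(comp == k)
    for (ch in channels) {
      orig <- if (length(d) == 3L) original[, , ch] else original
      syn <- if (length(d) == 3L) synthetic[, , ch] else synthetic
      sol <- tryCatch(.poissonSolveComponent(orig, syn, idx, H, W),
                      error = function(e) {
                        warning("Poisson system not solvable; falling back to direct replacement")
                        syn[idx]
                      })
      if (length(d) == 3L) out[idx + (ch - 1) * H * W] <- clamp(sol)
      else out[idx] <- clamp(sol)
    }
  }
  out
}

#' Detect and repair artifacts in a labelled section
#'
#' Synthesizes the section's expected appearance from its labels (tiled
#' through [tileAndStitch()] with per-tile seeds derived from `seed`),
#' detects artifact pixels with [detectArtifacts()], and repairs them
#' with [poissonRepair()]. Labels are returned unchanged; the artifact
#' mask is returned for audit.
#'
#' @param section a [LabeledSection-class].
#' @param model an [AppearanceModel-class].
#' @param cfg a [repairConfig()].
#' @param seed integer seed for the synthesizer.
#' @return List with `section` (repaired [LabeledSection-class]), `mask`
#'   (logical matrix) and `synthetic` (the synthesized prediction).
#' @export
repairSection <- function(section, model, cfg = repairConfig(), seed = 1) {
  tileNo <- 0L
  synth <- tileAndStitch(section@labels, cfg, function(tile) {
    tileNo <<- tileNo + 1L
    synthesizeSection(tile, model, seed = childSeed(seed, tileNo))
  })
  if (is.matrix(synth)) synth <- array(rep(synth, 3), c(dim(synth), 3))
  mask <- detectArtifacts(section@image, synth, cfg)
  repaired <- poissonRepair(section@image, synth, mask)
  list(section = labeledSection(repaired, section@labels,
                                section@sectionIndex, section@spacingUm),
       mask = mask, synthetic = synth)
}
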