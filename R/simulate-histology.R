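# Seeded generator for serial-section histology fixtures with known
# ground truth: a clean stack, a corrupted copy with injected artifacts
# (tears, folds, stain shifts) and known rigid misalignments, per-section
# artifact masks and the true per-section transforms.

# Deterministic Nissl-like palette: violet tissue tones darkening with
# label depth, background white.
.labelPalette <- function(nLabels) {
  t <- seq(0.15, 0.85, length.out = nLabels)
  cbind(r = 0.85 - 0.45 * t, g = 0.55 - 0.40 * t, b = 0.88 - 0.25 * t)
}

# Concentric, angularly deformed elliptical shells: label 1 is the
# outermost ring, nLabels the innermost core; 0 is background. Shell
# geometry drifts smoothly with the section's position along the axis so
# neighbouring sections resemble each other.
.syntheticLabelMap <- function(height, width, nLabels, sectionFrac, phase = 0) {
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), times = width), height, width)
  sz <- 0.8 + 0.12 * sin(pi * sectionFrac)         # waxing/waning profile
  a <- 0.42 * width * sz; b <- 0.38 * height * sz
  phi <- atan2(y - cy, x - cx)
  # pronounced angular signature so in-plane rotation is well determined
  rho <- 1 + 0.10 * sin(3 * phi + phase) + 0.06 * cos(5 * phi - 0.4) +
    0.04 * cos(2 * phi - phase)
  r <- sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2) / rho
  lab <- matrix(0L, height, width)
  inside <- r < 1
  lab[inside] <- as.integer(pmin(nLabels, floor(r[inside] * nLabels) + 1L))
  # invert so label 1 = outer shell ... nLabels = core
  lab[inside] <- nLabels + 1L - lab[inside]
  lab
}

# Render an image from a label map: per-label base colour, a smooth
# angular shading shared by all sections (mimicking consistent
# cytoarchitectonic variation, and making in-plane rotation observable
# from appearance), plus iid texture.
.renderSection <- function(labels, palette, textureSd = 0.03) {
  H <- nrow(labels); W <- ncol(labels)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), times = W), H, W)
  phi <- atan2(y - cy, x - cx)
  shade <- 1 + 0.12 * sin(4 * phi + 1) + 0.08 * cos(7 * phi)
  img <- array(1, c(H, W, 3))          # white background
  for (l in sort(setdiff(unique(as.integer(labels)), 0L))) {
    px <- which(labels == l)
    for (ch in 1:3)
      img[px + (ch - 1) * H * W] <-
        clamp(palette[l, ch] * shade[px] + stats::rnorm(length(px), 0, textureSd))
  }
  img
}

# Elliptical blob pixel set around (cy0, cx0), ~nPixels in size.
.blobPixels <- function(H, W, cy0, cx0, nPixels, elong = 2) {
  b <- sqrt(nPixels / (pi * elong)); a <- elong * b
  th <- stats::runif(1, 0, pi)
  x <- rep(0:(W - 1), each = H); y <- rep(0:(H - 1), times = W)
  dx <- x - cx0; dy <- y - cy0
  u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
  which((u / a)^2 + (v / b)^2 < 1)
}

.rotateHue <- function(rgbMat, dh) {
  hsv <- grDevices::rgb2hsv(t(rgbMat) * 255, maxColorValue = 255)
  hsv[1, ] <- (hsv[1, ] + dh) %% 1
  t(grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255)
}

#' Simulate a serial-section histology stack with known ground truth
#'
#' Generates an artifact-free stack of labelled sections over a smooth
#' synthetic anatomy (nested deformed elliptical shells, so every label
#' is spatially contiguous and changes smoothly along the cutting axis),
#' then corrupts a copy by injecting tears (pixels set to background),
#' folds (a duplicated, darkened patch) and stain shifts (hue rotation in
#' a disc), and finally misaligns each section by a random rigid
#' transform. The middle section keeps the identity transform so that it
#' can serve as the registration reference. Every injected artifact is
#' recorded in the injection log and in per-section binary masks drawn in
#' the corrupted frame.
#'
#' @param nSections number of sections (>= 3).
#' @param height,width section size in pixels.
#' @param nLabels number of tissue labels (<= 20).
#' @param tearsPerSection,foldsPerSection,stainsPerSection expected
#'   artifact counts per section; the fractional part is realised as a
#'   Bernoulli draw.
#' @param tearSizePx approximate pixel count of each tear.
#' @param maxRotationDeg,maxTranslationPx misalignment amplitudes
#'   (uniform in +/- the bound).
#' @param textureSd per-pixel texture noise standard deviation.
#' @param spacingUm,sliceSpacingUm in-plane and between-section spacing.
#' @param seed integer seed; outputs are byte-identical for a fixed seed.
#' @return A [HistologySimTruth-class] object.
#' @export
simulateHistologyStack <- function(nSections = 10, height = 128, width = 128,
                                   nLabels = 6, tearsPerSection = 1,
                                   foldsPerSection = 0.5,
                                   stainsPerSection = 0.5, tearSizePx = 400,
                                   maxRotationDeg = 5, maxTranslationPx = 6,
                                   textureSd = 0.03, spacingUm = 20,
                                   sliceSpacingUm = 500, seed = 1) {
  stopIfNot(nSections >= 3, "need at least 3 sections")
  stopIfNot(nLabels >= 1 && nLabels <= 20, "nLabels must be in 1..20")
  stopIfNot(height >= 16 && width >= 16, "sections must be at least 16 px")
  rates <- c(tearsPerSection, foldsPerSection, stainsPerSection)
  stopIfNot(all(rates >= 0), "artifact rates must be >= 0")
  stopIfNot(maxRotationDeg >= 0 && maxTranslationPx >= 0,
            "misalignment bounds must be >= 0")
  palette <- .labelPalette(nLabels)
  withSeed(seed, {
    cleanSections <- vector("list", nSections)
    for (s in seq_len(nSections)) {
      # fixed angular phase: a drifting phase would masquerade as a
      # rotation between neighbouring sections
      lab <- .syntheticLabelMap(height, width, nLabels,
                                sectionFrac = (s - 1) / (nSections - 1),
                                phase = 0.7)
      img <- .renderSection(lab, palette, textureSd)
      cleanSections[[s]] <- labeledSection(img, lab, s, spacingUm)
    }
    clean <- sectionStack(cleanSections, sliceSpacingUm)

    mid <- (nSections + 1) %/% 2
    trueTransforms <- vector("list", nSections)
    masks <- vector("list", nSections)
    corrupted <- vector("list", nSections)
    log <- list()
    nDraw <- function(rate) floor(rate) + (stats::runif(1) < rate - floor(rate))
    for (s in seq_len(nSections)) {
      img <- cleanSections[[s]]@image
      lab <- cleanSections[[s]]@labels
      cen <- imageCenter(lab)
      tf <- if (s == mid) rigidTransform(0, 0, 0, cen) else
        rigidTransform(stats::runif(1, -maxRotationDeg, maxRotationDeg),
                       round(stats::runif(1, -maxTranslationPx, maxTranslationPx)),
                       round(stats::runif(1, -maxTranslationPx, maxTranslationPx)),
                       cen)
      trueTransforms[[s]] <- tf
      # misalign first, then inject artifacts in the corrupted frame so
      # masks mark exactly the pixels that differ from the (misaligned)
      # clean geometry
      img <- resampleRigid(img, tf, "bilinear", background = 1)
      lab <- resampleRigid(lab, tf, "nearest", background = 0L)
      storage.mode(lab) <- "integer"
      mask <- matrix(FALSE, height, width)
      H <- height; W <- width
      tissue <- which(lab > 0)
      drawCentre <- function() {
        p <- tissue[sample.int(length(tissue), 1)]
        c(cy = (p - 1) %% H, cx = (p - 1) %/% H)
      }
      for (i in seq_len(nDraw(tearsPerSection))) {
        ce <- drawCentre()
        px <- intersect(.blobPixels(H, W, ce[1], ce[2], tearSizePx), tissue)
        for (ch in 1:3) img[px + (ch - 1) * H * W] <- 1
        mask[px] <- TRUE
        log[[length(log) + 1]] <- data.frame(section = s, type = "tear",
                                             nPixels = length(px))
      }
      for (i in seq_len(nDraw(foldsPerSection))) {
        ce <- drawCentre()
        side <- max(6L, round(sqrt(tearSizePx / 2)))
        r0 <- clamp(round(ce[1]) - side %/% 2, 0, H - side) + 1
        c0 <- clamp(round(ce[2]) - side %/% 2, 0, W - side) + 1
        sr0 <- clamp(r0 + side, 1, H - side + 1)  # duplicated source patch
        patch <- img[sr0:(sr0 + side - 1), c0:(c0 + side - 1), , drop = FALSE]
        img[r0:(r0 + side - 1), c0:(c0 + side - 1), ] <- patch * 0.55
        mask[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- TRUE
        log[[length(log) + 1]] <- data.frame(section = s, type = "fold",
                                             nPixels = side^2)
      }
      for (i in seq_len(nDraw(stainsPerSection))) {
        ce <- drawCentre()
        px <- intersect(.blobPixels(H, W, ce[1], ce[2], tearSizePx, elong = 1),
                        tissue)
        rgbPix <- cbind(img[px], img[px + H * W], img[px + 2 * H * W])
        shifted <- .rotateHue(rgbPix, 0.18)
        for (ch in 1:3) img[px + (ch - 1) * H * W] <- shifted[, ch]
        mask[px] <- TRUE
        log[[length(log) + 1]] <- data.frame(section = s, type = "stain",
                                             nPixels = length(px))
      }
      corrupted[[s]] <- labeledSection(clamp(img), lab, s, spacingUm)
      masks[[s]] <- mask
    }
    methods::new("HistologySimTruth",
                 clean = clean,
                 corrupted = sectionStack(corrupted, sliceSpacingUm),
                 artifactMasks = masks,
                 trueTransforms = trueTransforms,
                 injectionLog = if (length(log)) do.call(rbind, log) else
                   data.frame(section = integer(), type = character(),
                              nPixels = integer()))
  })
}
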