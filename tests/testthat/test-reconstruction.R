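test_that("rigid registration recovers known transforms", {
  img <- tearStack()@clean@sections[[2]]@image
  cen <- imageCenter(img[, , 1])
  reg0 <- registerRigid2d(img, img)
  expect_lt(reg0$cost, 1e-3)
  expect_identical(c(reg0$transform@rotation, reg0$transform@tx,
                     reg0$transform@ty), c(0, 0, 0))
  # pure rotation
  fixedR <- resampleRigid(img, rigidTransform(7, 0, 0, cen), "bilinear", 1)
  regR <- registerRigid2d(img, fixedR)
  expect_lt(abs(regR$transform@rotation - 7), 0.5)
  # pure translation
  fixedT <- resampleRigid(img, rigidTransform(0, 5, -3, cen), "bilinear", 1)
  regT <- registerRigid2d(img, fixedT)
  expect_lte(abs(regT$transform@tx - 5), 1)
  expect_lte(abs(regT$transform@ty + 3), 1)
  expect_lt(abs(regT$transform@rotation), 0.5)
  blank <- array(1, dim(img))
  expect_error(registerRigid2d(img, blank), "tissue mask")
})

test_that("alignment graph has edges only toward the reference", {
  s3 <- sectionStack(cleanStack()@clean@sections[1:3])
  g3 <- buildAlignmentGraph(s3, k = 1)
  expect_identical(nrow(g3@edges), 2L)
  expect_identical(g3@reference, 2L)
  s5 <- sectionStack(cleanStack()@clean@sections)
  g5 <- buildAlignmentGraph(s5, k = 2)
  got <- sort(sprintf("%d->%d", g5@edges$from, g5@edges$to))
  expect_identical(got, sort(c("1->2", "1->3", "2->3", "5->4", "5->3",
                               "4->3")))
  # identical geometry: near-zero costs everywhere
  expect_lt(max(g5@edges$cost), 0.25)
})

test_that("shortest-path composition picks the cheaper multi-hop route", {
  cen <- c(10, 10)
  tA <- rigidTransform(2, 1, 0, cen)   # 1 -> 2
  tB <- rigidTransform(3, 0, 1, cen)   # 2 -> 3
  tC <- rigidTransform(10, 5, 5, cen)  # 1 -> 3 (expensive direct edge)
  g <- new("AlignmentGraph", nodes = 1:3,
           edges = data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                              cost = c(0.1, 0.1, 0.5)),
           transforms = list("1->2" = tA, "2->3" = tB, "1->3" = tC),
           reference = 3L)
  tfs <- shortestPathTransforms(g)
  # reference gets the identity
  expect_identical(c(tfs[["3"]]@rotation, tfs[["3"]]@tx, tfs[["3"]]@ty),
                   c(0, 0, 0))
  # path 1 -> 2 -> 3 (cost 0.2) beats the direct edge (0.5)
  expected <- composeTransform(tB, tA)
  expect_equal(tfs[["1"]]@rotation, expected@rotation)
  expect_equal(c(tfs[["1"]]@tx, tfs[["1"]]@ty),
               c(expected@tx, expected@ty))
  expect_false(isTRUE(all.equal(tfs[["1"]]@rotation, tC@rotation)))
})

test_that("applying transforms preserves labels and is invertible", {
  stack <- sectionStack(cleanStack()@clean@sections[1:3])
  cen <- imageCenter(stack@sections[[1]]@labels)
  ids <- replicate(3, rigidTransform(0, 0, 0, cen))
  same <- applyTransforms(stack, ids)
  expect_equal(same@sections[[2]]@image, stack@sections[[2]]@image)
  # band-limit the texture first: round-trip interpolation loss is only
  # meaningful on images without white-noise detail
  smooth <- lapply(stack@sections, function(s) {
    img <- s@image
    for (ch in 1:3)
      img[, , ch] <- EBImage::filter2(img[, , ch], matrix(1 / 25, 5, 5),
                                      boundary = "replicate")
    labeledSection(pmin(pmax(img, 0), 1), s@labels, s@sectionIndex,
                   s@spacingUm)
  })
  stack <- sectionStack(smooth)
  tfs <- list(rigidTransform(5, 2, -1, cen), rigidTransform(-3, 0, 2, cen),
              rigidTransform(8, -2, 0, cen))
  fwd <- applyTransforms(stack, tfs)
  vocab <- c(0L, sort(unique(as.integer(stack@sections[[1]]@labels))))
  for (i in 1:3)
    expect_true(all(fwd@sections[[i]]@labels %in% vocab))
  back <- applyTransforms(fwd, lapply(tfs, invertTransform))
  tissue <- stack@sections[[1]]@labels > 0
  expect_lt(mean(abs(back@sections[[1]]@image -
                       stack@sections[[1]]@image)[rep(tissue, 3)]), 2 / 255)
})

test_that("graph alignment recovers injected misalignments on a small stack", {
  h <- simulateHistologyStack(nSections = 6, height = 96, width = 96,
                              nLabels = 5, tearsPerSection = 0,
                              foldsPerSection = 0, stainsPerSection = 0,
                              maxRotationDeg = 4, maxTranslationPx = 5,
                              seed = 13)
  g <- buildAlignmentGraph(h@corrupted, k = 2)
  tfs <- shortestPathTransforms(g)
  for (i in seq_along(tfs)) {
    resid <- composeTransform(tfs[[i]], h@trueTransforms[[i]])
    expect_lt(abs(resid@rotation), 1.5)
    expect_lt(max(abs(c(resid@tx, resid@ty))), 2.5)
  }
  # shortest-path cost never exceeds a direct edge where one exists
  ig <- fetalcortex:::.igraphOf(g)
  d <- igraph::distances(ig, mode = "out", weights = igraph::E(ig)$weight)
  for (r in seq_len(nrow(g@edges))) {
    e <- g@edges[r, ]
    expect_lte(d[as.character(e$from), as.character(e$to)], e$cost + 1e-12)
  }
  # per-label pixel counts conserved within tolerance under alignment
  aligned <- applyTransforms(h@corrupted, tfs)
  for (i in c(2, 5)) {
    before <- table(factor(h@corrupted@sections[[i]]@labels, levels = 0:5))
    after <- table(factor(aligned@sections[[i]]@labels, levels = 0:5))
    keep <- before > 200
    expect_lt(max(abs(after[keep] / before[keep] - 1)), 0.04)
  }
})

test_that("shape-prior affine refinement converges and recovers scale", {
  h <- cleanStack()
  prior <- lapply(h@clean@sections, function(s) fetalcortex:::toGray(s@image))
  sp <- shapePriorAffine(h@clean, prior, iterations = 2)
  drift <- max(vapply(sp$affines, function(a)
    max(abs(a - c(1, 0, 0, 1, 0, 0))), 1))
  expect_lt(drift, 0.01)  # prior equals the stack: transforms stay identity
  scaled <- lapply(h@clean@sections, function(s) {
    img <- resampleAffine(s@image, c(0.9, 0, 0, 0.9, 0, 0),
                          imageCenter(s@image[, , 1]), "bilinear", 1)
    labeledSection(pmin(pmax(img, 0), 1), s@labels, s@sectionIndex,
                   s@spacingUm)
  })
  sp2 <- shapePriorAffine(sectionStack(scaled), prior, iterations = 3)
  scales <- vapply(sp2$affines, function(a)
    sqrt(abs(a[1] * a[4] - a[2] * a[3])), 1)
  expect_lt(max(abs(scales - 1 / 0.9)), 0.02 / 0.9)
  # mean registration cost does not deteriorate across iterations
  expect_true(all(diff(sp2$costs) <= 0.01))
  expect_error(shapePriorAffine(h@clean, prior[1:2]), "one slice")
})

test_that("ISH projection registers into the aligned geometry", {
  h <- cleanStack()
  cen <- imageCenter(h@clean@sections[[1]]@labels)
  ids <- replicate(5, rigidTransform(0, 0, 0, cen))
  # already-aligned ISH equals the stored plane
  ish <- list(list(index = 2, image = h@clean@sections[[2]]@image))
  pr <- projectIsh(ish, h@clean, ids)
  expect_identical(which(pr$present), 2L)
  expect_gt(fetalcortex:::ncc(pr$volume[, , 2],
                              h@clean@sections[[2]]@image[, , 1]), 0.995)
  expect_true(all(is.na(pr$volume[, , c(1, 3, 4, 5)])))
  # no ISH at all: an all-missing volume
  pr0 <- projectIsh(list(), h@clean, ids)
  expect_true(all(!pr0$present))
  expect_true(all(is.na(pr0$volume)))
  # known-transform fixture: recovered plane matches the original
  warped <- resampleRigid(h@clean@sections[[3]]@image,
                          rigidTransform(6, 3, -2, cen), "bilinear", 1)
  pr2 <- projectIsh(list(list(index = 3, image = warped)), h@clean, ids)
  expect_gt(fetalcortex:::ncc(pr2$volume[, , 3],
                              h@clean@sections[[3]]@image[, , 1]), 0.95)
  expect_error(projectIsh(list(list(index = 9, image = warped)),
                          h@clean, ids), "outside")
})

test_that("regional ISH means average only present planes", {
  lab <- array(0L, c(6, 6, 3))
  lab[1:3, , ] <- 1L; lab[4:6, , ] <- 2L
  vol <- array(NA_real_, c(6, 6, 3))
  vol[, , 1] <- 0.5
  out <- regionalIshMeans(vol, lab)
  expect_equal(out$meanIntensity, c(0.5, 0.5))
  expect_equal(out$nSections, c(1L, 1L))
  vol[1:3, , 2] <- 10; vol[4:6, , 2] <- 20
  vol[, , 1] <- NA
  out2 <- regionalIshMeans(vol, lab)
  expect_equal(out2$meanIntensity, c(10, 20))
  # brute-force voxel loop oracle on a random fixture
  set.seed(2)
  vol3 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  vol3[, , 2] <- NA
  lab3 <- array(sample(0:2, 108, replace = TRUE), c(6, 6, 3))
  out3 <- regionalIshMeans(vol3, lab3)
  for (l in 1:2) {
    acc <- c()
    for (z in c(1, 3)) for (r in 1:6) for (cc in 1:6)
      if (lab3[r, cc, z] == l && !is.na(vol3[r, cc, z]))
        acc <- c(acc, vol3[r, cc, z])
    expect_equal(out3$meanIntensity[out3$structure == l], mean(acc))
  }
})

test_that("volume export has the geometry implied by spacing", {
  expect_equal(volumeExtentMm(189, 150), 28.35)
  h <- cleanStack()  # 64 px at 20 um, 5 sections at 500 um
  stack <- applyTransforms(h@clean, replicate(5, rigidTransform(
    0, 0, 0, imageCenter(h@clean@sections[[1]]@labels))))
  vol <- exportVolume(stack, voxelUm = 40)
  expect_identical(vol$dims, c(32L, 32L, 62L))
  expect_equal(vol$extentMm, c(32, 32, 62) * 40 / 1000)
  f1 <- tempfile(fileext = ".nii.gz")
  vol2 <- exportVolume(stack, voxelUm = 40, fileImage = f1)
  ni <- RNifti::readNifti(f1)
  expect_equal(unname(RNifti::pixdim(ni)), rep(0.04, 3), tolerance = 1e-6)
  expect_identical(dim(ni), vol2$dims)
  unlink(f1)
})
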