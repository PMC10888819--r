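# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# small clean/corrupted histology stack with tears only
tearStack <- function() cachedFixture("tearStack", function()
  simulateHistologyStack(nSections = 5, height = 128, width = 128,
                         nLabels = 5, tearsPerSection = 1,
                         foldsPerSection = 0, stainsPerSection = 0,
                         tearSizePx = 400, seed = 3))

# aligned stack without artifacts or misalignment
cleanStack <- function() cachedFixture("cleanStack", function()
  simulateHistologyStack(nSections = 5, height = 64, width = 64,
                         nLabels = 4, tearsPerSection = 0,
                         foldsPerSection = 0, stainsPerSection = 0,
                         maxRotationDeg = 0, maxTranslationPx = 0, seed = 2))

# expression dataset with strong planted effects
plantedExpression <- function() cachedFixture("plantedExpression", function()
  simulateExpressionDataset(nGenes = 2000,
                            effectFractions = c(zone = 0.3, region = 0.3,
                                                time = 0.3),
                            effectSize = 1, noiseSd = 0.5, seed = 6))

# moderate surface cohort
surfaceTruth <- function() cachedFixture("surfaceTruth", function()
  simulateSurfaceCohort(nSubjects = 40, subdivisions = 3, noiseSd = 0.02,
                        curvatureLeak = 0.05, seed = 4))

# brute-force tie-corrected Kendall tau over all pairs
bruteTauB <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# brute-force Benjamini-Hochberg (sort, scale, cumulative minimum)
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / (n:1)))
  out <- numeric(n)
  out[o] <- q
  out
}

# dense-solver oracle for the masked Poisson system (single channel)
densePoisson <- function(orig, synth, mask) {
  H <- nrow(orig); W <- ncol(orig)
  mask[1, ] <- FALSE; mask[H, ] <- FALSE; mask[, 1] <- FALSE
  mask[, W] <- FALSE
  idx <- which(mask)
  n <- length(idx)
  pos <- integer(H * W); pos[idx] <- seq_len(n)
  A <- matrix(0, n, n); b <- numeric(n)
  for (k in seq_len(n)) {
    i <- idx[k]; r <- (i - 1) %% H + 1; cc <- (i - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1 || rr > H || c2 < 1 || c2 > W) next
      j <- (c2 - 1) * H + rr
      A[k, k] <- A[k, k] + 1
      b[k] <- b[k] + synth[i] - synth[j]
      if (pos[j] > 0) A[k, pos[j]] <- -1 else b[k] <- b[k] + orig[j]
    }
  }
  out <- orig
  # the repair clips to the valid intensity range; mirror that here
  out[idx] <- pmin(pmax(solve(A, b), 0), 1)
  out
}
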