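# Seeded generator for expression tensors with planted zone / region /
# time effects and known per-gene ground-truth flags.

#' Simulate a gene x specimen x region x zone expression dataset
#'
#' Each gene follows an additive linear model
#' `baseline + zone shift + region shift + time shift + N(0, noiseSd)`.
#' Effects are planted independently per factor with the configured
#' fractions, so the expected number of genes carrying all three effects
#' is `nGenes * prod(effectFractions)`. For a flagged factor the level
#' shifts are equally spaced over `[-effectSize/2, effectSize/2]` and
#' randomly assigned to levels, giving every flagged gene the same
#' planted effect magnitude. A configurable subset of region-flagged
#' genes instead receives shifts that increase monotonically along
#' `regionOrder`, to seed downstream association tests. Missing entries
#' are injected completely at random.
#'
#' @param nGenes number of genes.
#' @param zones tissue-zone vocabulary (outermost first).
#' @param nRegions number of cortical regions (named R01, R02, ...).
#' @param specimenAges named numeric vector of specimen ages in PCW;
#'   defaults to two early (15, 16) and two mid (21, 21) specimens.
#' @param effectFractions named numeric (zone, region, time) in [0, 1]:
#'   fraction of genes carrying each effect.
#' @param effectSize full range of the planted level shifts.
#' @param noiseSd residual standard deviation.
#' @param missingRate completely-at-random missingness rate in [0, 1].
#' @param monotoneFraction fraction of region-flagged genes whose region
#'   shifts are monotone in `regionOrder`.
#' @param regionOrder region ordering used for monotone effects
#'   (default: natural order).
#' @param baselineMean,baselineSd distribution of per-gene baselines.
#' @param seed integer seed.
#' @return An [ExpressionSimTruth-class] object.
#' @export
simulateExpressionDataset <- function(nGenes = 2000,
                                      zones = c("CP", "SP", "IZ", "SVZ", "VZ"),
                                      nRegions = 12,
                                      specimenAges = c(S1 = 15, S2 = 16,
                                                       S3 = 21, S4 = 21),
                                      effectFractions = c(zone = 0.1,
                                                          region = 0.1,
                                                          time = 0.1),
                                      effectSize = 1, noiseSd = 0.5,
                                      missingRate = 0, monotoneFraction = 0,
                                      regionOrder = NULL,
                                      baselineMean = 6, baselineSd = 1,
                                      seed = 1) {
  stopIfNot(all(effectFractions >= 0 & effectFractions <= 1),
            "effect fractions must lie in [0, 1]")
  stopIfNot(missingRate >= 0 && missingRate < 1,
            "missingRate must lie in [0, 1)")
  stopIfNot(monotoneFraction >= 0 && monotoneFraction <= 1,
            "monotoneFraction must lie in [0, 1]")
  stopIfNot(length(specimenAges) >= 2 && !is.null(names(specimenAges)),
            "specimenAges must be a named vector")
  regionNames <- sprintf("R%02d", seq_len(nRegions))
  if (is.null(regionOrder)) regionOrder <- regionNames
  stopIfNot(setequal(regionOrder, regionNames),
            "regionOrder must be a permutation of the region names")
  geneNames <- sprintf("G%05d", seq_len(nGenes))
  sp <- names(specimenAges)
  tp <- ifelse(specimenAges <= 16, "early", "mid")

  withSeed(seed, {
    flags <- data.frame(
      gene = geneNames,
      zoneEffect = stats::runif(nGenes) < effectFractions[["zone"]],
      regionEffect = stats::runif(nGenes) < effectFractions[["region"]],
      timeEffect = stats::runif(nGenes) < effectFractions[["time"]],
      monotoneRegion = FALSE)
    rIdx <- which(flags$regionEffect)
    nMono <- round(monotoneFraction * length(rIdx))
    if (nMono > 0)
      flags$monotoneRegion[rIdx[seq_len(nMono)]] <- TRUE

    vals <- array(NA_real_,
                  dim = c(nGenes, length(sp), nRegions, length(zones)),
                  dimnames = list(geneNames, sp, regionNames, zones))
    nZ <- length(zones); nR <- nRegions; nS <- length(sp)
    shiftScale <- function(n) effectSize * (seq_len(n) - (n + 1) / 2) / (n - 1)
    baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
    monoShift <- shiftScale(nR)
    names(monoShift) <- regionOrder
    for (g in seq_len(nGenes)) {
      zShift <- if (flags$zoneEffect[g]) sample(shiftScale(nZ)) else rep(0, nZ)
      rShift <- if (!flags$regionEffect[g]) rep(0, nR) else
        if (flags$monotoneRegion[g]) monoShift[regionNames] else
          sample(shiftScale(nR))
      tShift <- if (flags$timeEffect[g])
        sample(c(-0.5, 0.5)) * effectSize else c(0, 0)
      names(tShift) <- c("early", "mid")
      # cell means: specimen (via timepoint) x region x zone
      cell <- array(baseline[g], c(nS, nR, nZ))
      cell <- cell + array(rep(tShift[tp], nR * nZ), c(nS, nR, nZ))
      cell <- cell + array(rep(rShift, each = nS), c(nS, nR, nZ))
      cell <- cell + array(rep(zShift, each = nS * nR), c(nS, nR, nZ))
      vals[g, , , ] <- cell +
        array(stats::rnorm(nS * nR * nZ, 0, noiseSd), c(nS, nR, nZ))
    }
    if (missingRate > 0) {
      drop <- stats::runif(length(vals)) < missingRate
      vals[drop] <- NA_real_
    }
    methods::new("ExpressionSimTruth",
                 tensor = expressionTensor(vals, specimenAges),
                 flags = flags, effectSize = effectSize, noiseSd = noiseSd)
  })
}

#' Planted ZRT gene set of a simulated dataset
#'
#' @param truth an [ExpressionSimTruth-class].
#' @return Character vector of genes with all three planted effects.
#' @export
plantedZrtGenes <- function(truth) {
  f <- truth@flags
  f$gene[f$zoneEffect & f$regionEffect & f$timeEffect]
}
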