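# Seeded generator for annotation resources: gene sets with planted
# enrichment, a probe->gene table, and per-gene score tables with a
# planted low-median subset.

#' Simulate gene sets, a probe table and annotation scores
#'
#' Builds a background gene universe, a designated set of interest, and
#' a collection of gene sets each drawn to achieve a planted enrichment
#' ratio against the interest set (ratio 1 corresponds to a uniform
#' random draw from the background). Also emits a probe table in which
#' genes may carry multiple probes (with present/absent flags, a
#' multi-gene flag and a per-probe cross-specimen reproducibility score)
#' and a per-gene score table in which a planted subset is shifted by a
#' fixed amount.
#'
#' @param nGenes background universe size.
#' @param interestFraction fraction of the universe forming the set of
#'   interest.
#' @param geneSets data.frame with columns `name`, `size`,
#'   `enrichmentRatio` describing the sets to plant.
#' @param maxProbesPerGene probes per gene are uniform on
#'   `1..maxProbesPerGene`.
#' @param absentRate fraction of probes flagged absent.
#' @param multiGeneRate fraction of probes additionally assigned to a
#'   second gene (flagged `multiGene`).
#' @param scoreShift additive shift applied to the planted score subset.
#' @param scoreShiftSetSize size of the planted shifted subset.
#' @param scoreBase,scoreNoiseSd baseline score level and noise; with
#'   `scoreNoiseSd = 0` the planted median shift equals `scoreShift`
#'   exactly.
#' @param seed integer seed.
#' @return List with `universe`, `interestSet`, `geneSets` (named list of
#'   character vectors), `probeTable`, `scoreTable`, `plantedLowSet`.
#' @export
simulateAnnotationResources <- function(nGenes = 1000, interestFraction = 0.2,
                                        geneSets = data.frame(
                                          name = c("setA", "setB"),
                                          size = c(50, 50),
                                          enrichmentRatio = c(2, 1)),
                                        maxProbesPerGene = 3,
                                        absentRate = 0.2,
                                        multiGeneRate = 0.02,
                                        scoreShift = -0.3,
                                        scoreShiftSetSize = 50,
                                        scoreBase = 0.5, scoreNoiseSd = 0,
                                        seed = 1) {
  stopIfNot(interestFraction > 0 && interestFraction < 1,
            "interestFraction must lie in (0, 1)")
  universe <- sprintf("G%05d", seq_len(nGenes))
  withSeed(seed, {
    nInt <- round(interestFraction * nGenes)
    interest <- sort(sample(universe, nInt))
    rest <- setdiff(universe, interest)
    sets <- list()
    for (i in seq_len(nrow(geneSets))) {
      K <- geneSets$size[i]
      rho <- geneSets$enrichmentRatio[i]
      # enrichment ratio = (x/N)/(K/M) with N = |interest|, M = |universe|
      x <- round(rho * K * nInt / nGenes)
      if (x > min(K, nInt) || K - x > length(rest))
        stop(sprintf("planted overlap %d exceeds set sizes for '%s'",
                     x, geneSets$name[i]))
      sets[[geneSets$name[i]]] <- if (abs(rho - 1) < 1e-12)
        sort(sample(universe, K))
      else sort(c(sample(interest, x), sample(rest, K - x)))
    }
    nProbes <- sample.int(maxProbesPerGene, nGenes, replace = TRUE)
    probeGene <- rep(universe, nProbes)
    probeTable <- data.frame(
      probeId = sprintf("P%06d", seq_along(probeGene)),
      gene = probeGene,
      present = stats::runif(length(probeGene)) >= absentRate,
      multiGene = stats::runif(length(probeGene)) < multiGeneRate,
      reproducibility = stats::runif(length(probeGene), 0, 1),
      stringsAsFactors = FALSE)
    low <- sort(sample(universe, scoreShiftSetSize))
    score <- rep(scoreBase, nGenes) +
      if (scoreNoiseSd > 0) stats::rnorm(nGenes, 0, scoreNoiseSd) else 0
    names(score) <- universe
    score[low] <- score[low] + scoreShift
    list(universe = universe, interestSet = interest, geneSets = sets,
         probeTable = probeTable,
         scoreTable = data.frame(gene = universe, score = unname(score),
                                 stringsAsFactors = FALSE),
         plantedLowSet = low)
  })
}
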