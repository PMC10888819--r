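# Expression-scaling association (Kendall tau), allometric gene-set
# splitting, and enrichment statistics: hypergeometric tests, odds
# ratios and permutation tests against random gene sets.

#' Kendall correlation of regional expression with parcel scaling
#'
#' For each gene, zone and timepoint, correlates the gene's regional
#' expression profile (averaged over the timepoint's specimens) with the
#' parcel-mean allometric scaling beta across the regions shared by the
#' tensor and the parcel table, using tie-corrected Kendall tau-b.
#' Benjamini-Hochberg FDR is applied across the whole gene x zone x
#' timepoint batch. A `regionSubset` restricts the analysis (e.g. to the
#' neocortex by excluding allo- and periallocortical regions). Genes
#' with constant expression across regions have undefined tau and are
#' excluded from the FDR batch.
#'
#' @param tensor an [ExpressionTensor-class].
#' @param parcelBeta named numeric vector of mean scaling per region.
#' @param zoneSet zones to test (default: all in the tensor).
#' @param timepointSet timepoints to test (`"early"`, `"mid"`).
#' @param regionSubset optional character vector restricting regions.
#' @param geneSubset optional character vector restricting genes.
#' @param alpha FDR significance level.
#' @param minRegions minimum shared regions required.
#' @return data.frame (gene, zone, timepoint, tau, p, q, nRegions,
#'   direction, significant).
#' @export
expressionScalingAssociation <- function(tensor, parcelBeta,
                                         zoneSet = zones(tensor),
                                         timepointSet = c("early", "mid"),
                                         regionSubset = NULL,
                                         geneSubset = NULL, alpha = 0.01,
                                         minRegions = 5) {
  rg <- intersect(regions(tensor), names(parcelBeta))
  if (!is.null(regionSubset)) rg <- intersect(rg, regionSubset)
  stopIfNot(length(rg) >= minRegions,
            sprintf("need >= %d regions common to tensor and parcel table",
                    minRegions))
  gs <- if (is.null(geneSubset)) genes(tensor) else
    intersect(genes(tensor), geneSubset)
  tp <- timepoints(tensor)
  beta <- parcelBeta[rg]
  rows <- list()
  for (t in timepointSet) {
    spSel <- specimens(tensor)[tp == t]
    if (!length(spSel)) next
    for (z in intersect(zoneSet, zones(tensor))) {
      # genes x regions, averaged over the timepoint's specimens
      sub <- tensor@values[gs, spSel, rg, z, drop = FALSE]
      em <- apply(sub, c(1, 3), mean, na.rm = TRUE)
      for (g in gs) {
        ev <- em[g, ]
        ok <- is.finite(ev)
        if (sum(ok) < minRegions) next
        x <- ev[ok]; y <- beta[ok]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # tau undefined
        tau <- stats::cor(x, y, method = "kendall")
        p <- suppressWarnings(
          stats::cor.test(x, y, method = "kendall")$p.value)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, zone = z, timepoint = t, tau = tau, p = p,
          nRegions = sum(ok),
          direction = if (tau > 0) "hyper" else if (tau < 0) "hypo" else "none")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), zone = character(),
               timepoint = character(), tau = numeric(), p = numeric(),
               nRegions = integer(), direction = character())
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

#' Split significant associations into hyper-/hypoallometric sets
#'
#' Partitions significant association records by the sign of tau, per
#' (zone, timepoint) and pooled over the batch (a gene counts once in
#' the pooled set even when significant in several zones).
#'
#' @param records data.frame from [expressionScalingAssociation()].
#' @param alpha FDR significance level applied to `q`.
#' @return List with `perZone` (data.frame of counts), `hyper`, `hypo`
#'   (pooled unique gene sets), `pooled` (all significant genes) and
#'   `nSignificantAssociations`.
#' @export
splitAllometricSets <- function(records, alpha = 0.01) {
  sig <- records[!is.na(records$q) & records$q < alpha, , drop = FALSE]
  perZone <- if (nrow(sig)) stats::aggregate(
    list(n = sig$gene),
    by = list(zone = sig$zone, timepoint = sig$timepoint,
              direction = sig$direction), FUN = length) else
    data.frame(zone = character(), timepoint = character(),
               direction = character(), n = integer())
  list(perZone = perZone,
       hyper = sort(unique(sig$gene[sig$direction == "hyper"])),
       hypo = sort(unique(sig$gene[sig$direction == "hypo"])),
       pooled = sort(unique(sig$gene)),
       nSignificantAssociations = nrow(sig))
}

#' Hypergeometric gene-set enrichment
#'
#' Overlap test of a set of interest (size N) against an annotation
#' gene set (size K) within a background universe (size M), after
#' deduplication and intersection with the background. The enrichment
#' ratio is `(x/N) / (K/M)` and the p value is the upper tail
#' `P(X >= x)` of the hypergeometric distribution, evaluated with
#' log-gamma arithmetic. Setting `strictPrintedFormula = TRUE` uses the
#' strict-inequality tail `P(X > x)` instead.
#'
#' @param interestSet,geneSet,background character vectors of gene
#'   symbols.
#' @param name label carried into the result.
#' @param strictPrintedFormula use `P(X > x)` instead of `P(X >= x)`.
#' @return One-row data.frame (name, M, N, K, x, enrichmentRatio, p).
#' @export
hypergeometricEnrichment <- function(interestSet, geneSet, background,
                                     name = "geneset",
                                     strictPrintedFormula = FALSE) {
  background <- unique(background)
  interest <- intersect(unique(interestSet), background)
  gset <- intersect(unique(geneSet), background)
  M <- length(background); N <- length(interest); K <- length(gset)
  x <- length(intersect(interest, gset))
  ratio <- if (N == 0 || K == 0) NA_real_ else (x / N) / (K / M)
  p <- if (N == 0 || K == 0) 1 else
    stats::phyper(x - !strictPrintedFormula, K, M - K, N, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  data.frame(name = name, M = M, N = N, K = K, x = x,
             enrichmentRatio = ratio, p = p, stringsAsFactors = FALSE)
}

#' Batched enrichment over a list of gene sets
#'
#' @param interestSet character vector of genes of interest.
#' @param geneSets named list of character vectors.
#' @param background background universe.
#' @param ... passed to [hypergeometricEnrichment()].
#' @return data.frame with one row per gene set and BH-adjusted `q`.
#' @export
enrichGeneSets <- function(interestSet, geneSets, background, ...) {
  out <- do.call(rbind, lapply(names(geneSets), function(nm)
    hypergeometricEnrichment(interestSet, geneSets[[nm]], background,
                             name = nm, ...)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Odds ratio between two proportions or 2x2 counts
#'
#' `OR = [p1 / (1 - p1)] / [p2 / (1 - p2)]`. With counts
#' (`x1` of `n1` vs `x2` of `n2`), a two-sided Fisher exact p value is
#' also computed; with bare proportions the p value is omitted.
#' Degenerate proportions (0 or 1) yield an infinite or zero odds ratio.
#'
#' @param x1,n1,x2,n2 success counts and totals.
#' @param p1,p2 proportions (alternative to counts).
#' @return List with `oddsRatio` and (for counts) `p`.
#' @export
proportionOddsRatio <- function(x1 = NULL, n1 = NULL, x2 = NULL, n2 = NULL,
                                p1 = NULL, p2 = NULL) {
  if (is.null(p1)) {
    stopIfNot(!is.null(x1) && !is.null(n1) && !is.null(x2) && !is.null(n2),
              "supply counts (x1, n1, x2, n2) or proportions (p1, p2)")
    stopIfNot(n1 >= 1 && n2 >= 1, "totals must be >= 1")
    p1 <- x1 / n1; p2 <- x2 / n2
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE)
    pv <- stats::fisher.test(tab)$p.value
  } else {
    stopIfNot(p1 >= 0 && p1 <= 1 && p2 >= 0 && p2 <= 1,
              "proportions must lie in [0, 1]")
    pv <- NULL
  }
  o1 <- if (p1 == 1) Inf else p1 / (1 - p1)
  o2 <- if (p2 == 1) Inf else p2 / (1 - p2)
  or <- if (o2 == 0) (if (o1 == 0) NaN else Inf) else o1 / o2
  out <- list(oddsRatio = or)
  if (!is.null(pv)) out$p <- pv
  out
}

#' Permutation test of a gene set's median annotation score
#'
#' Compares the observed median score of a gene set against the medians
#' of `nPerm` uniformly drawn random gene sets of the same size from the
#' scored universe. The one-sided p value is
#' `(1 + #{null <= observed}) / (nPerm + 1)` for `side = "low"` (and
#' with `>=` for `side = "high"`), so `p >= 1 / (nPerm + 1)` always.
#'
#' @param geneSet character vector.
#' @param scoreTable data.frame (gene, score).
#' @param nPerm number of random gene sets.
#' @param seed integer seed.
#' @param side `"low"`: is the median lower than chance? `"high"`:
#'   higher?
#' @return List of class `PermutationTestResult`: observed, null
#'   quantiles, nPerm, seed, side, p.
#' @export
permutationMedianTest <- function(geneSet, scoreTable, nPerm = 10000,
                                  seed = 1, side = c("low", "high")) {
  side <- match.arg(side)
  stopIfNot(nPerm >= 99, "nPerm too small")
  scores <- stats::setNames(scoreTable$score, scoreTable$gene)
  scores <- scores[!is.na(scores)]
  inSet <- intersect(unique(geneSet), names(scores))
  if (length(inSet) < 2) stop("gene set has fewer than 2 scored genes")
  observed <- stats::median(scores[inSet])
  g <- length(inSet)
  nullMed <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i)
      stats::median(scores[sample.int(length(scores), g)]), numeric(1))
  })
  p <- if (side == "low") (1 + sum(nullMed <= observed)) / (nPerm + 1)
  else (1 + sum(nullMed >= observed)) / (nPerm + 1)
  structure(list(observed = observed,
                 nullSummary = stats::quantile(nullMed,
                                               c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 nPerm = nPerm, seed = seed, side = side, p = p,
                 setSize = g),
            class = "PermutationTestResult")
}

#' @export
print.PermutationTestResult <- function(x, ...) {
  cat(sprintf(
    "Permutation median test (%s side): observed %.4f over %d genes, p = %.4g (%d permutations)\n",
    x$side, x$observed, x$setSize, x$p, x$nPerm))
  invisible(x)
}
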