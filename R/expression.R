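# Probe-level microarray processing: probe filtering, differential
# stability, per-gene probe selection and aggregation into an expression
# tensor.

#' Filter probes by annotation quality
#'
#' Drops probes assigned to more than one gene, probes without a gene
#' assignment, and probes flagged absent (low signal over background).
#' Counts of each removal class are attached as attribute `"audit"`.
#'
#' @param probeTable data.frame with columns probeId, gene, present,
#'   multiGene.
#' @param expression numeric matrix, probes x samples, rownames
#'   probeId.
#' @return List with filtered `probeTable` and `expression`.
#' @export
filterProbes <- function(probeTable, expression) {
  stopIfNot(all(rownames(expression) %in% probeTable$probeId),
            "expression row without probe record")
  pt <- probeTable[match(rownames(expression), probeTable$probeId), ]
  geneless <- is.na(pt$gene) | pt$gene == ""
  multi <- as.logical(pt$multiGene)
  absent <- !as.logical(pt$present)
  keep <- !(geneless | multi | absent)
  if (!any(keep))
    warning("all probes removed by filtering; empty output")
  audit <- c(input = nrow(pt), geneless = sum(geneless),
             multiGene = sum(multi & !geneless),
             absent = sum(absent & !multi & !geneless), retained = sum(keep))
  out <- list(probeTable = pt[keep, , drop = FALSE],
              expression = expression[keep, , drop = FALSE])
  attr(out, "audit") <- audit
  out
}

# probe x (specimen, cell) averaging: samples sharing a (specimen,
# region, zone) cell are averaged before correlation.
.specimenCellMatrices <- function(expression, meta) {
  cell <- paste(meta$region, meta$zone, sep = "|")
  out <- list()
  for (sp in unique(meta$specimenId)) {
    sel <- meta$specimenId == sp
    cells <- cell[sel]
    sub <- expression[, sel, drop = FALSE]
    ag <- t(apply(sub, 1, function(r) tapply(r, cells, mean, na.rm = TRUE)))
    if (nrow(sub) == 1L) {
      ag <- matrix(ag, 1, dimnames = list(rownames(sub), sort(unique(cells))))
    }
    out[[sp]] <- ag
  }
  out
}

# vectorised row-wise Pearson correlation of two matrices over their
# shared finite cells (>= minOverlap), NA otherwise.
.rowwisePearson <- function(A, B, minOverlap) {
  common <- intersect(colnames(A), colnames(B))
  A <- A[, common, drop = FALSE]; B <- B[, common, drop = FALSE]
  ok <- is.finite(A) & is.finite(B)
  A[!ok] <- 0; B[!ok] <- 0
  n <- rowSums(ok)
  sa <- rowSums(A); sb <- rowSums(B)
  saa <- rowSums(A^2); sbb <- rowSums(B^2); sab <- rowSums(A * B)
  num <- sab - sa * sb / n
  den <- sqrt(pmax(saa - sa^2 / n, 0) * pmax(sbb - sb^2 / n, 0))
  r <- ifelse(n >= minOverlap & den > 0, num / den, NA_real_)
  r
}

#' Differential stability per probe
#'
#' For every pair of specimens, the Pearson correlation of a probe's
#' expression over the (region, zone) cells sampled in both specimens
#' (replicate samples within a cell are averaged first). The DS score is
#' the mean over specimen pairs with at least `minOverlap` common cells;
#' probes for which no pair qualifies have undefined (`NA`) DS, which is
#' treated as below threshold downstream.
#'
#' @param expression probes x samples matrix.
#' @param meta data.frame with columns sampleId, specimenId, region,
#'   zone matching the expression columns (by position or sampleId).
#' @param minOverlap minimum common cells per specimen pair.
#' @return Named numeric vector of DS values per probe.
#' @export
differentialStability <- function(expression, meta, minOverlap = 4) {
  specimens <- unique(meta$specimenId)
  stopIfNot(length(specimens) >= 2, "differential stability needs >= 2 specimens")
  mats <- .specimenCellMatrices(expression, meta)
  pairs <- utils::combn(specimens, 2, simplify = FALSE)
  rs <- sapply(pairs, function(p)
    .rowwisePearson(mats[[p[1]]], mats[[p[2]]], minOverlap))
  if (is.null(dim(rs))) rs <- matrix(rs, nrow = nrow(expression))
  ds <- rowMeans(rs, na.rm = TRUE)
  ds[!is.finite(ds)] <- NA_real_
  names(ds) <- rownames(expression)
  ds
}

#' Select one probe per gene by differential stability
#'
#' Keeps, for each gene, the probe with the highest DS (ties broken by
#' lexicographically smaller probeId; undefined DS sorts last), then
#' drops genes whose selected probe has `DS < threshold`.
#'
#' @param probeTable filtered probe table (probeId, gene).
#' @param expression probes x samples matrix.
#' @param ds named DS vector from [differentialStability()].
#' @param threshold DS threshold below which genes are removed.
#' @return List with `expression` (genes x samples, rownames = gene),
#'   `selection` (data.frame gene, probeId, ds) and attribute `"audit"`.
#' @export
selectProbePerGene <- function(probeTable, expression, ds, threshold = 0.2) {
  dsv <- ds[probeTable$probeId]
  ord <- order(probeTable$gene, -ifelse(is.na(dsv), -Inf, dsv),
               probeTable$probeId)
  pt <- probeTable[ord, ]
  sel <- pt[!duplicated(pt$gene), ]
  selDs <- ds[sel$probeId]
  keep <- !is.na(selDs) & selDs >= threshold
  selection <- data.frame(gene = sel$gene, probeId = sel$probeId,
                          ds = unname(selDs))[keep, ]
  expr <- expression[selection$probeId, , drop = FALSE]
  rownames(expr) <- selection$gene
  out <- list(expression = expr, selection = selection)
  attr(out, "audit") <- c(genesIn = length(unique(probeTable$gene)),
                          genesBelowThreshold = sum(!keep),
                          genesRetained = sum(keep))
  out
}

#' Aggregate gene-level samples into an expression tensor
#'
#' Averages replicate samples per (gene, specimen, region, zone) cell,
#' then removes genes missing in more than `missingCeiling` of the
#' sampled tensor cells. Samples whose region or zone cannot be mapped
#' to the supplied vocabularies are excluded with a warning.
#'
#' @param expression genes x samples matrix (rownames = gene).
#' @param meta data.frame with sampleId, specimenId, agePcw, region,
#'   zone.
#' @param missingCeiling maximum tolerated fraction of missing cells per
#'   gene, counted over the cells sampled in at least one specimen.
#' @param zoneVocabulary allowed zone labels.
#' @return An [ExpressionTensor-class]; drop counts in attribute
#'   `"audit"`.
#' @export
aggregateSamples <- function(expression, meta, missingCeiling = 0.10,
                             zoneVocabulary = c("CP", "SP", "IZ", "SVZ", "VZ")) {
  bad <- is.na(meta$region) | meta$region == "" | !(meta$zone %in% zoneVocabulary)
  if (any(bad)) {
    warning(sum(bad), " samples with unmappable region/zone excluded")
    meta <- meta[!bad, , drop = FALSE]
    expression <- expression[, !bad, drop = FALSE]
  }
  specimensU <- sort(unique(meta$specimenId))
  regionsU <- sort(unique(meta$region))
  zonesU <- zoneVocabulary[zoneVocabulary %in% meta$zone]
  G <- nrow(expression)
  vals <- array(NA_real_, c(G, length(specimensU), length(regionsU),
                            length(zonesU)),
                dimnames = list(rownames(expression), specimensU, regionsU,
                                zonesU))
  cellOf <- paste(meta$specimenId, meta$region, meta$zone, sep = "|")
  for (cl in unique(cellOf)) {
    sel <- cellOf == cl
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    v <- rowMeans(expression[, sel, drop = FALSE], na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    vals[, parts[1], parts[2], parts[3]] <- v
  }
  # cells sampled anywhere in the design define the missingness universe
  sampled <- array(FALSE, dim(vals)[2:4], dimnames = dimnames(vals)[2:4])
  for (cl in unique(cellOf)) {
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    sampled[parts[1], parts[2], parts[3]] <- TRUE
  }
  nCells <- sum(sampled)
  missFrac <- apply(vals, 1, function(a) sum(is.na(a[sampled])) / nCells)
  keep <- missFrac <= missingCeiling
  age <- tapply(meta$agePcw, meta$specimenId, function(a) a[1])
  tensor <- expressionTensor(vals[keep, , , , drop = FALSE],
                             stats::setNames(as.numeric(age), names(age)))
  attr(tensor, "audit") <- c(genesIn = G, genesDropped = sum(!keep),
                             genesRetained = sum(keep), cells = nCells)
  tensor
}
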