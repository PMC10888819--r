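# Per-gene linear models of expression over tissue zone, cortical region
# and gestational timepoint; FDR-controlled classification into the ZRT
# set; zone-wise fold changes.

# long-format design of a tensor: one row per (specimen, region, zone)
# cell, plus the derived timepoint factor
.tensorDesign <- function(tensor) {
  d <- dim(tensor@values)
  sp <- specimens(tensor); rg <- regions(tensor); zn <- zones(tensor)
  grid <- expand.grid(specimen = sp, region = rg, zone = zn,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$time <- ifelse(tensor@specimenAge[grid$specimen] <= 16, "early", "mid")
  grid
}

# response matrix: cells x genes
.tensorResponse <- function(tensor) {
  d <- dim(tensor@values)
  m <- matrix(aperm(tensor@values, c(2, 3, 4, 1)), prod(d[2:4]), d[1])
  colnames(m) <- genes(tensor)
  m
}

# guarded F ratio: a numerically zero full-model residual means either a
# perfect fit with no factor contribution (F = 0) or an exact effect
# (F = Inf, p = 0); plain division would return floating-point noise
.guardedF <- function(num, den, scale) {
  tol <- 1e-10 * (scale + 1e-300)
  ifelse(den > tol, pmax(num / den, 0),
         ifelse(num > tol, Inf, 0))
}

.partialF <- function(X, Xred, y) {
  qf <- qr(X)
  rf <- qr.resid(qf, y)
  rssF <- sum(rf^2)
  dfResid <- length(y) - qf$rank
  qr_ <- qr(Xred)
  rssR <- sum(qr.resid(qr_, y)^2)
  dfe <- qf$rank - qr_$rank
  if (dfe < 1 || dfResid < 1) return(c(NA, NA))
  Fv <- .guardedF((rssR - rssF) / dfe, rssF / dfResid, mean(y^2))
  c(Fv, stats::pf(Fv, dfe, dfResid, lower.tail = FALSE))
}

#' Per-gene main-effects linear models over zone, region and time
#'
#' Fits, for every gene, an ordinary least squares model of expression
#' on dummy-coded main effects of tissue zone, cortical region and
#' timepoint (early, <= 16 PCW, vs mid gestation), and computes a
#' partial (type II) F test per factor:
#' `F = ((RSS_reduced - RSS_full) / ddf) / (RSS_full / df_resid)`.
#' Missing cells are dropped listwise per gene; a gene whose design
#' collapses to a single level on some factor is flagged unevaluable for
#' that factor (`NA` statistics).
#'
#' @param tensor an [ExpressionTensor-class].
#' @return data.frame with one row per gene: F, p per factor and an
#'   `evaluable` flag.
#' @export
fitZrtModels <- function(tensor) {
  design <- .tensorDesign(tensor)
  Y <- .tensorResponse(tensor)
  factors <- c("zone", "region", "time")
  for (f in factors)
    stopIfNot(length(unique(design[[f]])) >= 2,
              sprintf("factor '%s' needs >= 2 levels", f))
  fullF <- stats::as.formula("~ zone + region + time")
  X <- stats::model.matrix(fullF, design)
  Xred <- lapply(factors, function(f)
    stats::model.matrix(stats::as.formula(paste("~", paste(setdiff(factors, f),
                                                           collapse = " + "))),
                        design))
  names(Xred) <- factors
  G <- ncol(Y)
  out <- data.frame(gene = colnames(Y),
                    F_zone = NA_real_, p_zone = NA_real_,
                    F_region = NA_real_, p_region = NA_real_,
                    F_time = NA_real_, p_time = NA_real_,
                    evaluable = FALSE)
  complete <- colSums(is.na(Y)) == 0L
  if (any(complete)) {
    # shared design: residual sums of squares for all complete genes at once
    qf <- qr(X)
    dfResid <- nrow(X) - qf$rank
    rssF <- colSums(qr.resid(qf, Y[, complete, drop = FALSE])^2)
    scale <- colMeans(Y[, complete, drop = FALSE]^2)
    for (f in factors) {
      qr_ <- qr(Xred[[f]])
      dfe <- qf$rank - qr_$rank
      rssR <- colSums(qr.resid(qr_, Y[, complete, drop = FALSE])^2)
      Fv <- .guardedF((rssR - rssF) / dfe, rssF / dfResid, scale)
      out[complete, paste0("F_", f)] <- Fv
      out[complete, paste0("p_", f)] <- stats::pf(Fv, dfe, dfResid,
                                                  lower.tail = FALSE)
    }
    out$evaluable[complete] <- TRUE
  }
  for (g in which(!complete)) {
    ok <- !is.na(Y[, g])
    if (sum(ok) < 4) next
    sub <- design[ok, , drop = FALSE]
    if (any(vapply(factors, function(f) length(unique(sub[[f]])) < 2, TRUE)))
      next
    Xg <- stats::model.matrix(fullF, sub)
    y <- Y[ok, g]
    evaluable <- TRUE
    for (f in factors) {
      Xr <- stats::model.matrix(
        stats::as.formula(paste("~", paste(setdiff(factors, f),
                                           collapse = " + "))), sub)
      fp <- .partialF(Xg, Xr, y)
      if (anyNA(fp)) evaluable <- FALSE
      out[g, paste0("F_", f)] <- fp[1]
      out[g, paste0("p_", f)] <- fp[2]
    }
    out$evaluable[g] <- evaluable
  }
  out
}

#' Single-gene zone/region/time model
#'
#' @param tensor an [ExpressionTensor-class].
#' @param gene gene identifier.
#' @return One-row data.frame as in [fitZrtModels()].
#' @export
fitGeneGLM <- function(tensor, gene) {
  stopIfNot(gene %in% genes(tensor), "unknown gene")
  sub <- expressionTensor(tensor@values[gene, , , , drop = FALSE],
                          tensor@specimenAge)
  fitZrtModels(sub)
}

#' Classify genes into zone / region / time sets by FDR
#'
#' Applies Benjamini-Hochberg FDR correction across genes separately
#' within each factor and intersects the significant sets: the ZRT set
#' contains genes significant on all three factors at `q < alpha`.
#'
#' @param stats data.frame from [fitZrtModels()].
#' @param alpha FDR significance level.
#' @return List with the augmented `stats` (q values, zrt flag), the
#'   per-factor gene `sets`, `zrt` genes and `vennCounts`.
#' @export
classifyZrt <- function(stats, alpha = 0.01) {
  for (f in c("zone", "region", "time"))
    stats[[paste0("q_", f)]] <- stats::p.adjust(stats[[paste0("p_", f)]],
                                                method = "BH")
  sig <- function(f) !is.na(stats[[paste0("q_", f)]]) &
    stats[[paste0("q_", f)]] < alpha
  z <- sig("zone"); r <- sig("region"); t <- sig("time")
  stats$zrt <- z & r & t
  venn <- c(Z = sum(z & !r & !t), R = sum(!z & r & !t), T = sum(!z & !r & t),
            ZR = sum(z & r & !t), ZT = sum(z & !r & t), RT = sum(!z & r & t),
            ZRT = sum(z & r & t), none = sum(!z & !r & !t))
  list(stats = stats,
       sets = list(zone = stats$gene[z], region = stats$gene[r],
                   time = stats$gene[t]),
       zrt = stats$gene[stats$zrt],
       vennCounts = venn, alpha = alpha)
}

#' Zone-wise fold change between timepoints
#'
#' Per gene, the mean expression over specimens and regions at each
#' timepoint within a tissue zone, and the log2 ratio mid vs early.
#' Genes with a non-positive mean at either timepoint have undefined
#' fold change (recorded as `NA`).
#'
#' @param tensor an [ExpressionTensor-class].
#' @param zone tissue zone to evaluate.
#' @param threshold absolute log2 fold-change flag threshold.
#' @return data.frame (gene, zone, meanEarly, meanMid, log2fc, flagged).
#' @export
zoneFoldChange <- function(tensor, zone, threshold = 0.3) {
  stopIfNot(zone %in% zones(tensor), "unknown zone")
  tp <- timepoints(tensor)
  stopIfNot(all(c("early", "mid") %in% tp),
            "both timepoints must be present")
  sub <- tensor@values[, , , zone, drop = FALSE]
  me <- apply(sub[, tp == "early", , 1, drop = FALSE], 1, mean, na.rm = TRUE)
  mm <- apply(sub[, tp == "mid", , 1, drop = FALSE], 1, mean, na.rm = TRUE)
  lfc <- rep(NA_real_, length(me))
  pos <- is.finite(me) & is.finite(mm) & me > 0 & mm > 0
  lfc[pos] <- log2(mm[pos]) - log2(me[pos])
  data.frame(gene = genes(tensor), zone = zone, meanEarly = me, meanMid = mm,
             log2fc = lfc,
             flagged = !is.na(lfc) & abs(lfc) > threshold,
             row.names = NULL)
}
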