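makeMeta <- function(nSpec = 2, regions = paste0("R", 1:4), zones = "CP",
                     ages = c(15, 21)) {
  grid <- expand.grid(specimenId = paste0("S", seq_len(nSpec)),
                      region = regions, zone = zones,
                      stringsAsFactors = FALSE)
  grid$sampleId <- sprintf("s%03d", seq_len(nrow(grid)))
  grid$agePcw <- ages[match(grid$specimenId, paste0("S", seq_len(nSpec)))]
  grid
}

test_that("probe filtering drops multi-gene, gene-less and absent probes", {
  pt <- data.frame(probeId = sprintf("P%02d", 1:10),
                   gene = c(paste0("G", 1:8), NA, "G9"),
                   present = c(rep(TRUE, 5), FALSE, FALSE, FALSE, TRUE, TRUE),
                   multiGene = c(FALSE, TRUE, TRUE, rep(FALSE, 7)))
  expr <- matrix(rnorm(20), 10, 2, dimnames = list(pt$probeId, c("a", "b")))
  out <- filterProbes(pt, expr)
  # 3 absent, 2 multi-gene, 1 gene-less removed (disjoint sets)
  expect_identical(nrow(out$expression), 4L)
  expect_identical(sort(out$probeTable$gene), c("G1", "G4", "G5", "G9"))
  # untouched table passes through unchanged
  clean <- data.frame(probeId = c("P1", "P2"), gene = c("A", "B"),
                      present = TRUE, multiGene = FALSE)
  exprC <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  expect_identical(filterProbes(clean, exprC)$expression, exprC)
  allAbsent <- transform(clean, present = FALSE)
  expect_warning(out0 <- filterProbes(allAbsent, exprC), "all probes")
  expect_identical(nrow(out0$expression), 0L)
  expect_error(filterProbes(clean[1, ], exprC), "probe record")
})

test_that("differential stability averages pairwise specimen correlations", {
  meta <- makeMeta()
  # identical profiles across specimens: DS = 1; reversed: DS = -1
  expr <- rbind(p1 = c(1, 2, 3, 4, 1, 2, 3, 4),
                p2 = c(1, 2, 3, 4, 4, 3, 2, 1))
  ord <- order(meta$specimenId, meta$region)
  meta <- meta[ord, ]
  colnames(expr) <- meta$sampleId
  ds <- differentialStability(expr, meta, minOverlap = 4)
  expect_equal(unname(ds), c(1, -1))
  # three specimens: DS equals the mean of the pairwise Pearson values
  meta3 <- makeMeta(nSpec = 3, regions = paste0("R", 1:5),
                    ages = c(15, 16, 21))
  set.seed(4)
  prof <- matrix(rnorm(15), 3, 5)
  expr3 <- matrix(NA_real_, 1, nrow(meta3),
                  dimnames = list("p1", meta3$sampleId))
  for (i in seq_len(nrow(meta3)))
    expr3[1, i] <- prof[match(meta3$specimenId[i], c("S1", "S2", "S3")),
                        match(meta3$region[i], paste0("R", 1:5))]
  ds3 <- differentialStability(expr3, meta3, minOverlap = 4)
  oracle <- mean(c(cor(prof[1, ], prof[2, ]), cor(prof[1, ], prof[3, ]),
                   cor(prof[2, ], prof[3, ])))
  expect_equal(unname(ds3), oracle)
  # DS is invariant to affine rescaling of one specimen's values
  expr3b <- expr3
  sel <- meta3$specimenId == "S2"
  expr3b[, sel] <- 10 + 3 * expr3b[, sel]
  expect_equal(differentialStability(expr3b, meta3), ds3)
  # pairs with too few shared cells are excluded
  meta2 <- makeMeta(regions = paste0("R", 1:3))
  expr2 <- matrix(rnorm(6), 1, 6, dimnames = list("p1", meta2$sampleId))
  expect_true(is.na(differentialStability(expr2, meta2, minOverlap = 4)))
  one <- meta2$specimenId == "S1"
  expect_error(differentialStability(expr2[, one, drop = FALSE],
                                     meta2[one, ]), "2 specimens")
})

test_that("probe selection keeps the most stable probe per gene", {
  pt <- data.frame(probeId = c("P2", "P1", "P3", "P4", "P5"),
                   gene = c("A", "A", "B", "B", "C"))
  expr <- matrix(seq_len(10), 5, 2,
                 dimnames = list(c("P2", "P1", "P3", "P4", "P5"), NULL))
  ds <- c(P2 = 0.3, P1 = 0.1, P3 = 0.4, P4 = 0.4, P5 = 0.15)
  out <- selectProbePerGene(pt, expr, ds, threshold = 0.2)
  # gene A keeps its ds=0.3 probe; B breaks the tie lexicographically;
  # C falls below the threshold and is dropped
  expect_identical(out$selection$probeId[out$selection$gene == "A"], "P2")
  expect_identical(out$selection$probeId[out$selection$gene == "B"], "P3")
  expect_false("C" %in% out$selection$gene)
  expect_identical(rownames(out$expression), c("A", "B"))
  # single probe with adequate DS is kept
  one <- selectProbePerGene(data.frame(probeId = "P9", gene = "Z"),
                            matrix(1:2, 1, 2, dimnames = list("P9", NULL)),
                            c(P9 = 0.5))
  expect_identical(one$selection$gene, "Z")
})

test_that("aggregation averages replicates and enforces the missingness
           ceiling", {
  meta <- makeMeta()
  # add a replicate sample for (S1, R1, CP)
  meta <- rbind(meta, data.frame(specimenId = "S1", region = "R1",
                                 zone = "CP", sampleId = "s999",
                                 agePcw = 15))
  expr <- matrix(1, 2, nrow(meta),
                 dimnames = list(c("G1", "G2"), meta$sampleId))
  expr["G1", meta$sampleId[meta$specimenId == "S1" & meta$region == "R1"][1]] <- 2
  expr["G1", "s999"] <- 4
  tensor <- aggregateSamples(expr, meta)
  expect_equal(unname(tensor@values["G1", "S1", "R1", "CP"]), 3)  # mean(2, 4)
  # missingness: 1 of 8 cells (12.5%) > 10% ceiling drops the gene;
  # widen the design so 1 of 16 cells (6.25%) survives
  exprNA <- expr
  # the NA must hit an unreplicated cell; (S1, R1) has a backup replicate
  exprNA["G2", meta$sampleId[2]] <- NA
  expect_identical(genes(aggregateSamples(exprNA, meta)), "G1")
  metaW <- makeMeta(regions = paste0("R", 1:8))
  exprW <- matrix(1, 2, nrow(metaW),
                  dimnames = list(c("G1", "G2"), metaW$sampleId))
  exprW["G2", 1] <- NA
  expect_identical(sort(genes(aggregateSamples(exprW, metaW))),
                   c("G1", "G2"))
  # unmappable zone excluded with a warning
  metaBad <- meta; metaBad$zone[2] <- "XX"
  expect_warning(aggregateSamples(expr, metaBad), "unmappable")
})

test_that("the probe pipeline is stable under input row permutation", {
  a <- simulateAnnotationResources(nGenes = 60,
                                   geneSets = data.frame(name = "s",
                                                         size = 10,
                                                         enrichmentRatio = 1),
                                   seed = 3)
  e <- simulateExpressionDataset(nGenes = 60, effectFractions =
    c(zone = 0.5, region = 0.5, time = 0.5), seed = 4)
  pl <- fetalcortex:::.probeLevelData(e, a$probeTable, seed = 9)
  run <- function(expr, pt, meta) {
    filt <- filterProbes(pt, expr)
    ds <- differentialStability(filt$expression, meta)
    sel <- selectProbePerGene(filt$probeTable, filt$expression, ds)
    aggregateSamples(sel$expression, meta)
  }
  t1 <- run(pl$expression, pl$probeTable, pl$meta)
  set.seed(1)
  perm <- sample(nrow(pl$expression))
  t2 <- run(pl$expression[perm, ], pl$probeTable[perm, ], pl$meta)
  expect_equal(t1@values, t2@values)
  # every aggregated cell equals the mean of its contributing samples
  cellOf <- paste(pl$meta$specimenId, pl$meta$region, pl$meta$zone)
  sel <- selectProbePerGene(
    filterProbes(pl$probeTable, pl$expression)$probeTable,
    filterProbes(pl$probeTable, pl$expression)$expression,
    differentialStability(
      filterProbes(pl$probeTable, pl$expression)$expression, pl$meta))
  g <- rownames(sel$expression)[1]
  for (cl in unique(cellOf)[1:5]) {
    parts <- strsplit(cl, " ")[[1]]
    expect_equal(unname(t1@values[g, parts[1], parts[2], parts[3]]),
                 mean(sel$expression[g, cellOf == cl]))
  }
})
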