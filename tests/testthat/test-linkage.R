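test_that("nearest gene uses signed TSS-to-centre distance with lexicographic ties", {
  genes <- gr0("chr1", c(4000, 9000), c(4500, 9500), "+")
  genes$gene_id <- c("gX", "gY")
  region <- gr0("chr1", 4800, 5200)        # centre 5000
  names(region) <- "r1"
  out <- nearestGeneTss(region, genes)
  expect_equal(out$geneId, "gX")
  expect_equal(out$distance, -1000)

  tie <- gr0("chr1", c(3000, 7000), c(3400, 7400), "+")
  tie$gene_id <- c("B", "A")               # equidistant TSS at +-2000
  out2 <- nearestGeneTss(region, tie)
  expect_equal(out2$geneId, "A")

  ## minus-strand TSS is the high coordinate
  mgene <- gr0("chr1", 6000, 7001, "-")
  mgene$gene_id <- "gM"
  out3 <- nearestGeneTss(region, mgene)
  expect_equal(out3$distance, 7000 - 5000)

  nohit <- gr0("chr9", 0, 100)
  expect_true(is.na(nearestGeneTss(nohit, genes)$geneId))
})

test_that("nearest gene matches the exhaustive scan on random genomes", {
  for (seed in 31:35) {
    tabs <- randomGenomeTables(seed, nGenes = 50)
    genes <- gr0(tabs$genes$chrom, tabs$genes$start, tabs$genes$end,
                 tabs$genes$strand)
    genes$gene_id <- tabs$genes$gene_id
    regions <- gr0(tabs$peaks$chrom, tabs$peaks$start, tabs$peaks$end)
    names(regions) <- paste0("r", seq_along(regions))
    out <- nearestGeneTss(regions, genes)
    for (i in seq_along(regions)) {
      cen <- (tabs$peaks$start[i] + tabs$peaks$end[i]) %/% 2
      want <- oracleNearest(cen, tabs$peaks$chrom[i], tabs$genes)
      expect_equal(out$geneId[i], want$gene)
      expect_equal(out$distance[i], want$dist)
    }
  }
})

test_that("windowed correlation finds monotone transforms and respects the window", {
  set.seed(61)
  genes <- gr0("chr1", c(1000, 5000, 400000), c(2000, 6000, 401000), "+")
  genes$gene_id <- c("gNear", "gNeg", "gFar")
  region <- gr0("chr1", 2900, 3100)   # centre 3000: gFar outside 100 kb
  names(region) <- "e1"
  e <- matrix(runif(10), 1, dimnames = list("e1", paste0("s", 1:10)))
  g <- rbind(gNear = exp(2 * e[1, ]),          # monotone transform: rho 1
             gNeg = -e[1, ],                   # reversed ranks: rho -1
             gFar = e[1, ] + 100)
  colnames(g) <- colnames(e)
  res <- windowedBestCorrelation(e, g, region, genes)
  expect_equal(res$table$bestGeneId, "gNear")
  expect_equal(res$table$rho, 1)
  expect_equal(res$rho[1, "gNeg"], -1)
  expect_true(is.na(res$rho[1, "gFar"]))
  expect_equal(res$table$nGenesInWindow, 2L)
  ## |rho| ranking can prefer the strong negative
  resAbs <- windowedBestCorrelation(e, rbind(g, gNeg2 = g["gNeg", ]),
                                    region, c(genes, genes[2]), useAbs = TRUE)
  expect_equal(abs(resAbs$table$rho), 1)
  expect_error(windowedBestCorrelation(e[, 1:2, drop = FALSE], g, region, genes),
               "3 shared samples")
})

test_that("Spearman rho equals the hand rank formula on a small case", {
  genes <- gr0("chr1", 1000, 2000, "+")
  genes$gene_id <- "g1"
  region <- gr0("chr1", 900, 1100)
  names(region) <- "e1"
  e <- matrix(c(12, 7, 3, 9, 5), 1, dimnames = list("e1", paste0("s", 1:5)))
  g <- matrix(c(2, 9, 8, 1, 4), 1, dimnames = list("g1", paste0("s", 1:5)))
  res <- windowedBestCorrelation(e, g, region, genes)
  dr <- rank(e[1, ]) - rank(g[1, ])           # no ties: 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(res$table$rho, 1 - 6 * sum(dr^2) / (5 * 24))
})

test_that("net enhancer change counts gained minus lost within the TSS window and clamps", {
  genes <- gr0("chr1", 500000, 505000, "+")
  genes$gene_id <- "g1"
  mk <- function(cen) gr0("chr1", cen - 50, cen + 50)
  regions <- do.call(c, lapply(c(350000, 420000, 550000, 680000, 699000, 701000),
                               mk))
  labels <- c("B_specific", "B_specific", "A_specific", "B_specific",
              "B_specific", "B_specific")
  ## last region centre 701000 is 201000 bp from TSS 500000: outside
  nct <- netEnhancerChange(genes, regions, labels)
  expect_equal(nct$nGained, 4L)
  expect_equal(nct$nLost, 1L)
  expect_equal(nct$net, 3L)
  expect_equal(nct$bin, 3L)

  many <- do.call(c, lapply(seq(400000, 600000, by = 40000), mk))
  nct2 <- netEnhancerChange(genes, many, rep("B_specific", length(many)))
  expect_equal(nct2$net, 6L)
  expect_equal(nct2$bin, 4L)   # clamped into the nine bins
})

test_that("net change matches a brute-force all-pairs scan on random placements", {
  for (seed in 51:53) {
    tabs <- randomGenomeTables(seed, nGenes = 30, nPeaks = 80)
    genes <- gr0(tabs$genes$chrom, tabs$genes$start, tabs$genes$end,
                 tabs$genes$strand)
    genes$gene_id <- tabs$genes$gene_id
    regions <- gr0(tabs$peaks$chrom, tabs$peaks$start, tabs$peaks$end)
    set.seed(seed)
    labels <- sample(c("A_specific", "B_specific", "unclassified"), 80, TRUE)
    nct <- netEnhancerChange(genes, regions, labels, halfWindow = 5000)
    cen <- (tabs$peaks$start + tabs$peaks$end) %/% 2
    tss <- ifelse(tabs$genes$strand == "-", tabs$genes$end - 1, tabs$genes$start)
    for (i in seq_along(genes)) {
      near <- tabs$peaks$chrom == tabs$genes$chrom[i] & abs(cen - tss[i]) <= 5000
      expect_equal(nct$net[i],
                   sum(near & labels == "B_specific") -
                     sum(near & labels == "A_specific"))
    }
  }
})

test_that("bin expression shift summarises bins and applies Kruskal-Wallis", {
  nct <- S4Vectors::DataFrame(geneId = paste0("g", 1:6),
                              nGained = 0L, nLost = 0L, net = 0L,
                              bin = rep(c(-1L, 1L), each = 3))
  same <- setNames(rep(2, 6), nct$geneId)
  resSame <- binExpressionShift(nct, same)
  expect_equal(resSame$H, 0)
  expect_equal(resSame$p, 1)

  lfc <- setNames(c(1, 2, 3, 4, 5, 6), nct$geneId)
  res <- binExpressionShift(nct, lfc)
  expect_equal(res$H, 27 / 7, tolerance = 1e-10)   # hand rank computation
  expect_equal(res$p, pchisq(27 / 7, df = 1, lower.tail = FALSE))
  expect_equal(res$summary$median, c(2, 5))

  one <- nct; one$bin <- rep(0L, 6)
  expect_error(binExpressionShift(one, lfc), "2 non-empty bins")
})

test_that("overlap tests give exact hypergeometric tails and Fisher p-values", {
  u <- paste0("x", 1:10)
  res <- overlapTest(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$pHyper, 1 / 252)
  res0 <- overlapTest(u[1:5], u[6:10], u)
  expect_equal(res0$overlap, 0)
  resAll <- overlapTest(u, u, u)
  expect_equal(resAll$pHyper, 1)
  expect_equal(resAll$pFisher, 1)
  expect_error(overlapTest(c(u[1], "zz"), u[1:2], u), "subsets")

  set.seed(14)
  for (i in 1:5) {
    N <- sample(10:40, 1)
    un <- paste0("m", seq_len(N))
    A <- sample(un, sample(2:N, 1)); B <- sample(un, sample(2:N, 1))
    r <- overlapTest(A, B, un)
    expect_equal(r$pHyper,
                 oracleHyperUpper(N, length(A), length(B), r$overlap))
    expect_gte(r$pFisher, min(r$pHyper, 1 - r$pHyper + 1e-12) - 1e-12)
  }
})

test_that("outlier-high stratification uses median plus two population SDs", {
  x <- c(rep(10, 19), 30)
  expr <- matrix(x, 1, dimnames = list("ERBB2", paste0("s", 1:20)))
  hi <- stratifyByGene(expr, "ERBB2")
  sdPop <- sqrt(mean((x - mean(x))^2))
  expect_equal(unname(hi), x > median(x) + 2 * sdPop)
  expect_true(hi["s20"])
  expect_error(stratifyByGene(expr, "nope"), "not found")
})
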