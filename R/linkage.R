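#' Nearest-gene annotation of eRNA regions
#'
#' For each region, the signed distance to every gene is the strand-aware TSS
#' position minus the region centre; the nearest gene minimises the absolute
#' distance, with exact ties broken towards the lexicographically smaller
#' gene id. Regions on chromosomes without genes get `NA`.
#'
#' @param regions `GRanges` of eRNA regions.
#' @param genes `GRanges` with a `gene_id` column (see [readGeneAnnotation()]).
#' @return `DataFrame` with `regionId`, `geneId`, `distance` (bp, TSS minus
#'   centre).
#' @export
nearestGeneTss <- function(regions, genes) {
  ids <- if (!is.null(names(regions))) names(regions) else
    paste0("region_", seq_along(regions))
  out <- S4Vectors::DataFrame(regionId = ids,
                              geneId = rep(NA_character_, length(regions)),
                              distance = rep(NA_real_, length(regions)))
  if (length(regions) == 0L || length(genes) == 0L) return(out)
  tss <- .tss0(genes)
  cen <- .centre0(regions)
  gchr <- as.character(seqnames(genes))
  rchr <- as.character(seqnames(regions))
  for (chr in unique(rchr)) {
    gi <- which(gchr == chr)
    if (!length(gi)) next
    ord <- gi[order(tss[gi], genes$gene_id[gi])]
    tssS <- tss[ord]
    idS <- genes$gene_id[ord]
    for (r in which(rchr == chr)) {
      i <- findInterval(cen[r], tssS)
      cand <- integer()
      if (i >= 1L) cand <- match(tssS[i], tssS)          # first gene at left TSS
      if (i < length(tssS)) cand <- c(cand, i + 1L)      # first gene right of centre
      d <- tssS[cand] - cen[r]
      best <- which(abs(d) == min(abs(d)))
      if (length(best) > 1L) best <- best[order(idS[cand][best])][1L]
      out$geneId[r] <- idS[cand][best]
      out$distance[r] <- d[best]
    }
  }
  out
}

#' Windowed best-correlation eRNA-gene linkage
#'
#' For each eRNA region, Spearman's rho is computed between its expression
#' and that of every gene whose TSS lies within `halfWindow` bp of the region
#' centre, over the shared samples; the best-linked gene maximises the signed
#' rho (or `|rho|` with `useAbs = TRUE`).
#'
#' @param ernaExpr region x sample numeric matrix (e.g. FPM).
#' @param geneExpr gene x sample numeric matrix.
#' @param regions `GRanges` matching `rownames(ernaExpr)`.
#' @param genes `GRanges` with `gene_id` matching `rownames(geneExpr)`.
#' @param halfWindow window half-width around the region centre (default
#'   100000, i.e. a 200 kb window flanking the eRNA).
#' @param useAbs rank genes by `|rho|` instead of signed rho?
#' @return list with `table` (`DataFrame`: `regionId`, `bestGeneId`, `rho`,
#'   `nGenesInWindow`) and `rho`, the full region x gene Spearman matrix with
#'   `NA` outside the window.
#' @export
windowedBestCorrelation <- function(ernaExpr, geneExpr, regions, genes,
                                    halfWindow = 100000, useAbs = FALSE) {
  shared <- intersect(colnames(ernaExpr), colnames(geneExpr))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  e <- as.matrix(ernaExpr)[, shared, drop = FALSE]
  g <- as.matrix(geneExpr)[, shared, drop = FALSE]
  cen <- .centre0(regions)
  tss <- .tss0(genes)
  rchr <- as.character(seqnames(regions))
  gchr <- as.character(seqnames(genes))
  nR <- length(regions)
  rho <- matrix(NA_real_, nR, length(genes),
                dimnames = list(rownames(e), genes$gene_id))
  tab <- S4Vectors::DataFrame(regionId = rownames(e),
                              bestGeneId = rep(NA_character_, nR),
                              rho = rep(NA_real_, nR),
                              nGenesInWindow = integer(nR))
  for (r in seq_len(nR)) {
    inWin <- which(gchr == rchr[r] & abs(tss - cen[r]) <= halfWindow)
    tab$nGenesInWindow[r] <- length(inWin)
    if (!length(inWin)) next
    rr <- suppressWarnings(
      stats::cor(e[r, ], t(g[inWin, , drop = FALSE]), method = "spearman"))
    rho[r, inWin] <- rr
    score <- if (useAbs) abs(rr) else rr
    if (all(is.na(score))) next
    best <- which.max(score)
    tab$bestGeneId[r] <- genes$gene_id[inWin[best]]
    tab$rho[r] <- rr[best]
  }
  list(table = tab, rho = rho)
}

#' Net enhancer change per gene
#'
#' Counts, for each gene, the cohort-gained (`B_specific`) minus cohort-lost
#' (`A_specific`) eRNA regions whose centre lies within `halfWindow` bp of
#' the gene's TSS, and clamps the net change into the nine bins -4..+4.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param regions `GRanges` of eRNA regions.
#' @param labels factor from [classifyRegions()], parallel to `regions`.
#' @param halfWindow bp around the TSS (default 200000).
#' @return `DataFrame` with `geneId`, `nGained`, `nLost`, `net`, `bin`.
#' @export
netEnhancerChange <- function(genes, regions, labels, halfWindow = 200000) {
  stopifnot(length(labels) == length(regions))
  labels <- as.character(labels)
  tss <- .tss0(genes)
  cen <- .centre0(regions)
  gchr <- as.character(seqnames(genes))
  rchr <- as.character(seqnames(regions))
  nG <- length(genes)
  gained <- lost <- integer(nG)
  for (i in seq_len(nG)) {
    near <- rchr == gchr[i] & abs(cen - tss[i]) <= halfWindow
    gained[i] <- sum(near & labels == "B_specific")
    lost[i] <- sum(near & labels == "A_specific")
  }
  net <- gained - lost
  S4Vectors::DataFrame(geneId = genes$gene_id, nGained = gained, nLost = lost,
                       net = net, bin = pmin(4L, pmax(-4L, net)))
}

#' Gene expression shift between cohorts
#'
#' Mean expression in cohort B minus mean in cohort A per gene; on
#' log2-scale expression this is the log2 fold change.
#'
#' @param expr gene x sample matrix (log2 scale).
#' @param groups per-sample two-level factor (first level = cohort A).
#' @return named numeric vector.
#' @export
geneExpressionShift <- function(expr, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(expr) == length(groups))
  rowMeans(expr[, groups == levels(groups)[2], drop = FALSE]) -
    rowMeans(expr[, groups == levels(groups)[1], drop = FALSE])
}

#' Gene expression shift across net-enhancer-change bins
#'
#' Summarises the per-gene expression shift within each net-change bin
#' (median and quartiles) and tests for a bin effect with the Kruskal-Wallis
#' rank-sum test.
#'
#' @param net `DataFrame` from [netEnhancerChange()].
#' @param geneLfc named numeric vector of gene log2 fold changes (names =
#'   gene ids).
#' @return list with `summary` (per-bin n, median, q25, q75), `H`, `p`.
#' @export
binExpressionShift <- function(net, geneLfc) {
  lfc <- geneLfc[net$geneId]
  ok <- !is.na(lfc)
  bin <- net$bin[ok]
  lfc <- lfc[ok]
  if (length(unique(bin)) < 2L) stop("need at least 2 non-empty bins")
  f <- factor(bin, levels = sort(unique(bin)))
  if (length(unique(lfc)) == 1L) {
    kw <- list(statistic = c(H = 0), p.value = 1)   # all ranks tied
  } else {
    kw <- stats::kruskal.test(lfc, f)
  }
  summ <- do.call(rbind, lapply(levels(f), function(b) {
    x <- lfc[f == b]
    data.frame(bin = as.integer(b), n = length(x), median = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)))
  }))
  list(summary = summ, H = unname(kw$statistic), p = kw$p.value)
}

#' Gene-set overlap tests
#'
#' Upper-tail hypergeometric probability `P[X >= k]` of observing the overlap
#' `k` between two gene sets drawn from a common universe, plus Fisher's
#' two-sided exact p on the corresponding 2x2 table.
#'
#' @param setA,setB character vectors of ids, subsets of `universe`.
#' @param universe character vector of all ids.
#' @return list with `N`, `sizeA`, `sizeB`, `overlap`, `pHyper`, `pFisher`.
#' @export
overlapTest <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  N <- length(universe)
  k <- length(intersect(setA, setB))
  a <- length(setA); b <- length(setB)
  pHyper <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  tab <- matrix(c(k, a - k, b - k, N - a - b + k), nrow = 2)
  pFisher <- stats::fisher.test(tab)$p.value
  list(N = N, sizeA = a, sizeB = b, overlap = k,
       pHyper = pHyper, pFisher = pFisher)
}

#' Stratify samples by outlier-high expression of one gene
#'
#' A sample is called "high" for a gene when its expression exceeds the
#' cohort median plus two population standard deviations — the rule used to
#' call amplified-like outliers (e.g. ERBB2-amplified tumours) from
#' expression alone.
#'
#' @param expr gene x sample matrix.
#' @param gene gene id (row of `expr`).
#' @return logical vector per sample (`TRUE` = high).
#' @export
stratifyByGene <- function(expr, gene) {
  if (!gene %in% rownames(expr)) stop("gene not found in expression matrix")
  x <- as.numeric(expr[gene, ])
  sdPop <- sqrt(mean((x - mean(x))^2))
  stats::setNames(x > stats::median(x) + 2 * sdPop, colnames(expr))
}
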