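## Independent brute-force oracles, deliberately naive: per-base coverage
## scans and all-pairs loops, kept free of the package's interval code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## GRanges from 0-based half-open triples
gr0 <- function(chrom, start0, end0, strand = "*", seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqlengths(gr) <- unname(seqlen)
  }
  gr
}

## per-base exclusion oracle: boolean coverage vector per chromosome
oracleZoneCover <- function(genes0, chromLen, upstream, downstream) {
  cover <- lapply(chromLen, function(L) logical(L))
  for (i in seq_len(nrow(genes0))) {
    g <- genes0[i, ]
    if (g$strand == "-") { up <- downstream; dn <- upstream }
    else { up <- upstream; dn <- downstream }
    a <- max(0, g$start - up)
    b <- min(chromLen[[g$chrom]], g$end + dn)
    if (b > a) cover[[g$chrom]][(a + 1):b] <- TRUE
  }
  cover
}

coverToRanges0 <- function(coverVec) {
  r <- rle(coverVec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

## does interval [s0, e0) touch any covered base?
oracleOverlapsCover <- function(cover, chrom, s0, e0) {
  any(cover[[chrom]][(s0 + 1):e0])
}

## brute-force nearest gene by scanning every gene
oracleNearest <- function(centre0, chrom, genes0) {
  cand <- genes0[genes0$chrom == chrom, ]
  if (nrow(cand) == 0) return(list(gene = NA, dist = NA))
  tss <- ifelse(cand$strand == "-", cand$end - 1, cand$start)
  d <- tss - centre0
  best <- which(abs(d) == min(abs(d)))
  best <- best[order(cand$gene_id[best])][1]
  list(gene = cand$gene_id[best], dist = d[best])
}

## brute-force BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(1, p[o[i]] * m / i, prev)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

## exact hypergeometric upper tail by enumeration over the support
oracleHyperUpper <- function(N, a, b, k) {
  i <- max(k, 0):min(a, b)
  sum(choose(a, i) * choose(N - a, b - i)) / choose(N, b)
}

## random toy genome as plain data frames (for oracle-equivalence tests)
randomGenomeTables <- function(seed, nGenes = 20, nPeaks = 60, L = 50000) {
  set.seed(seed)
  chroms <- c(chrA = L, chrB = L)
  genes <- data.frame(
    chrom = sample(names(chroms), nGenes, replace = TRUE),
    start = sample(0:(L - 600), nGenes),
    gene_id = sprintf("g%03d", sample(999, nGenes)),
    strand = sample(c("+", "-"), nGenes, replace = TRUE))
  genes$end <- genes$start + sample(100:500, nGenes, replace = TRUE)
  peaks <- data.frame(
    chrom = sample(names(chroms), nPeaks, replace = TRUE),
    start = sample(0:(L - 400), nPeaks, replace = TRUE))
  peaks$end <- peaks$start + sample(50:350, nPeaks, replace = TRUE)
  list(genes = genes, peaks = peaks, chroms = chroms)
}

## small helper: ErnaExperiment straight from matrices
toyExperiment <- function(counts, plus = NULL, lib = NULL, chrom = "chr1") {
  n <- nrow(counts)
  regions <- GRanges(chrom, IRanges(seq_len(n) * 1000, width = 100))
  names(regions) <- rownames(counts) <- paste0("r", seq_len(n))
  if (is.null(lib)) lib <- rep(1e6, ncol(counts))
  if (is.null(plus)) plus <- counts
  ErnaExperiment(regions, counts, plus, counts - plus, lib)
}
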