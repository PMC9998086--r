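test_that("GTF genes are read with the 1-based inclusive convention and collapsed per gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\ttranscript\t101\t200\t.\t-\t.\tgene_id "gB";',
    'chr1\tsrc\ttranscript\t151\t400\t.\t-\t.\tgene_id "gB";'), gtf)
  ann <- readGeneAnnotation(gtf, chromSizes = c(chr1 = 30000))
  expect_setequal(ann$gene_id, c("gA", "gB"))
  ## gene rows present -> only gene rows used; 10001..20000 is [10000, 20000)
  expect_equal(start(ann[ann$gene_id == "gA"]), 10001)
  expect_equal(end(ann[ann$gene_id == "gA"]), 20000)

  ## transcript-only file: union of 100..200 and 150..400 -> (99, 400)
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t100\t200\t.\t-\t.\tgene_id "gB";',
    'chr1\tsrc\ttranscript\t150\t400\t.\t-\t.\tgene_id "gB";'), gtf2)
  ann2 <- readGeneAnnotation(gtf2)
  expect_equal(start(ann2), 100)
  expect_equal(end(ann2), 400)
  expect_equal(as.character(strand(ann2)), "-")
})

test_that("annotation reader errors are informative", {
  empty <- tempfile(fileext = ".gtf")
  file.create(empty)
  expect_length(readGeneAnnotation(empty), 0)

  bad <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tsrc\tgene\t1\t10\t.\t+\t.\tgene_id "g";',
               "chr1\tonly-three-fields"), bad)
  expect_error(readGeneAnnotation(bad), "line 2")

  gtf <- tempfile(fileext = ".gtf")
  writeLines('chrUn\tsrc\tgene\t1\t10\t.\t+\t.\tgene_id "g";', gtf)
  expect_error(readGeneAnnotation(gtf, chromSizes = c(chr1 = 100)), "chrUn")
})

test_that("exclusion zones follow strand-aware flank arithmetic and clip to the chromosome", {
  sizes <- c(chr1 = 1e6)
  plus <- gr0("chr1", 9999, 20000, "+", sizes)
  expect_equal(buildExclusionZones(plus), gr0("chr1", 7999, 20500, seqlen = sizes),
               ignore_attr = TRUE)
  minus <- gr0("chr1", 9999, 20000, "-", sizes)
  expect_equal(buildExclusionZones(minus), gr0("chr1", 9499, 22000, seqlen = sizes),
               ignore_attr = TRUE)
  small <- gr0("chr1", 500, 1000, "+", c(chr1 = 1200))
  z <- buildExclusionZones(small)
  expect_equal(start(z), 1)
  expect_equal(end(z), 1200)
})

test_that("exclusion zones cover every gene-body base (per-base oracle)", {
  for (seed in 1:5) {
    tabs <- randomGenomeTables(seed)
    genes <- gr0(tabs$genes$chrom, tabs$genes$start, tabs$genes$end,
                 tabs$genes$strand, tabs$chroms)
    zones <- buildExclusionZones(genes)
    cover <- oracleZoneCover(tabs$genes, as.list(tabs$chroms), 2000, 500)
    for (chr in names(tabs$chroms)) {
      got <- zones[seqnames(zones) == chr]
      want <- coverToRanges0(cover[[chr]])
      expect_equal(start(got) - 1, want$start)
      expect_equal(end(got), want$end)
    }
  }
})

test_that("intergenic filter drops whole peaks on any overlap", {
  zone <- gr0("chr1", 7999, 20500)
  keepPeak <- gr0("chr1", 30000, 30500)
  expect_length(filterIntergenicPeaks(keepPeak, zone), 1)
  onebp <- gr0("chr1", 20400, 20900)   # overlaps the zone by 100 bp
  expect_length(filterIntergenicPeaks(onebp, zone), 0)
  expect_length(filterIntergenicPeaks(GRanges(), zone), 0)
  unmerged <- c(gr0("chr1", 0, 100), gr0("chr1", 50, 150))
  expect_error(filterIntergenicPeaks(keepPeak, unmerged), "merged")
})

test_that("intergenic filter is identity on empty exclusion and anti-monotone", {
  set.seed(41)
  tabs <- randomGenomeTables(41)
  peaks <- gr0(tabs$peaks$chrom, tabs$peaks$start, tabs$peaks$end)
  expect_equal(filterIntergenicPeaks(peaks, GRanges()), peaks)
  genes <- gr0(tabs$genes$chrom, tabs$genes$start, tabs$genes$end,
               tabs$genes$strand, tabs$chroms)
  zSmall <- buildExclusionZones(genes[1:5])
  zBig <- buildExclusionZones(genes)
  keptSmall <- filterIntergenicPeaks(peaks, zSmall)
  keptBig <- filterIntergenicPeaks(peaks, zBig)
  expect_true(all(GenomicRanges::countOverlaps(keptBig, keptSmall,
                                               type = "equal") >= 1))
})

test_that("union merging follows the centre-distance-or-overlap fixpoint rule", {
  a <- gr0("chr1", 900, 1100)
  b <- gr0("chr1", 1100, 1300)   # centres 1000 and 1200: within 250
  m <- mergePeakSets(list(a, b))
  expect_equal(m, gr0("chr1", 900, 1300), ignore_attr = TRUE)

  c2 <- gr0("chr1", 1200, 1400)  # centres 1000 and 1300: 300 > 250, disjoint
  m2 <- mergePeakSets(list(a, c2))
  expect_length(m2, 2)
  expect_equal(start(m2), c(901, 1201))

  ## idempotence and order independence
  set.seed(7)
  tabs <- randomGenomeTables(7, nPeaks = 80)
  sets <- split(gr0(tabs$peaks$chrom, tabs$peaks$start, tabs$peaks$end),
                rep(1:4, length.out = 80))
  m1 <- mergePeakSets(sets)
  expect_equal(mergePeakSets(list(m1)), m1)
  m3 <- mergePeakSets(rev(sets))
  expect_equal(m1, m3)
})

test_that("no pair in a merged set still satisfies the merge criterion", {
  for (seed in 8:12) {
    tabs <- randomGenomeTables(seed, nPeaks = 100)
    m <- mergePeakSets(gr0(tabs$peaks$chrom, tabs$peaks$start, tabs$peaks$end))
    expect_true(GenomicRanges::isDisjoint(m))
    cen <- (start(m) - 1 + end(m)) %/% 2
    sameChr <- as.character(seqnames(m))[-1] == as.character(seqnames(m))[-length(m)]
    expect_true(all(!sameChr | diff(cen) > 250))
  }
})

test_that("chrom sizes and BED round-trip through the readers", {
  f <- tempfile()
  writeLines(c("chr1\t1000", "chr2\t2000"), f)
  expect_equal(readChromSizes(f), c(chr1 = 1000L, chr2 = 2000L))
  bed <- tempfile(fileext = ".bed")
  gr <- gr0("chr1", c(100, 500), c(200, 900))
  writeBed(gr, bed)
  back <- readBed(bed)
  expect_equal(granges(back), gr, ignore_attr = TRUE)
})
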