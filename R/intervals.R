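#' @importFrom GenomicRanges GRanges granges reduce seqnames start end width
#'   strand countOverlaps findOverlaps gaps sort.GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#'   seqlevels<-
NULL

## 0-based region centre: floor((start0 + end0) / 2). All user-facing objects
## are 1-based GRanges; candidates/fragments keep the BED half-open arithmetic
## through this helper.
.centre0 <- function(gr) (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L

## 0-based strand-aware TSS position (minus-strand TSS = last base of the gene)
.tss0 <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  ifelse(s == "-", GenomicRanges::end(gr) - 1L, GenomicRanges::start(gr) - 1L)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file with columns chromosome name and length (bp).
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(as.integer(tab$size), tab$chrom)
}

#' Read a gene annotation from GTF
#'
#' Rows of feature type `gene` are used directly; if absent, all rows sharing
#' a `gene_id` are collapsed to the union extent of their features. GTF
#' coordinates (1-based, inclusive) are kept in the usual Bioconductor
#' representation; BED-style half-open arithmetic is applied internally where
#' the region grammar requires it.
#'
#' @param path GTF file.
#' @param chromSizes optional named vector of chromosome lengths
#'   (see [readChromSizes()]). When supplied, genes on chromosomes absent from
#'   it raise an error and gene extents are checked against the lengths.
#' @return `GRanges` with one range per gene and a `gene_id` metadata column.
#' @export
readGeneAnnotation <- function(path, chromSizes = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  if (any(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf < 9))
      stop("malformed GTF row at line ", which(body)[nf < 9][1],
           ": expected 9 tab-separated fields")
  }
  if (!any(body)) {
    gr <- GRanges()
    gr$gene_id <- character()
  } else {
    raw <- rtracklayer::import(path, format = "gtf")
    if (is.null(raw$gene_id) || anyNA(raw$gene_id))
      stop("GTF rows must carry a gene_id attribute")
    ## gene extent = union of all its feature rows (gene rows, if present,
    ## already span their transcripts)
    ext <- range(S4Vectors::split(granges(raw), raw$gene_id),
                 ignore.strand = FALSE)
    if (any(lengths(ext) != 1L))
      stop("gene(s) with features on multiple strands/chromosomes: ",
           paste(names(ext)[lengths(ext) != 1L], collapse = ", "))
    gr <- unlist(ext, use.names = TRUE)
    gr$gene_id <- names(gr)
    gr <- unname(sort(gr, ignore.strand = TRUE))
  }
  if (anyDuplicated(gr$gene_id)) stop("duplicate gene_id in annotation")
  if (!is.null(chromSizes)) {
    bad <- setdiff(as.character(seqnames(gr)), names(chromSizes))
    if (length(bad))
      stop("gene(s) on chromosome(s) missing from chrom sizes: ",
           paste(bad, collapse = ", "))
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- unname(chromSizes)
    if (any(end(gr) > seqlengths(gr)[as.character(seqnames(gr))]))
      stop("gene extends beyond its chromosome length")
  }
  names(gr) <- gr$gene_id
  gr
}

#' Build strand-aware exclusion zones around genes
#'
#' Expands each gene body upstream of its TSS and downstream of its TTS
#' (strand-aware: for minus-strand genes the TSS is the higher coordinate),
#' clips to chromosome bounds, and merges overlaps. The complement of the
#' result is the "truncated genome" within which intergenic eRNA candidates
#' are sought; the flanks avoid promoter signal and transcriptional
#' read-through respectively.
#'
#' @param genes `GRanges` of gene extents (strand set; see
#'   [readGeneAnnotation()]).
#' @param upstream bp excluded upstream of the TSS (default 2000).
#' @param downstream bp excluded downstream of the TTS (default 500).
#' @return merged, unstranded `GRanges` of exclusion zones.
#' @export
buildExclusionZones <- function(genes, upstream = 2000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (length(genes) == 0L) return(granges(genes))
  minus <- as.character(strand(genes)) == "-"
  up <- ifelse(minus, downstream, upstream)
  dn <- ifelse(minus, upstream, downstream)
  newStart <- pmax(1L, start(genes) - as.integer(up))
  newEnd <- end(genes) + as.integer(dn)
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  newEnd <- ifelse(is.na(sl), newEnd, pmin(newEnd, sl))
  zones <- GRanges(seqnames(genes), IRanges(newStart, newEnd),
                   seqinfo = seqinfo(genes))
  GenomicRanges::reduce(sort(zones), min.gapwidth = 0L)
}

## a merged RegionSet is sorted and pairwise non-overlapping
.checkMerged <- function(gr, what = "region set") {
  if (GenomicRanges::isDisjoint(gr, ignore.strand = TRUE) &&
      !S4Vectors::is.unsorted(gr, ignore.strand = TRUE)) return(invisible(TRUE))
  stop(what, " must be merged (sorted and non-overlapping); ",
       "see mergePeakSets()/buildExclusionZones()")
}

#' Retain only peaks fully outside the exclusion zones
#'
#' A peak overlapping any exclusion zone by even one base is dropped whole
#' (regions are classified, not trimmed), leaving the intergenic peaks that
#' are at least the upstream flank away from any TSS and the downstream flank
#' beyond any TTS.
#'
#' @param peaks `GRanges` of peaks.
#' @param exclusion merged `GRanges` from [buildExclusionZones()].
#' @return the retained subset of `peaks`.
#' @export
filterIntergenicPeaks <- function(peaks, exclusion) {
  .checkMerged(exclusion, "exclusion set")
  peaks[countOverlaps(peaks, exclusion, ignore.strand = TRUE) == 0L]
}

#' Merge peak sets into a union peak set
#'
#' Pools all peaks and repeatedly merges any two same-chromosome peaks that
#' overlap or whose centres (floor of the half-open midpoint) lie within
#' `mergeDistance` bp, replacing them by their spanning interval, until a
#' fixpoint is reached.
#'
#' @param peakSets a `GRanges`, `GRangesList` or list of `GRanges`.
#' @param mergeDistance maximum centre-to-centre distance merged (default 250).
#' @return merged, unstranded, sorted `GRanges`.
#' @export
mergePeakSets <- function(peakSets, mergeDistance = 250) {
  stopifnot(mergeDistance >= 0)
  if (inherits(peakSets, "GRanges")) peakSets <- list(peakSets)
  pool <- unlist(GenomicRanges::GRangesList(lapply(as.list(peakSets), granges)),
                 use.names = FALSE)
  strand(pool) <- "*"
  repeat {
    pool <- GenomicRanges::reduce(sort(pool, ignore.strand = TRUE),
                                  min.gapwidth = 0L)
    n <- length(pool)
    if (n < 2L) break
    cen <- .centre0(pool)
    chr <- as.character(seqnames(pool))
    close <- chr[-1] == chr[-n] & (cen[-1] - cen[-n]) <= mergeDistance
    if (!any(close)) break
    grp <- cumsum(c(TRUE, !close))
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    pool <- GRanges(seqnames(pool)[first],
                    IRanges(start(pool)[first], end(pool)[last]),
                    seqinfo = seqinfo(pool))
  }
  pool
}

#' Read a BED file of intervals
#'
#' @param path BED3/BED6 file (0-based half-open on disk).
#' @return `GRanges` (1-based in memory; strand from column 6 when present).
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) return(GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Write intervals to BED
#'
#' @param gr `GRanges` to write (emitted 0-based half-open).
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
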