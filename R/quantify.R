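#' Read a BED6 file of stranded RNA fragments
#'
#' The library size of a fragment set read from BED is, by definition, the
#' number of fragments in the file; it is attached as the `librarySize`
#' attribute and consumed by [quantifyRegions()].
#'
#' @param path BED6 file; strand in column 6.
#' @return `GRanges` of fragments with a `librarySize` attribute.
#' @export
readFragmentsBed <- function(path) {
  fr <- readBed(path)
  attr(fr, "librarySize") <- length(fr)
  fr
}

#' Count fragments in candidate regions by midpoint assignment
#'
#' Each fragment is assigned to the unique region containing its midpoint
#' (floor of the half-open midpoint); fragments whose midpoint falls in no
#' region are left uncounted, so no fragment is ever counted twice. Strand
#' tallies follow the fragment's strand.
#'
#' @param regions non-overlapping `GRanges` of candidate regions.
#' @param fragments stranded `GRanges` of fragments.
#' @return list with integer vectors `total`, `plus`, `minus` (one entry per
#'   region).
#' @export
countFragments <- function(regions, fragments) {
  if (!GenomicRanges::isDisjoint(regions, ignore.strand = TRUE))
    stop("regions overlap: fragment assignment would be ambiguous; ",
         "merge them first (mergePeakSets)")
  n <- length(regions)
  if (length(fragments) == 0L)
    return(list(total = integer(n), plus = integer(n), minus = integer(n)))
  mids <- GRanges(seqnames(fragments), IRanges(.centre0(fragments) + 1L, width = 1L))
  hits <- findOverlaps(mids, regions, ignore.strand = TRUE)
  isPlus <- as.character(strand(fragments))[S4Vectors::queryHits(hits)] != "-"
  reg <- S4Vectors::subjectHits(hits)
  plus <- tabulate(reg[isPlus], nbins = n)
  minus <- tabulate(reg[!isPlus], nbins = n)
  list(total = plus + minus, plus = plus, minus = minus)
}

#' Quantify stranded fragments over regions for a set of samples
#'
#' @param regions non-overlapping `GRanges` of candidate regions.
#' @param fragmentSets named list of fragment `GRanges` (one per sample), e.g.
#'   from [readFragmentsBed()].
#' @param librarySizes optional per-sample library sizes; defaults to the
#'   `librarySize` attribute of each fragment set, falling back to the
#'   fragment count.
#' @param colData optional per-sample annotation.
#' @return an [ErnaExperiment-class].
#' @export
quantifyRegions <- function(regions, fragmentSets, librarySizes = NULL,
                            colData = NULL) {
  if (is.null(names(fragmentSets)))
    names(fragmentSets) <- paste0("sample_", seq_along(fragmentSets))
  tallies <- lapply(fragmentSets, countFragments, regions = regions)
  cts <- vapply(tallies, `[[`, integer(length(regions)), "total")
  pl <- vapply(tallies, `[[`, integer(length(regions)), "plus")
  mi <- vapply(tallies, `[[`, integer(length(regions)), "minus")
  if (length(regions) == 1L) {
    cts <- matrix(cts, nrow = 1, dimnames = list(NULL, names(fragmentSets)))
    pl <- matrix(pl, nrow = 1, dimnames = dimnames(cts))
    mi <- matrix(mi, nrow = 1, dimnames = dimnames(cts))
  }
  if (is.null(librarySizes))
    librarySizes <- vapply(fragmentSets, function(f) {
      ls <- attr(f, "librarySize")
      if (is.null(ls)) length(f) else ls
    }, numeric(1))
  ErnaExperiment(regions, cts, pl, mi, librarySizes, colData = colData)
}

#' Fragments per million
#'
#' `fpm_ij = counts_ij * 1e6 / librarySize_j`, the plain library-size scaling
#' used by the candidate filter. (A size-factor-robust alternative is
#' available via [estimateSizeFactors()] for the differential test.)
#'
#' @param object an [ErnaExperiment-class], or a counts matrix.
#' @param librarySizes required when `object` is a matrix.
#' @return numeric matrix of FPM values.
#' @export
fpm <- function(object, librarySizes = NULL) {
  if (is(object, "ErnaExperiment")) {
    librarySizes <- libSizes(object)
    object <- regionCounts(object)
  }
  if (is.null(librarySizes)) stop("librarySizes required for matrix input")
  if (any(librarySizes <= 0) || anyNA(librarySizes))
    stop("library sizes must be strictly positive")
  sweep(as.matrix(object), 2L, librarySizes / 1e6, "/")
}

#' Candidate-region filter mask
#'
#' A region passes when its mean raw count over all samples (both cohorts
#' pooled) is at least `minMeanCount` and its mean FPM is at least
#' `minMeanFpm`.
#'
#' @param object an [ErnaExperiment-class].
#' @param minMeanCount mean raw-count threshold (default 3).
#' @param minMeanFpm mean FPM threshold (default 1.5).
#' @return logical vector, one entry per region.
#' @export
candidateMask <- function(object, minMeanCount = 3, minMeanFpm = 1.5) {
  stopifnot(minMeanCount >= 0, minMeanFpm >= 0)
  rowMeans(regionCounts(object)) >= minMeanCount &
    rowMeans(fpm(object)) >= minMeanFpm
}

#' Filter candidate eRNA regions by mean count and mean FPM
#'
#' @inheritParams candidateMask
#' @return the filtered [ErnaExperiment-class]; the logical mask over the
#'   input regions is stored in `metadata(.)$candidateMask`.
#' @export
filterCandidates <- function(object, minMeanCount = 3, minMeanFpm = 1.5) {
  mask <- candidateMask(object, minMeanCount, minMeanFpm)
  out <- object[mask, ]
  S4Vectors::metadata(out)$candidateMask <- mask
  out
}

#' Transcriptional directionality score
#'
#' `log10((plus + 1) / (minus + 1)) + 1`. A score of 1 indicates perfectly
#' balanced bidirectional transcription (the eRNA-like signature); scores far
#' from 1 indicate strand-biased, promoter-like transcription.
#'
#' @param plus,minus non-negative per-strand expression scores (vectorised).
#' @return numeric score(s).
#' @export
directionalityScore <- function(plus, minus) {
  if (any(plus < 0) || any(minus < 0) || anyNA(plus) || anyNA(minus))
    stop("strand expression scores must be non-negative")
  log10((plus + 1) / (minus + 1)) + 1
}

#' Per-region directionality scores from an ErnaExperiment
#'
#' The per-strand expression score is the strand-specific fragment count
#' summed over samples; with `normalized = TRUE` (default) each sample is
#' first scaled to fragments per million so deep samples do not dominate.
#'
#' @param object an [ErnaExperiment-class].
#' @param normalized scale each sample per million before summing?
#' @return numeric vector of directionality scores, one per region.
#' @export
regionDirectionality <- function(object, normalized = TRUE) {
  pl <- plusCounts(object)
  mi <- minusCounts(object)
  if (normalized) {
    sc <- libSizes(object) / 1e6
    pl <- sweep(pl, 2L, sc, "/")
    mi <- sweep(mi, 2L, sc, "/")
  }
  stats::setNames(directionalityScore(rowSums(pl), rowSums(mi)),
                  rownames(object))
}
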