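#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' ErnaExperiment: stranded fragment counts over candidate eRNA regions
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment] with three
#' assays — `counts`, `plus` and `minus` — holding total and per-strand
#' fragment counts for each candidate region (rows) in each RNA-seq sample
#' (columns), plus a mandatory `librarySize` column in `colData` giving the
#' total number of fragments per sample (the FPM denominator).
#'
#' The class invariant is `counts == plus + minus` elementwise, with all
#' entries non-negative and all library sizes strictly positive.
#'
#' @seealso [ErnaExperiment()], [quantifyRegions()], [fpm()],
#'   [regionDirectionality()]
#' @export
setClass("ErnaExperiment", contains = "RangedSummarizedExperiment")

setValidity("ErnaExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "plus", "minus") %in% an))
    msg <- c(msg, "assays 'counts', 'plus' and 'minus' are required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    pl <- SummarizedExperiment::assay(object, "plus")
    mi <- SummarizedExperiment::assay(object, "minus")
    if (any(cts < 0) || any(pl < 0) || any(mi < 0))
      msg <- c(msg, "counts must be non-negative")
    if (!isTRUE(all(cts == pl + mi)))
      msg <- c(msg, "'counts' must equal 'plus' + 'minus' elementwise")
  }
  if (!"librarySize" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'librarySize' column")
  else if (any(object$librarySize <= 0) || anyNA(object$librarySize))
    msg <- c(msg, "library sizes must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ErnaExperiment
#'
#' @param regions `GRanges` of candidate regions (non-overlapping); names or a
#'   `name` metadata column provide region ids.
#' @param counts,plus,minus integer matrices region x sample. If `plus`/`minus`
#'   are omitted the total is attributed to the plus strand (only sensible for
#'   unstranded input; directionality is then meaningless).
#' @param librarySizes numeric vector of per-sample total fragment counts.
#' @param colData optional extra per-sample annotation (e.g. cohort).
#' @return An [ErnaExperiment-class] object.
#' @export
ErnaExperiment <- function(regions, counts, plus = NULL, minus = NULL,
                           librarySizes, colData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(plus)) plus <- counts
  if (is.null(minus)) minus <- counts - plus
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  dimnames(plus) <- dimnames(minus) <- dimnames(counts)
  cd <- S4Vectors::DataFrame(librarySize = as.numeric(librarySizes),
                             row.names = colnames(counts))
  if (!is.null(colData)) cd <- cbind(cd, S4Vectors::DataFrame(colData))
  if (is.null(names(regions)) && !is.null(regions$name))
    names(regions) <- regions$name
  if (is.null(names(regions)))
    names(regions) <- paste0("region_", seq_along(regions))
  rownames(counts) <- rownames(plus) <- rownames(minus) <- names(regions)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, plus = plus, minus = minus),
    rowRanges = regions, colData = cd)
  new("ErnaExperiment", se)
}

#' @describeIn ErnaExperiment-class per-sample library sizes
#' @param object,x an `ErnaExperiment`
#' @export
libSizes <- function(object) object$librarySize

#' @describeIn ErnaExperiment-class total count matrix
#' @export
regionCounts <- function(object) SummarizedExperiment::assay(object, "counts")

#' @describeIn ErnaExperiment-class plus-strand count matrix
#' @export
plusCounts <- function(object) SummarizedExperiment::assay(object, "plus")

#' @describeIn ErnaExperiment-class minus-strand count matrix
#' @export
minusCounts <- function(object) SummarizedExperiment::assay(object, "minus")

#' @export
setMethod("show", "ErnaExperiment", function(object) {
  cat("ErnaExperiment:", nrow(object), "regions x", ncol(object), "samples\n")
  cat("  median library size:",
      format(stats::median(libSizes(object)), big.mark = ","), "fragments\n")
  callNextMethod()
})

#' CoxRiskModel: a Cox risk-score survival signature
#'
#' Holds the gene ids and multivariate Cox coefficients of a risk-score
#' signature (risk score = sum over signature genes of expression x beta),
#' together with the training-set median risk score used to split samples
#' into high- and low-risk groups.
#'
#' @seealso [buildRiskModel()], [riskScores()], [riskGroups()]
#' @export
setClass("CoxRiskModel",
         representation(geneIds = "character", beta = "numeric",
                        threshold = "numeric", fit = "ANY"))

setValidity("CoxRiskModel", function(object) {
  if (length(object@geneIds) != length(object@beta))
    return("geneIds and beta must have equal length")
  if (anyNA(object@beta)) return("beta must be finite")
  TRUE
})

#' @describeIn CoxRiskModel-class signature gene identifiers
#' @param object a `CoxRiskModel`
#' @export
signatureGenes <- function(object) object@geneIds

#' @describeIn CoxRiskModel-class Cox coefficients of the signature
#' @export
signatureBeta <- function(object) stats::setNames(object@beta, object@geneIds)

#' @export
setMethod("show", "CoxRiskModel", function(object) {
  cat("CoxRiskModel with", length(object@geneIds), "genes\n")
  print(round(signatureBeta(object), 4))
  cat("median-risk threshold:", format(object@threshold, digits = 4), "\n")
})

#' ClusteringResult: correlation-based hierarchical clustering of samples
#'
#' @slot tree the `hclust` tree (average linkage on 1 - Pearson r by default)
#' @slot labels integer cluster label per sample (cut at `k`)
#' @slot k number of clusters
#' @slot dist the sample-sample distance matrix (as `dist`)
#' @seealso [correlationCluster()], [misclassificationCount()]
#' @export
setClass("ClusteringResult",
         representation(tree = "ANY", labels = "integer", k = "integer",
                        dist = "ANY"))

#' @describeIn ClusteringResult-class cluster labels per sample
#' @param object a `ClusteringResult`
#' @export
clusterLabels <- function(object) object@labels

#' @export
setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult:", length(object@labels), "samples cut into",
      object@k, "clusters\n")
  print(table(cluster = object@labels))
})
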