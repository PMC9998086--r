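#' Row z-score a matrix
#'
#' Each row is centred and scaled to unit sample standard deviation (n - 1
#' denominator); constant rows map to all zeros.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf   # constant rows -> 0
  (m - mu) / sd
}

#' Correlation-based hierarchical clustering of samples
#'
#' Rows (regions) are z-scored, pairwise Pearson correlation between samples
#' is computed, and samples are clustered on the distance `1 - r` by
#' agglomerative hierarchical clustering (average linkage by default), then
#' cut into `k` clusters.
#'
#' @param m region x sample expression matrix.
#' @param k number of clusters (default 2).
#' @param linkage agglomeration method.
#' @return a [ClusteringResult-class].
#' @export
correlationCluster <- function(m, k = 2,
                               linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need at least 2 samples and 2 rows")
  if (ncol(m) < k) stop("fewer samples than clusters")
  z <- zscoreRows(m)
  r <- stats::cor(z)
  if (anyNA(r)) stop("undefined sample correlation (constant sample profile)")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = linkage)
  labs <- stats::cutree(hc, k = k)
  new("ClusteringResult", tree = hc, labels = labs, k = as.integer(k), dist = d)
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (sub in .permutations(n - 1L))
      out[[length(out) + 1L]] <- c(i, rest[sub])
  }
  out
}

#' Minimum misclassification count between clusters and cohorts
#'
#' Clusters are assigned to cohorts by the bijection minimising the number of
#' samples whose cohort differs from the cohort assigned to their cluster —
#' the only label-symmetric definition of "misclassified".
#'
#' @param clusterLabels cluster assignment per sample (or a
#'   [ClusteringResult-class]).
#' @param cohortLabels known cohort per sample.
#' @return integer misclassification count.
#' @export
misclassificationCount <- function(clusterLabels, cohortLabels) {
  if (is(clusterLabels, "ClusteringResult"))
    clusterLabels <- clusterLabels(clusterLabels)
  cl <- as.factor(clusterLabels)
  co <- as.factor(cohortLabels)
  if (length(cl) != length(co)) stop("label vectors differ in length")
  if (nlevels(cl) != nlevels(co))
    stop("number of clusters (", nlevels(cl), ") must equal number of cohorts (",
         nlevels(co), ")")
  conf <- table(cl, co)
  k <- nlevels(cl)
  if (k > 8L) stop("more than 8 clusters not supported")
  best <- 0L
  for (p in .permutations(k))
    best <- max(best, sum(conf[cbind(seq_len(k), p)]))
  length(cl) - best
}
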