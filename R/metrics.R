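#' K-nearest-neighbor preservation (local structure)
#'
#' For each cell, the proportion of its K nearest neighbors in the
#' pre-embedding space (Euclidean, self excluded, distance ties broken by
#' cell index) that remain among its K nearest neighbors in the
#' 2D-embedding space; the mean over cells is returned. 1 means perfect
#' local preservation; for an embedding unrelated to the pre-embedding
#' space the expectation is K/(n - 1).
#'
#' @param pre a [PreEmbedding-class] or cells x d matrix.
#' @param emb an [Embedding2D-class] or cells x 2 matrix, row-aligned
#'   with \code{pre}.
#' @param K neighborhood size (default 10), at most n - 1.
#' @return a proportion in [0, 1].
#' @export
knnPreservation <- function(pre, emb, K = 10) {
  pre <- .coordMatrix(pre, "pre")
  emb <- .coordMatrix(emb, "emb")
  n <- nrow(pre)
  if (nrow(emb) != n) stop("'pre' and 'emb' have different cell counts")
  K <- as.integer(K)
  if (K < 1L || K > n - 1L) stop("'K' must be in [1, n - 1]")
  dPre <- as.matrix(stats::dist(pre))
  dEmb <- as.matrix(stats::dist(emb))
  mean(vapply(seq_len(n), function(i) {
    a <- .orderedFromDistRow(dPre[i, ], i, K)
    b <- .orderedFromDistRow(dEmb[i, ], i, K)
    length(intersect(a, b)) / K
  }, numeric(1)))
}

#' K-nearest-cluster preservation (global structure)
#'
#' Cluster centers are the per-dimension medians of each cluster's member
#' cells, computed separately in the pre-embedding and the 2D-embedding
#' space (medians rather than means for robustness to outliers). For each
#' cell, the proportion of the K cluster centers nearest to it in the
#' pre-embedding space (Euclidean; ties broken by cluster identifier)
#' that remain among the K nearest centers in the 2D space; the mean over
#' cells is returned.
#'
#' @inheritParams knnPreservation
#' @param labels named character vector (or factor) of cluster labels,
#'   one per cell, at least 2 distinct clusters.
#' @param K number of nearest clusters (default 4), at most the number of
#'   clusters (minus one when excluding the own cluster).
#' @param excludeOwnCluster drop each cell's own cluster from its
#'   candidate centers (default FALSE: the own center is a legitimate
#'   nearest center).
#' @return a proportion in [0, 1].
#' @export
kncPreservation <- function(pre, emb, labels, K = 4,
                            excludeOwnCluster = FALSE) {
  pre <- .coordMatrix(pre, "pre")
  emb <- .coordMatrix(emb, "emb")
  n <- nrow(pre)
  if (nrow(emb) != n) stop("'pre' and 'emb' have different cell counts")
  labels <- as.character(labels)
  if (length(labels) != n) stop("'labels' length must equal cell count")
  if (anyNA(labels)) stop("'labels' contains missing values")
  clusters <- sort(unique(labels))
  cNum <- length(clusters)
  if (cNum < 2L) stop("need at least 2 clusters")
  K <- as.integer(K)
  kmax <- if (excludeOwnCluster) cNum - 1L else cNum
  if (K < 1L || K > kmax) stop("'K' must be in [1, ", kmax, "]")

  centerOf <- function(coordsMat) {
    t(vapply(clusters, function(cl) {
      apply(coordsMat[labels == cl, , drop = FALSE], 2L, stats::median)
    }, numeric(ncol(coordsMat))))
  }
  cPre <- centerOf(pre)
  cEmb <- centerOf(emb)

  nearestClusters <- function(point, centers, drop) {
    d <- sqrt(colSums((t(centers) - point)^2))
    keep <- setdiff(seq_len(cNum), drop)
    ord <- keep[order(d[keep], clusters[keep])]
    ord[seq_len(K)]
  }
  mean(vapply(seq_len(n), function(i) {
    drop <- if (excludeOwnCluster) match(labels[i], clusters) else integer(0)
    a <- nearestClusters(pre[i, ], cPre, drop)
    b <- nearestClusters(emb[i, ], cEmb, drop)
    length(intersect(a, b)) / K
  }, numeric(1)))
}

#' Jaccard index of two identifier sets
#'
#' \code{|A intersect B| / |A union B|}, used to compare the dubious-cell
#' sets found at different similarity percents. Two empty sets have
#' Jaccard index 1 by convention (they agree exactly).
#'
#' @param a,b vectors of identifiers (duplicates ignored).
#' @return a number in [0, 1].
#' @examples
#' jaccardIndex(c("a", "b"), c("b", "c"))  # 1/3
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
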