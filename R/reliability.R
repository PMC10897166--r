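# Neighborhood size m from the similarity percent x: round(x/100 * n)
# half-up, clamped to [2, n - 1] (a Pearson correlation needs >= 2 points;
# a cell has at most n - 1 neighbors).
.mSize <- function(n, similarityPercent) {
  if (similarityPercent <= 0 || similarityPercent > 100) {
    stop("'similarityPercent' must be in (0, 100]")
  }
  m <- .roundHalfUp(similarityPercent / 100 * n)
  as.integer(min(max(m, 2L), n - 1L))
}

#' Neighborhood size used at a given similarity percent
#'
#' The number of ordered neighbors per cell, \code{round(x/100 * n)}
#' (half-up), clamped to \code{[2, n - 1]}. At the default x = 50 this is
#' the cell's closest 50\% neighboring cells.
#'
#' @param n number of cells.
#' @param similarityPercent the similarity percent x in (0, 100].
#' @return integer neighborhood size m.
#' @examples
#' neighborhoodSizeFor(100, 50)  # 50
#' neighborhoodSizeFor(7, 50)    # round(3.5) half-up = 4
#' neighborhoodSizeFor(10, 100)  # clamped to n - 1 = 9
#' @export
neighborhoodSizeFor <- function(n, similarityPercent = 50) {
  .mSize(as.integer(n), similarityPercent)
}

#' Ordered nearest neighbors of one cell
#'
#' The m nearest cells to \code{cell} by Euclidean distance in
#' \code{coords}, self excluded, ordered closest to farthest. Distance
#' ties are broken by ascending cell index so results are
#' machine-independent.
#'
#' @param coords cells x d numeric matrix (or
#'   [PreEmbedding-class]/[Embedding2D-class]).
#' @param cell index of the query cell.
#' @param m number of neighbors, in \code{[1, n - 1]}.
#' @return integer vector of m cell indices.
#' @examples
#' xy <- cbind(c(0, 1, 3, 7), 0)
#' orderedNeighbors(xy, 1, 2)  # 2, 3
#' @export
orderedNeighbors <- function(coords, cell, m) {
  coords <- .coordMatrix(coords, "coords")
  n <- nrow(coords)
  cell <- as.integer(cell)
  m <- as.integer(m)
  if (cell < 1L || cell > n) stop("'cell' out of range")
  if (m < 1L || m > n - 1L) {
    stop("'m' must be in [1, n - 1] = [1, ", n - 1L, "]")
  }
  d <- sqrt(colSums((t(coords) - coords[cell, ])^2))
  ord <- order(d, seq_len(n))
  ord <- ord[ord != cell]
  ord[seq_len(m)]
}

# Neighbor ordering from a precomputed distance row (ties by index).
.orderedFromDistRow <- function(drow, cell, m) {
  ord <- order(drow, seq_along(drow))
  ord <- ord[ord != cell]
  ord[seq_len(m)]
}

# Pearson correlation with the zero-variance degenerate case mapped to NA
# (score undefined) instead of an error or a silent zero.
.safeCor <- function(a, b) {
  if (stats::var(a) < .Machine$double.eps ||
      stats::var(b) < .Machine$double.eps) {
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Reliability score of one cell's 2D embedding
#'
#' The per-cell statistic: let A be the cell's m nearest neighbors in the
#' pre-embedding space and B its m nearest neighbors in the 2D-embedding
#' space, each ordered closest to farthest in its own space. Both distance
#' vectors are measured in the 2D-embedding space: \code{v_pre} holds the
#' 2D distances from the cell to the cells of A in A's order, \code{v_emb}
#' the 2D distances to the cells of B in B's order (non-decreasing by
#' construction). The score is the Pearson correlation of \code{v_pre}
#' and \code{v_emb}: 1 when the embedding preserves the pre-embedding
#' neighbor order up to the m-th neighbor, low or negative when mid-range
#' neighbors are scrambled. Undefined (\code{NA}) when either vector has
#' zero variance.
#'
#' @param pre a [PreEmbedding-class] (or cells x d matrix).
#' @param emb an [Embedding2D-class] (or cells x 2 matrix), row-aligned
#'   with \code{pre}.
#' @param cell index of the cell to score.
#' @param m neighborhood size (>= 2).
#' @return a number in [-1, 1], or \code{NA} when undefined.
#' @seealso [reliabilityScores()] for all cells at a similarity percent.
#' @export
reliabilityScore <- function(pre, emb, cell, m) {
  pre <- .coordMatrix(pre, "pre")
  emb <- .coordMatrix(emb, "emb")
  n <- nrow(pre)
  if (nrow(emb) != n) stop("'pre' and 'emb' have different cell counts")
  m <- as.integer(m)
  if (m < 2L || m > n - 1L) stop("'m' must be in [2, n - 1]")
  a <- orderedNeighbors(pre, cell, m)
  b <- orderedNeighbors(emb, cell, m)
  dEmb <- sqrt(colSums((t(emb) - emb[cell, ])^2))
  .safeCor(dEmb[a], dEmb[b])
}

#' Reliability scores for all cells
#'
#' Applies [reliabilityScore()] to every cell with the neighborhood size
#' implied by the similarity percent, m = round(x/100 * n) clamped to
#' [2, n - 1].
#'
#' @inheritParams reliabilityScore
#' @param similarityPercent the similarity percent x in (0, 100]
#'   (default 50, half of all cells).
#' @return named numeric vector of n scores (NA where undefined), in cell
#'   order.
#' @examples
#' sim <- simulateClusters(nCells = 60, nGenes = 40, kClusters = 3,
#'                         separation = 8, seed = 1)
#' pre <- computePCA(sim$matrix, K = 2)
#' emb <- embed2D(pre, passthroughSetting())
#' range(reliabilityScores(pre, emb))  # identity embedding: all 1
#' @export
reliabilityScores <- function(pre, emb, similarityPercent = 50) {
  pre <- .coordMatrix(pre, "pre")
  emb <- .coordMatrix(emb, "emb")
  n <- nrow(pre)
  if (nrow(emb) != n) stop("'pre' and 'emb' have different cell counts")
  if (n < 4L) stop("need at least 4 cells")
  if (!is.null(rownames(pre)) && !is.null(rownames(emb)) &&
      !identical(rownames(pre), rownames(emb))) {
    stop("'pre' and 'emb' cell identifiers are misaligned")
  }
  m <- .mSize(n, similarityPercent)
  dPre <- as.matrix(stats::dist(pre))
  dEmb <- as.matrix(stats::dist(emb))
  out <- vapply(seq_len(n), function(i) {
    a <- .orderedFromDistRow(dPre[i, ], i, m)
    b <- .orderedFromDistRow(dEmb[i, ], i, m)
    .safeCor(dEmb[i, a], dEmb[i, b])
  }, numeric(1))
  names(out) <- rownames(pre)
  out
}

#' Null reliability scores from the gene-permutation pipeline
#'
#' Runs the full null pipeline on an expression matrix: permute every
#' gene independently across cells ([permuteGenes()]), rebuild the
#' pre-embedding space on the permuted matrix (an independent PCA fit
#' when \code{numPCs} is given, never reusing the original loadings;
#' otherwise the permuted features directly), embed it with the same
#' setting and embedding seed as the original data, and score every cell.
#' Because the permutation destroys all cell-cell structure, these n
#' scores form the null distribution of the reliability score under
#' random neighbor assignment.
#'
#' @param x numeric genes x cells matrix (or SummarizedExperiment).
#' @param setting the [HyperparamSetting-class] under evaluation.
#' @param numPCs number of principal components for the pre-embedding
#'   space, or \code{NULL} to use the (permuted) features directly.
#' @param similarityPercent similarity percent x (default 50).
#' @param embedSeed seed for the embedder (default 100; must equal the
#'   seed used for the original embedding).
#' @param permuteSeed seed for the gene permutation (default 100).
#' @param center,scale PCA options, as in [computePCA()].
#' @return named numeric vector of n null scores.
#' @export
nullReliabilityScores <- function(x, setting, numPCs = NULL,
                                  similarityPercent = 50, embedSeed = 100,
                                  permuteSeed = 100, center = TRUE,
                                  scale = FALSE) {
  x <- .asGeneCellMatrix(x)
  perm <- permuteGenes(x, permuteSeed = permuteSeed)
  preNull <- if (is.null(numPCs)) {
    preEmbedding(t(perm))
  } else {
    computePCA(perm, K = numPCs, center = center, scale = scale)
  }
  embNull <- embed2D(preNull, setting, seed = embedSeed)
  reliabilityScores(preNull, embNull, similarityPercent)
}

#' Classify cells as dubious or trustworthy against the permutation null
#'
#' Computes the two cutoffs as empirical percentiles of the null scores
#' (by default the 5th and 95th, with linear interpolation between order
#' statistics) and labels every cell: \code{"dubious"} when its score is
#' at or below the dubious cutoff, \code{"trustworthy"} at or above the
#' trustworthy cutoff, \code{"undefined"} when the score is \code{NA},
#' and \code{"intermediate"} otherwise. Undefined null scores are dropped
#' before taking percentiles (with a message reporting the count). Note
#' the fractions labeled dubious/trustworthy are not pinned to 5\%: the
#' cutoffs come from the null distribution, not from the observed scores.
#'
#' @param scores per-cell reliability scores (NA allowed).
#' @param nullScores null reliability scores (NA allowed; must not all be
#'   NA).
#' @param dubiousPercentile,trustworthyPercentile null percentiles in
#'   (0, 100) with \code{dubiousPercentile < trustworthyPercentile}
#'   (defaults 5 and 95).
#' @param quantileType \code{"interpolation"} (linear interpolation
#'   between order statistics, the common default; type 7) or
#'   \code{"nearest_rank"} (type 1).
#' @param neighborhoodSize the m the scores were computed with (recorded
#'   in the result; inferred as NA when not supplied).
#' @param metadata optional list stored in the result.
#' @return an [EmbeddingReliability-class].
#' @examples
#' null <- seq(0.1, 1, by = 0.1)
#' r <- classifyCells(c(0.10, 0.50, 0.96), null)
#' cutoffs(r)     # 0.145, 0.955
#' cellLabels(r)  # dubious, intermediate, trustworthy
#' @export
classifyCells <- function(scores, nullScores, dubiousPercentile = 5,
                          trustworthyPercentile = 95,
                          quantileType = c("interpolation", "nearest_rank"),
                          neighborhoodSize = NA_integer_,
                          metadata = list()) {
  quantileType <- match.arg(quantileType)
  if (dubiousPercentile <= 0 || trustworthyPercentile >= 100 ||
      dubiousPercentile >= trustworthyPercentile) {
    stop("percentiles must satisfy 0 < dubious < trustworthy < 100")
  }
  nullOk <- nullScores[!is.na(nullScores)]
  if (!length(nullOk)) stop("all null reliability scores are undefined")
  nDropped <- length(nullScores) - length(nullOk)
  if (nDropped > 0L) {
    message(nDropped, " undefined null score(s) dropped before percentiles")
  }
  type <- if (quantileType == "interpolation") 7L else 1L
  qs <- stats::quantile(nullOk,
                        c(dubiousPercentile, trustworthyPercentile) / 100,
                        type = type, names = FALSE)
  labels <- ifelse(is.na(scores), "undefined",
            ifelse(scores <= qs[1L], "dubious",
            ifelse(scores >= qs[2L], "trustworthy", "intermediate")))
  if (is.null(names(scores))) {
    names(scores) <- paste0("cell", seq_along(scores))
  }
  names(labels) <- names(scores)
  methods::new("EmbeddingReliability",
               scores = scores, nullScores = as.numeric(nullScores),
               dubiousCutoff = qs[1L], trustworthyCutoff = qs[2L],
               labels = labels,
               neighborhoodSize = as.integer(neighborhoodSize),
               metadata = metadata)
}

#' Score a 2D embedding of an expression matrix against its permutation
#' null
#'
#' The end-to-end diagnostic for one hyperparameter setting: build the
#' pre-embedding space (top-\code{numPCs} PCA scores, or the features as
#' given), embed it in 2D under \code{setting} and \code{embedSeed},
#' score every cell's preservation of its ordered mid-range neighborhood,
#' run the identical pipeline on the gene-permuted matrix to obtain the
#' null scores, and classify each cell's embedding as dubious,
#' trustworthy or intermediate.
#'
#' @inheritParams nullReliabilityScores
#' @param preCoords optional user-supplied cells x d pre-embedding matrix
#'   (e.g. independent components or CyTOF markers). When given together
#'   with \code{x}, it replaces the PCA step for the original data while
#'   the null pipeline still permutes \code{x}; when given alone, the
#'   transposed coordinates serve as the feature matrix to permute.
#' @param dubiousPercentile,trustworthyPercentile,quantileType passed to
#'   [classifyCells()].
#' @return an [EmbeddingReliability-class]; its \code{metadata} holds the
#'   [Embedding2D-class] (\code{$embedding}), the [PreEmbedding-class]
#'   (\code{$preEmbedding}) and the setting.
#' @examples
#' sim <- simulateClusters(nCells = 150, nGenes = 80, kClusters = 3,
#'                         separation = 8, seed = 1)
#' r <- scoreEmbedding(sim$matrix, tsneSetting(perplexity = 30),
#'                     numPCs = 2)
#' r
#' @export
scoreEmbedding <- function(x = NULL, setting, numPCs = NULL,
                           preCoords = NULL, similarityPercent = 50,
                           embedSeed = 100, permuteSeed = 100,
                           dubiousPercentile = 5,
                           trustworthyPercentile = 95,
                           quantileType = c("interpolation",
                                            "nearest_rank"),
                           center = TRUE, scale = FALSE) {
  quantileType <- match.arg(quantileType)
  if (is.null(x) && is.null(preCoords)) {
    stop("supply an expression matrix 'x', a pre-embedding 'preCoords', ",
         "or both")
  }
  if (is.null(x)) {
    # the pre-embedding features themselves are the permutation target
    x <- t(.coordMatrix(preCoords, "preCoords"))
  }
  x <- .asGeneCellMatrix(x)
  pre <- if (!is.null(preCoords)) {
    preEmbedding(preCoords)
  } else if (is.null(numPCs)) {
    preEmbedding(t(x))
  } else {
    computePCA(x, K = numPCs, center = center, scale = scale)
  }
  if (nrow(coords(pre)) != ncol(x)) {
    stop("'preCoords' rows must match the cells of 'x'")
  }
  emb <- embed2D(pre, setting, seed = embedSeed)
  sc <- reliabilityScores(pre, emb, similarityPercent)
  # the null mirrors the original pipeline: PCA is refit on the permuted
  # matrix only when the original pre-embedding came from PCA
  if (!is.null(preCoords)) numPCs <- NULL
  nullSc <- nullReliabilityScores(x, setting, numPCs = numPCs,
                                  similarityPercent = similarityPercent,
                                  embedSeed = embedSeed,
                                  permuteSeed = permuteSeed,
                                  center = center, scale = scale)
  classifyCells(sc, nullSc, dubiousPercentile = dubiousPercentile,
                trustworthyPercentile = trustworthyPercentile,
                quantileType = quantileType,
                neighborhoodSize = .mSize(ncol(x), similarityPercent),
                metadata = list(embedding = emb, preEmbedding = pre,
                                setting = setting))
}
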