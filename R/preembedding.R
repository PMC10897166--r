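#' Permute each gene independently across cells
#'
#' Builds the permuted data matrix underlying the null distribution of
#' reliability scores: the n values of every gene (row) are shuffled
#' independently of all other genes, so each row keeps its marginal
#' distribution while all cell-cell relationships are destroyed and cells
#' become exchangeable. One seeded permutation is drawn per gene.
#'
#' @param x numeric genes x cells matrix (or SummarizedExperiment).
#' @param permuteSeed integer seed for the permutation generator
#'   (default 100). The caller's RNG state is left untouched.
#' @return a matrix of the same dimensions and dimnames with every row
#'   independently permuted.
#' @examples
#' m <- matrix(1:20, 4, 5, dimnames = list(paste0("g", 1:4),
#'                                         paste0("c", 1:5)))
#' p <- permuteGenes(m)
#' stopifnot(all(apply(p, 1, sort) == apply(m, 1, sort)))
#' @export
permuteGenes <- function(x, permuteSeed = 100) {
  x <- .asGeneCellMatrix(x)
  n <- ncol(x)
  out <- .withSeed(permuteSeed, {
    idx <- vapply(seq_len(nrow(x)), function(i) sample.int(n),
                  integer(n))
    t(vapply(seq_len(nrow(x)), function(i) x[i, idx[, i]], numeric(n)))
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Compute a PCA pre-embedding space
#'
#' Projects cells onto the top-K principal components of the (gene-
#' centered) expression matrix, the conventional pre-embedding space for
#' t-SNE/UMAP pipelines. The matrix is taken as supplied -- any
#' normalization or log-transformation is at the user's discretion and
#' happens upstream. Component signs are fixed so that each component's
#' largest-magnitude gene loading is positive, which makes results
#' machine-independent; reliability scores only consume distances and are
#' unaffected by the sign convention.
#'
#' @param x numeric genes x cells matrix (or SummarizedExperiment).
#' @param K number of principal components to keep; at most
#'   \code{min(genes, cells - 1)}.
#' @param center center each gene before the decomposition (default TRUE).
#' @param scale scale each gene to unit variance (default FALSE; typical
#'   pipelines scale upstream if at all). Zero-variance genes are dropped
#'   with a warning when scaling.
#' @return a [PreEmbedding-class] with cells x K component scores, columns
#'   ordered by decreasing explained variance.
#' @examples
#' sim <- simulateClusters(nCells = 50, nGenes = 30, kClusters = 2,
#'                         separation = 6, seed = 1)
#' pre <- computePCA(sim$matrix, K = 2)
#' pre
#' @export
computePCA <- function(x, K, center = TRUE, scale = FALSE) {
  x <- .asGeneCellMatrix(x)
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (scale) {
    v <- apply(x, 1L, stats::var)
    zero <- v < .Machine$double.eps
    if (any(zero)) {
      warning(sum(zero), " zero-variance gene(s) dropped before scaling")
      x <- x[!zero, , drop = FALSE]
      if (nrow(x) < 1L) stop("no genes left after dropping zero variance")
    }
  }
  kmax <- min(nrow(x), ncol(x) - 1L)
  if (K > kmax) {
    stop("'K' = ", K, " exceeds min(genes, cells - 1) = ", kmax)
  }
  fit <- stats::prcomp(t(x), center = center, scale. = scale, rank. = K)
  sc <- fit$x[, seq_len(K), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(K)) {
    load <- fit$rotation[, j]
    if (load[which.max(abs(load))] < 0) sc[, j] <- -sc[, j]
  }
  rownames(sc) <- colnames(x)
  methods::new("PreEmbedding", coords = sc, source = "pca")
}

#' Wrap user-supplied coordinates as a pre-embedding space
#'
#' For pipelines whose pre-embedding space is not PCA -- independent
#' components, CyTOF markers, or any cells x d feature matrix.
#'
#' @param coords numeric cells x d matrix (d >= 2); row names are cell
#'   identifiers (generated when absent).
#' @return a [PreEmbedding-class] with \code{source = "user_supplied"}.
#' @export
preEmbedding <- function(coords) {
  coords <- .coordMatrix(coords, "coords")
  methods::new("PreEmbedding", coords = coords, source = "user_supplied")
}
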