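#' Construct embedding hyperparameter settings
#'
#' @param perplexity t-SNE perplexity.
#' @param nNeighbors,minDist UMAP hyperparameters.
#' @return a [HyperparamSetting-class].
#' @export
tsneSetting <- function(perplexity) {
  methods::new("HyperparamSetting", method = "tsne",
               perplexity = as.numeric(perplexity))
}

#' @rdname tsneSetting
#' @export
umapSetting <- function(nNeighbors, minDist) {
  methods::new("HyperparamSetting", method = "umap",
               nNeighbors = as.integer(nNeighbors),
               minDist = as.numeric(minDist))
}

#' @rdname tsneSetting
#' @export
passthroughSetting <- function() {
  methods::new("HyperparamSetting", method = "passthrough")
}

# Cheap feasibility check, run before the expensive embedding call.
.checkFeasible <- function(setting, n) {
  if (setting@method == "tsne") {
    if (setting@perplexity >= (n - 1) / 3) {
      stop("perplexity ", setting@perplexity, " infeasible for n = ", n,
           " cells (requires perplexity < (n - 1) / 3 = ",
           signif((n - 1) / 3, 5), ")")
    }
  } else if (setting@method == "umap") {
    if (setting@nNeighbors >= n) {
      stop("n_neighbors ", setting@nNeighbors, " infeasible for n = ", n,
           " cells (requires n_neighbors < n)")
    }
  }
  invisible(TRUE)
}

#' Embed a pre-embedding space in 2D
#'
#' Uniform contract over the embedding backends: given the same
#' pre-embedding, setting and seed, the returned coordinates are
#' bit-identical across calls (backends run single-threaded under a fixed
#' seed). The same setting and seed are used for the original and the
#' permuted pre-embedding within one diagnostic run. Reliability scores
#' computed downstream are invariant to rotation/translation/reflection of
#' the returned 2D space but not to anisotropic rescaling; coordinates are
#' therefore used exactly as produced, with no rescaling.
#'
#' Backends: t-SNE via \pkg{Rtsne} (Barnes-Hut, PCA pre-reduction
#' disabled -- the pre-embedding space is embedded as supplied), UMAP via
#' \pkg{uwot}. The \code{"passthrough"} method returns the first two
#' pre-embedding dimensions unchanged, which is useful for testing (it
#' makes every reliability score exactly 1 on a 2D pre-embedding) and for
#' scoring externally computed 2D coordinates.
#'
#' @param pre a [PreEmbedding-class] (or cells x d matrix).
#' @param setting a [HyperparamSetting-class]; infeasible settings for the
#'   given number of cells are rejected before the embedding is attempted.
#' @param seed integer random seed (default 100).
#' @return an [Embedding2D-class] whose rows align with \code{pre}.
#' @examples
#' sim <- simulateClusters(nCells = 120, nGenes = 50, kClusters = 3,
#'                         separation = 8, seed = 1)
#' pre <- computePCA(sim$matrix, K = 2)
#' emb <- embed2D(pre, tsneSetting(perplexity = 20))
#' emb
#' @export
embed2D <- function(pre, setting, seed = 100) {
  if (!methods::is(pre, "PreEmbedding")) pre <- preEmbedding(pre)
  stopifnot(methods::is(setting, "HyperparamSetting"))
  methods::validObject(setting)
  xy <- coords(pre)
  n <- nrow(xy)
  .checkFeasible(setting, n)
  seed <- as.integer(seed)
  out <- switch(setting@method,
    passthrough = xy[, 1:2, drop = FALSE],
    tsne = .withSeed(seed,
      Rtsne::Rtsne(xy, dims = 2, perplexity = setting@perplexity,
                   pca = FALSE, check_duplicates = FALSE,
                   num_threads = 1)$Y),
    umap = .withSeed(seed,
      uwot::umap(xy, n_neighbors = setting@nNeighbors,
                 min_dist = setting@minDist,
                 n_threads = 1, n_sgd_threads = 1))
  )
  out <- as.matrix(out)
  dimnames(out) <- list(rownames(xy), c("dim1", "dim2"))
  methods::new("Embedding2D", coords = out, setting = setting, seed = seed)
}
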