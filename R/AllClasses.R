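#' @import methods
NULL

#' Hyperparameter setting for a 2D embedding method
#'
#' A single candidate configuration of an embedding method. Exactly the
#' fields belonging to the method are populated: \code{perplexity} for
#' t-SNE; \code{nNeighbors} and \code{minDist} for UMAP; no fields for the
#' passthrough embedder (which simply returns the first two pre-embedding
#' dimensions and exists for testing and for pre-computed 2D inputs).
#'
#' @slot method one of \code{"tsne"}, \code{"umap"}, \code{"passthrough"}.
#' @slot perplexity t-SNE perplexity (positive; must satisfy
#'   \code{perplexity < (n - 1) / 3} for \code{n} cells).
#' @slot nNeighbors UMAP local neighborhood size (integer, at least 2,
#'   below the number of cells).
#' @slot minDist UMAP minimum spacing of embedded points, in (0, 1).
#'
#' @seealso [tsneSetting()], [umapSetting()], [passthroughSetting()]
#' @export
setClass("HyperparamSetting",
  representation(
    method = "character",
    perplexity = "numeric",
    nNeighbors = "integer",
    minDist = "numeric"
  ),
  prototype(
    method = NA_character_,
    perplexity = numeric(0),
    nNeighbors = integer(0),
    minDist = numeric(0)
  )
)

setValidity("HyperparamSetting", function(object) {
  msg <- character(0)
  if (length(object@method) != 1L ||
      !object@method %in% c("tsne", "umap", "passthrough")) {
    return("'method' must be one of \"tsne\", \"umap\", \"passthrough\"")
  }
  if (object@method == "tsne") {
    if (length(object@perplexity) != 1L || !is.finite(object@perplexity) ||
        object@perplexity <= 0) {
      msg <- c(msg, "t-SNE requires a single positive 'perplexity'")
    }
    if (length(object@nNeighbors) || length(object@minDist)) {
      msg <- c(msg, "UMAP fields must be unset for method \"tsne\"")
    }
  } else if (object@method == "umap") {
    if (length(object@nNeighbors) != 1L || is.na(object@nNeighbors) ||
        object@nNeighbors < 2L) {
      msg <- c(msg, "UMAP requires integer 'nNeighbors' >= 2")
    }
    if (length(object@minDist) != 1L || !is.finite(object@minDist) ||
        object@minDist <= 0 || object@minDist >= 1) {
      msg <- c(msg, "UMAP requires 'minDist' in (0, 1)")
    }
    if (length(object@perplexity)) {
      msg <- c(msg, "'perplexity' must be unset for method \"umap\"")
    }
  } else {
    if (length(object@perplexity) || length(object@nNeighbors) ||
        length(object@minDist)) {
      msg <- c(msg, "passthrough takes no hyperparameters")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pre-embedding coordinate space
#'
#' The coordinate space cells occupy before 2D embedding: either the
#' top-K principal-component scores computed by [computePCA()], or a
#' user-supplied feature space (e.g. independent components or CyTOF
#' markers). Row names carry the cell identifiers and define the cell
#' order that all downstream objects must respect.
#'
#' @slot coords numeric matrix, cells x dimensions (at least 2 columns),
#'   with unique row names.
#' @slot source \code{"pca"} or \code{"user_supplied"}.
#'
#' @seealso [computePCA()], [preEmbedding()]
#' @export
setClass("PreEmbedding",
  representation(coords = "matrix", source = "character")
)

setValidity("PreEmbedding", function(object) {
  msg <- character(0)
  if (!is.numeric(object@coords)) msg <- c(msg, "'coords' must be numeric")
  if (ncol(object@coords) < 2L) {
    msg <- c(msg, "pre-embedding needs at least 2 dimensions")
  }
  if (anyNA(object@coords)) msg <- c(msg, "'coords' contains missing values")
  if (is.null(rownames(object@coords))) {
    msg <- c(msg, "'coords' must have cell identifiers as row names")
  } else if (anyDuplicated(rownames(object@coords))) {
    msg <- c(msg, "cell identifiers are not unique")
  }
  if (length(object@source) != 1L ||
      !object@source %in% c("pca", "user_supplied")) {
    msg <- c(msg, "'source' must be \"pca\" or \"user_supplied\"")
  }
  if (length(msg)) msg else TRUE
})

#' Two-dimensional embedding of cells
#'
#' Coordinates produced by an embedding method under one hyperparameter
#' setting and one seed. Rows align with the pre-embedding's cell order.
#'
#' @slot coords numeric matrix, cells x 2, unique row names.
#' @slot setting the [HyperparamSetting-class] used.
#' @slot seed the random seed the embedder was run with.
#'
#' @seealso [embed2D()]
#' @export
setClass("Embedding2D",
  representation(coords = "matrix", setting = "HyperparamSetting",
                 seed = "integer")
)

setValidity("Embedding2D", function(object) {
  msg <- character(0)
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L) {
    msg <- c(msg, "'coords' must be a numeric cells x 2 matrix")
  }
  if (anyNA(object@coords)) msg <- c(msg, "'coords' contains missing values")
  if (is.null(rownames(object@coords))) {
    msg <- c(msg, "'coords' must have cell identifiers as row names")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell embedding reliability diagnostics
#'
#' Holds the per-cell reliability scores of an embedding, the permutation
#' null scores, the two null-percentile cutoffs, and the resulting label
#' for every cell: \code{"dubious"} (score at or below the dubious
#' cutoff), \code{"trustworthy"} (score at or above the trustworthy
#' cutoff), \code{"intermediate"} otherwise, or \code{"undefined"} when
#' the score could not be computed (a zero-variance distance vector).
#' Scores that are undefined are stored as \code{NA}.
#'
#' @slot scores named numeric vector of per-cell reliability scores in
#'   [-1, 1], \code{NA} where undefined.
#' @slot nullScores numeric vector of null reliability scores from the
#'   permuted data (same length).
#' @slot dubiousCutoff lower percentile of the null scores (default the
#'   5th).
#' @slot trustworthyCutoff upper percentile of the null scores (default
#'   the 95th).
#' @slot labels named character vector in
#'   \{dubious, trustworthy, intermediate, undefined\}.
#' @slot neighborhoodSize the number of ordered neighbors m used per cell.
#' @slot metadata list of auxiliary objects (e.g. the [Embedding2D-class]
#'   and [PreEmbedding-class] that produced the scores).
#'
#' @seealso [scoreEmbedding()], [classifyCells()]
#' @export
setClass("EmbeddingReliability",
  representation(
    scores = "numeric",
    nullScores = "numeric",
    dubiousCutoff = "numeric",
    trustworthyCutoff = "numeric",
    labels = "character",
    neighborhoodSize = "integer",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("EmbeddingReliability", function(object) {
  msg <- character(0)
  n <- length(object@scores)
  if (length(object@labels) != n) {
    msg <- c(msg, "'labels' and 'scores' lengths differ")
  }
  if (!all(object@labels %in%
           c("dubious", "trustworthy", "intermediate", "undefined"))) {
    msg <- c(msg, "invalid label value")
  }
  if (length(object@dubiousCutoff) != 1L ||
      length(object@trustworthyCutoff) != 1L) {
    msg <- c(msg, "cutoffs must be single numbers")
  } else if (object@dubiousCutoff > object@trustworthyCutoff) {
    msg <- c(msg, "dubious cutoff exceeds trustworthy cutoff")
  }
  ok <- !is.na(object@scores)
  if (any(object@scores[ok] < -1 - 1e-12 | object@scores[ok] > 1 + 1e-12)) {
    msg <- c(msg, "scores outside [-1, 1]")
  }
  if (any(is.na(object@scores) & object@labels != "undefined") ||
      any(!is.na(object@scores) & object@labels == "undefined")) {
    msg <- c(msg, "'undefined' labels must match NA scores exactly")
  }
  if (length(msg)) msg else TRUE
})

#' Candidate hyperparameter grid
#'
#' The set of candidate settings a [gridSearch()] evaluates. For t-SNE
#' this is a one-dimensional sweep over \code{perplexityValues}. For UMAP
#' the \code{mode} decides whether the two hyperparameters are swept
#' jointly (Cartesian product) or marginally (each swept with the other
#' held at its anchor value).
#'
#' @slot method \code{"tsne"} or \code{"umap"}.
#' @slot perplexityValues increasing candidate perplexities (t-SNE).
#' @slot nNeighborsValues increasing candidate n.neighbors (UMAP).
#' @slot minDistValues increasing candidate min.dist (UMAP).
#' @slot mode \code{"sweep"} (t-SNE), \code{"joint"} or \code{"marginal"}
#'   (UMAP).
#' @slot anchorNNeighbors,anchorMinDist values held fixed while the other
#'   UMAP hyperparameter is varied in marginal mode.
#'
#' @seealso [defaultGrid()], [gridSearch()]
#' @export
setClass("HyperparamGrid",
  representation(
    method = "character",
    perplexityValues = "numeric",
    nNeighborsValues = "integer",
    minDistValues = "numeric",
    mode = "character",
    anchorNNeighbors = "integer",
    anchorMinDist = "numeric"
  ),
  prototype(
    perplexityValues = numeric(0),
    nNeighborsValues = integer(0),
    minDistValues = numeric(0),
    anchorNNeighbors = integer(0),
    anchorMinDist = numeric(0)
  )
)

.strictlyIncreasing <- function(v) length(v) < 2L || all(diff(v) > 0)

setValidity("HyperparamGrid", function(object) {
  msg <- character(0)
  if (!object@method %in% c("tsne", "umap")) {
    msg <- c(msg, "'method' must be \"tsne\" or \"umap\"")
  }
  if (object@method == "tsne") {
    if (!length(object@perplexityValues)) {
      msg <- c(msg, "empty perplexity grid")
    }
    if (!.strictlyIncreasing(object@perplexityValues)) {
      msg <- c(msg, "'perplexityValues' must be strictly increasing")
    }
    if (!identical(object@mode, "sweep")) {
      msg <- c(msg, "t-SNE grids use mode \"sweep\"")
    }
  } else if (object@method == "umap") {
    if (!length(object@nNeighborsValues) || !length(object@minDistValues)) {
      msg <- c(msg, "empty UMAP grid")
    }
    if (!.strictlyIncreasing(object@nNeighborsValues) ||
        !.strictlyIncreasing(object@minDistValues)) {
      msg <- c(msg, "UMAP candidate lists must be strictly increasing")
    }
    if (!object@mode %in% c("joint", "marginal")) {
      msg <- c(msg, "UMAP grids use mode \"joint\" or \"marginal\"")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a hyperparameter grid search
#'
#' One row per evaluated setting with its dubious/trustworthy counts, the
#' setting minimizing the number of dubious cell embeddings (ties broken
#' by the first setting in ascending grid order; all minimizers are
#' retained), and optionally the elbow-point (kneedle) selection for
#' one-dimensional sweeps.
#'
#' @slot results data.frame with columns \code{setting} (printable label),
#'   the hyperparameter value columns, \code{n_dubious},
#'   \code{n_trustworthy}, \code{pct_dubious}, \code{pct_trustworthy} and
#'   \code{status} (\code{"ok"} or \code{"failed"}).
#' @slot bestSetting the minimizing [HyperparamSetting-class].
#' @slot allMinimizers list of every setting attaining the minimum.
#' @slot kneedleValue the hyperparameter value at the elbow of the
#'   dubious-count curve, or \code{NA} when not applicable.
#' @slot method,mode copied from the grid.
#'
#' @seealso [gridSearch()], [kneedleElbow()]
#' @export
setClass("EmbeddingOptimization",
  representation(
    results = "data.frame",
    bestSetting = "HyperparamSetting",
    allMinimizers = "list",
    kneedleValue = "numeric",
    method = "character",
    mode = "character"
  ),
  prototype(kneedleValue = NA_real_)
)

setValidity("EmbeddingOptimization", function(object) {
  msg <- character(0)
  ok <- object@results$status == "ok"
  if (any(ok)) {
    mn <- min(object@results$n_dubious[ok])
    if (!length(object@allMinimizers)) {
      msg <- c(msg, "'allMinimizers' is empty")
    }
    if (!any(vapply(object@allMinimizers, identical, logical(1),
                    y = object@bestSetting))) {
      msg <- c(msg, "'bestSetting' not among 'allMinimizers'")
    }
    if (any(object@results$n_dubious[ok] < mn)) {
      msg <- c(msg, "minimum dubious count inconsistent")
    }
  }
  if (length(msg)) msg else TRUE
})
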