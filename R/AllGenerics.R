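#' @rdname PreEmbedding-class
#' @param object,x a package object.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PreEmbedding-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("neighborhoodSize", function(x) standardGeneric("neighborhoodSize"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("dubiousCells", function(x) standardGeneric("dubiousCells"))

#' @rdname EmbeddingReliability-class
#' @export
setGeneric("trustworthyCells", function(x) standardGeneric("trustworthyCells"))

#' @rdname EmbeddingOptimization-class
#' @export
setGeneric("gridResults", function(x) standardGeneric("gridResults"))

#' @rdname EmbeddingOptimization-class
#' @export
setGeneric("bestSetting", function(x) standardGeneric("bestSetting"))

#' Write per-cell or per-setting result tables as CSV
#'
#' For an [EmbeddingReliability-class] the table has one row per cell
#' (\code{cell_id}, \code{reliability_score}, \code{label}; an undefined
#' score prints as an empty field with label \code{"undefined"}). For an
#' [EmbeddingOptimization-class] it has one row per evaluated setting
#' (printable \code{setting}, the hyperparameter columns, dubious and
#' trustworthy counts and percentages, \code{status}). Both re-read
#' losslessly at the printed precision with [utils::read.csv()].
#'
#' @param result the object to serialize.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
setGeneric("writeResults", function(result, path) {
  standardGeneric("writeResults")
})

#' @rdname PreEmbedding-class
setMethod("coords", "PreEmbedding", function(x) x@coords)

#' @rdname PreEmbedding-class
setMethod("cellIds", "PreEmbedding", function(x) rownames(x@coords))

#' @rdname Embedding2D-class
setMethod("coords", "Embedding2D", function(x) x@coords)

#' @rdname Embedding2D-class
setMethod("cellIds", "Embedding2D", function(x) rownames(x@coords))

#' @rdname EmbeddingReliability-class
setMethod("scores", "EmbeddingReliability", function(x) x@scores)

#' @rdname EmbeddingReliability-class
setMethod("nullScores", "EmbeddingReliability", function(x) x@nullScores)

#' @rdname EmbeddingReliability-class
setMethod("cutoffs", "EmbeddingReliability", function(x) {
  c(dubious = x@dubiousCutoff, trustworthy = x@trustworthyCutoff)
})

#' @rdname EmbeddingReliability-class
setMethod("cellLabels", "EmbeddingReliability", function(x) x@labels)

#' @rdname EmbeddingReliability-class
setMethod("neighborhoodSize", "EmbeddingReliability",
          function(x) x@neighborhoodSize)

#' @rdname EmbeddingReliability-class
setMethod("cellIds", "EmbeddingReliability", function(x) names(x@scores))

#' @rdname EmbeddingReliability-class
setMethod("dubiousCells", "EmbeddingReliability", function(x) {
  names(x@labels)[x@labels == "dubious"]
})

#' @rdname EmbeddingReliability-class
setMethod("trustworthyCells", "EmbeddingReliability", function(x) {
  names(x@labels)[x@labels == "trustworthy"]
})

#' @rdname EmbeddingOptimization-class
setMethod("gridResults", "EmbeddingOptimization", function(x) x@results)

#' @rdname EmbeddingOptimization-class
setMethod("bestSetting", "EmbeddingOptimization", function(x) x@bestSetting)

.settingLabel <- function(s) {
  switch(s@method,
    tsne = sprintf("perplexity=%g", s@perplexity),
    umap = sprintf("n_neighbors=%d,min_dist=%g", s@nNeighbors, s@minDist),
    passthrough = "passthrough"
  )
}

setMethod("show", "HyperparamSetting", function(object) {
  cat("HyperparamSetting:", .settingLabel(object), "\n")
})

setMethod("show", "PreEmbedding", function(object) {
  cat(sprintf("PreEmbedding (%s): %d cells x %d dims\n", object@source,
              nrow(object@coords), ncol(object@coords)))
})

setMethod("show", "Embedding2D", function(object) {
  cat(sprintf("Embedding2D: %d cells, %s, seed %d\n", nrow(object@coords),
              .settingLabel(object@setting), object@seed))
})

setMethod("show", "EmbeddingReliability", function(object) {
  n <- length(object@scores)
  tab <- table(factor(object@labels,
    levels = c("dubious", "intermediate", "trustworthy", "undefined")))
  cat(sprintf("EmbeddingReliability: %d cells, neighborhood size m = %d\n",
              n, object@neighborhoodSize))
  cat(sprintf("  null cutoffs: dubious <= %.4f, trustworthy >= %.4f\n",
              object@dubiousCutoff, object@trustworthyCutoff))
  for (lab in names(tab)) {
    cat(sprintf("  %-12s %6d (%5.2f%%)\n", lab, tab[[lab]],
                100 * tab[[lab]] / n))
  }
})

setMethod("show", "HyperparamGrid", function(object) {
  if (object@method == "tsne") {
    cat(sprintf("HyperparamGrid (t-SNE sweep): %d perplexity values\n",
                length(object@perplexityValues)))
  } else {
    cat(sprintf(
      "HyperparamGrid (UMAP, %s): %d n.neighbors x %d min.dist values\n",
      object@mode, length(object@nNeighborsValues),
      length(object@minDistValues)))
  }
})

setMethod("show", "EmbeddingOptimization", function(object) {
  cat(sprintf("EmbeddingOptimization (%s, %s): %d settings evaluated\n",
              object@method, object@mode, nrow(object@results)))
  cat("  best:", .settingLabel(object@bestSetting),
      sprintf("with %d dubious embeddings\n",
              min(object@results$n_dubious[object@results$status == "ok"])))
  if (length(object@allMinimizers) > 1L) {
    cat(sprintf("  (%d settings tie at the minimum)\n",
                length(object@allMinimizers)))
  }
  if (!is.na(object@kneedleValue)) {
    cat("  kneedle elbow at:", object@kneedleValue, "\n")
  }
})
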