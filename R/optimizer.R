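#' Default candidate hyperparameter grids
#'
#' The stock candidate values swept during optimization. For t-SNE the
#' candidate perplexities are 20, 50, ..., 380 (step 30), 410, then 450,
#' 500, ..., 750 (step 50) and 800, filtered to the feasible range
#' \code{perplexity < (n - 1)/3}. For UMAP the candidate n.neighbors are
#' 5, 6, ..., 30 then 35, 40, 45, 50 (filtered to \code{< n}) and the
#' candidate min.dist are 0.0125, 0.05, 0.1, 0.2, ..., 0.8.
#'
#' @param method \code{"tsne"} or \code{"umap"}.
#' @param n number of cells (used to filter infeasible candidates).
#' @param mode for UMAP, \code{"joint"} (Cartesian product; default) or
#'   \code{"marginal"} (each hyperparameter swept with the other held at
#'   its anchor).
#' @param anchorNNeighbors,anchorMinDist anchors for marginal mode;
#'   default to the backend defaults (15 and 0.01) and are normally set
#'   to the user's original published setting.
#' @return a [HyperparamGrid-class].
#' @examples
#' defaultGrid("tsne", n = 1e5)
#' defaultGrid("umap", n = 1e5)
#' @export
defaultGrid <- function(method = c("tsne", "umap"), n,
                        mode = c("joint", "marginal"),
                        anchorNNeighbors = 15L, anchorMinDist = 0.01) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (n < 4L) stop("'n' must be at least 4")
  if (method == "tsne") {
    perp <- c(seq(20, 380, by = 30), 410, seq(450, 750, by = 50), 800)
    perp <- perp[perp < (n - 1) / 3]
    if (!length(perp)) {
      stop("no feasible candidate perplexity for n = ", n,
           " (need perplexity < ", signif((n - 1) / 3, 5), ")")
    }
    methods::new("HyperparamGrid", method = "tsne",
                 perplexityValues = perp, mode = "sweep")
  } else {
    nn <- c(5:30, 35L, 40L, 45L, 50L)
    nn <- nn[nn < n]
    md <- c(0.0125, 0.05, seq(0.1, 0.8, by = 0.1))
    if (!length(nn)) stop("no feasible candidate n.neighbors for n = ", n)
    methods::new("HyperparamGrid", method = "umap",
                 nNeighborsValues = as.integer(nn), minDistValues = md,
                 mode = mode,
                 anchorNNeighbors = as.integer(anchorNNeighbors),
                 anchorMinDist = anchorMinDist)
  }
}

#' Build a custom hyperparameter grid
#'
#' @inheritParams defaultGrid
#' @param perplexityValues increasing candidate perplexities (t-SNE).
#' @param nNeighborsValues,minDistValues increasing candidate values
#'   (UMAP).
#' @return a [HyperparamGrid-class].
#' @export
hyperparamGrid <- function(method = c("tsne", "umap"),
                           perplexityValues = numeric(0),
                           nNeighborsValues = integer(0),
                           minDistValues = numeric(0),
                           mode = c("joint", "marginal"),
                           anchorNNeighbors = 15L, anchorMinDist = 0.01) {
  method <- match.arg(method)
  if (method == "tsne") {
    methods::new("HyperparamGrid", method = "tsne",
                 perplexityValues = as.numeric(perplexityValues),
                 mode = "sweep")
  } else {
    methods::new("HyperparamGrid", method = "umap",
                 nNeighborsValues = as.integer(nNeighborsValues),
                 minDistValues = as.numeric(minDistValues),
                 mode = match.arg(mode),
                 anchorNNeighbors = as.integer(anchorNNeighbors),
                 anchorMinDist = anchorMinDist)
  }
}

# Expand a grid into the ordered list of settings to evaluate. Ascending
# grid order (perplexity; or n.neighbors then min.dist) defines the
# tie-breaking order at the minimum.
.gridSettings <- function(grid) {
  if (grid@method == "tsne") {
    return(lapply(grid@perplexityValues, tsneSetting))
  }
  if (grid@mode == "joint") {
    out <- list()
    for (nn in grid@nNeighborsValues) {
      for (md in grid@minDistValues) {
        out[[length(out) + 1L]] <- umapSetting(nn, md)
      }
    }
    out
  } else {
    c(lapply(grid@nNeighborsValues, umapSetting,
             minDist = grid@anchorMinDist),
      lapply(grid@minDistValues,
             function(md) umapSetting(grid@anchorNNeighbors, md)))
  }
}

#' Optimize embedding hyperparameters by minimizing dubious embeddings
#'
#' Evaluates every candidate setting of the grid with the full diagnostic
#' pipeline -- embed the original pre-embedding space, embed the
#' (once-)permuted data under the same setting and seed, score both,
#' classify against the null -- and records the number of dubious cell
#' embeddings per setting. The permutation is drawn once per search
#' (it does not depend on the setting) and the permuted data are
#' re-embedded under each candidate setting. The chosen setting minimizes
#' the dubious count; ties are broken in favor of the first (smallest)
#' setting in ascending grid order, avoiding any bias toward large
#' hyperparameter values, and all minimizers are reported. A setting that
#' fails to embed is recorded with status \code{"failed"}, excluded from
#' the minimization, and warned about.
#'
#' For one-dimensional sweeps (t-SNE) the elbow of the dubious-count
#' curve is also located with [kneedleElbow()] and stored alongside the
#' global minimizer.
#'
#' @inheritParams scoreEmbedding
#' @param grid a [HyperparamGrid-class] (see [defaultGrid()]).
#' @param kneedle also compute the elbow-point selection for 1D sweeps
#'   (default TRUE).
#' @param verbose print one line per evaluated setting.
#' @return an [EmbeddingOptimization-class].
#' @examples
#' \donttest{
#' sim <- simulateClusters(nCells = 200, nGenes = 100, kClusters = 3,
#'                         separation = 8, seed = 1)
#' opt <- gridSearch(sim$matrix,
#'                   hyperparamGrid("tsne", perplexityValues = c(10, 30)),
#'                   numPCs = 2)
#' bestSetting(opt)
#' }
#' @export
gridSearch <- function(x = NULL, grid, numPCs = NULL, preCoords = NULL,
                       similarityPercent = 50, embedSeed = 100,
                       permuteSeed = 100, dubiousPercentile = 5,
                       trustworthyPercentile = 95, center = TRUE,
                       scale = FALSE, kneedle = TRUE, verbose = FALSE) {
  stopifnot(methods::is(grid, "HyperparamGrid"))
  methods::validObject(grid)
  if (is.null(x) && is.null(preCoords)) {
    stop("supply an expression matrix 'x', a pre-embedding 'preCoords', ",
         "or both")
  }
  if (is.null(x)) x <- t(.coordMatrix(preCoords, "preCoords"))
  x <- .asGeneCellMatrix(x)
  n <- ncol(x)

  pre <- if (!is.null(preCoords)) {
    preEmbedding(preCoords)
  } else if (is.null(numPCs)) {
    preEmbedding(t(x))
  } else {
    computePCA(x, K = numPCs, center = center, scale = scale)
  }
  # one permutation per search; setting-independent
  perm <- permuteGenes(x, permuteSeed = permuteSeed)
  preNull <- if (is.null(numPCs) || !is.null(preCoords)) {
    preEmbedding(t(perm))
  } else {
    computePCA(perm, K = numPCs, center = center, scale = scale)
  }

  settings <- .gridSettings(grid)
  rows <- vector("list", length(settings))
  for (k in seq_along(settings)) {
    s <- settings[[k]]
    res <- tryCatch({
      emb <- embed2D(pre, s, seed = embedSeed)
      embNull <- embed2D(preNull, s, seed = embedSeed)
      sc <- reliabilityScores(pre, emb, similarityPercent)
      nullSc <- reliabilityScores(preNull, embNull, similarityPercent)
      cl <- suppressMessages(classifyCells(
        sc, nullSc, dubiousPercentile = dubiousPercentile,
        trustworthyPercentile = trustworthyPercentile,
        neighborhoodSize = .mSize(n, similarityPercent)))
      tab <- table(factor(cl@labels,
        levels = c("dubious", "trustworthy", "intermediate", "undefined")))
      list(nd = tab[["dubious"]], nt = tab[["trustworthy"]], status = "ok")
    }, error = function(e) {
      warning("setting ", .settingLabel(s), " failed: ",
              conditionMessage(e), call. = FALSE)
      list(nd = NA_integer_, nt = NA_integer_, status = "failed")
    })
    rows[[k]] <- data.frame(
      setting = .settingLabel(s),
      perplexity = if (s@method == "tsne") s@perplexity else NA_real_,
      n_neighbors = if (s@method == "umap") s@nNeighbors else NA_integer_,
      min_dist = if (s@method == "umap") s@minDist else NA_real_,
      n_dubious = res$nd, n_trustworthy = res$nt,
      pct_dubious = 100 * res$nd / n, pct_trustworthy = 100 * res$nt / n,
      status = res$status, stringsAsFactors = FALSE
    )
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s dubious", k, length(settings),
                      .settingLabel(s),
                      ifelse(is.na(res$nd), "failed", res$nd)))
    }
  }
  results <- do.call(rbind, rows)
  ok <- which(results$status == "ok")
  if (!length(ok)) stop("every candidate setting failed")
  mn <- min(results$n_dubious[ok])
  minIdx <- ok[results$n_dubious[ok] == mn]
  best <- settings[[minIdx[1L]]]

  kv <- NA_real_
  if (kneedle && grid@method == "tsne" && length(ok) >= 3L) {
    kv <- tryCatch(
      kneedleElbow(results$perplexity[ok], results$n_dubious[ok]),
      warning = function(w) NA_real_, error = function(e) NA_real_)
  }
  methods::new("EmbeddingOptimization",
               results = results, bestSetting = best,
               allMinimizers = settings[minIdx], kneedleValue = kv,
               method = grid@method, mode = grid@mode)
}

#' Elbow-point hyperparameter selection (kneedle)
#'
#' Locates the elbow of the dubious-count versus hyperparameter curve:
#' both axes are min-max normalized, the vertical difference between the
#' chord (the segment joining the first and last points) and the curve is
#' computed, and the hyperparameter value maximizing that difference is
#' returned -- the knee of a convex-decreasing curve. Past this value the
#' dubious count no longer drops appreciably, so the elbow is a
#' parsimonious alternative to the global minimizer.
#'
#' @param values increasing hyperparameter values (at least 3).
#' @param dubiousCounts dubious-embedding counts at those values; must
#'   not be all equal.
#' @return the elbow value, or \code{NA} (with a warning) when the curve
#'   is flat or linear and has no knee.
#' @examples
#' kneedleElbow(1:5, c(100, 20, 10, 9, 8))  # 2
#' @export
kneedleElbow <- function(values, dubiousCounts) {
  if (length(values) < 3L) stop("need at least 3 points")
  if (length(values) != length(dubiousCounts)) {
    stop("'values' and 'dubiousCounts' lengths differ")
  }
  if (is.unsorted(values, strictly = TRUE)) {
    stop("'values' must be strictly increasing")
  }
  if (length(unique(dubiousCounts)) == 1L) {
    warning("dubious counts are constant; no elbow")
    return(NA_real_)
  }
  xn <- (values - min(values)) / diff(range(values))
  yn <- (dubiousCounts - min(dubiousCounts)) / diff(range(dubiousCounts))
  chord <- yn[1L] + (yn[length(yn)] - yn[1L]) * xn
  d <- chord - yn
  if (max(d) <= 1e-8) {
    warning("curve has no knee below its chord; no elbow")
    return(NA_real_)
  }
  values[which.max(d)]
}
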