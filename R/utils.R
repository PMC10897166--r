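# Run expr under a fixed RNG seed without clobbering the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Coerce x (matrix, Matrix, or SummarizedExperiment) to a dense numeric
# genes x cells matrix and enforce the input contract: no missing values,
# at least 4 cells, unique gene and cell identifiers (generated when the
# input carries none).
.asGeneCellMatrix <- function(x, what = "x") {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (methods::is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'", what, "' must be a numeric genes x cells matrix ",
         "(or a SummarizedExperiment)")
  }
  if (anyNA(x)) stop("'", what, "' contains missing values")
  if (nrow(x) < 1L) stop("'", what, "' has no genes")
  if (ncol(x) < 4L) {
    stop("'", what, "' has fewer than 4 cells; reliability scoring needs ",
         "at least 2 neighbors per cell")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("gene", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("cell", seq_len(ncol(x)))
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate cell identifiers")
  x
}

# Accept a PreEmbedding/Embedding2D or a bare cells x d matrix.
.coordMatrix <- function(x, what = "x") {
  if (methods::is(x, "PreEmbedding") || methods::is(x, "Embedding2D")) {
    return(x@coords)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'", what, "' must be a coordinate matrix or a PreEmbedding/",
         "Embedding2D object")
  }
  if (anyNA(x)) stop("'", what, "' contains missing values")
  if (is.null(rownames(x))) rownames(x) <- paste0("cell", seq_len(nrow(x)))
  x
}

# Half-up rounding (base round() is half-to-even).
.roundHalfUp <- function(v) floor(v + 0.5)
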