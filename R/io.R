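#' Read a gene-by-cell expression or coordinate matrix
#'
#' Reads either a delimited text matrix (comma-separated by default; tab
#' auto-detected from the header line) with identifiers in the header row
#' and first column, or a Matrix Market triplet file (\code{.mtx}) with
#' companion gene and barcode identifier files, the standard layout of
#' gene-expression exports. Whatever the on-disk orientation, the result
#' is returned as genes x cells.
#'
#' @param path path to the matrix file (\code{.csv}/\code{.tsv}/
#'   \code{.txt}, or \code{.mtx}).
#' @param layout orientation of the delimited file on disk:
#'   \code{"genes_by_cells"} (rows are genes; the default) or
#'   \code{"cells_by_genes"} (rows are cells; the matrix is transposed on
#'   read). Matrix Market input is always read as genes x cells.
#' @param featuresPath,barcodesPath identifier files for Matrix Market
#'   input; default to \code{features.tsv} and \code{barcodes.tsv} next to
#'   the \code{.mtx} file. The first column of each is used.
#' @return a dense numeric genes x cells matrix with gene row names and
#'   cell column names.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' f <- tempfile(fileext = ".csv")
#' write.csv(m, f)
#' stopifnot(all.equal(readExpressionMatrix(f), m))
#' @export
readExpressionMatrix <- function(path,
                                 layout = c("genes_by_cells",
                                            "cells_by_genes"),
                                 featuresPath = NULL, barcodesPath = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx(\\.gz)?$", path, ignore.case = TRUE)) {
    return(.readMtx(path, featuresPath, barcodesPath))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) {
      stop("parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (ncol(df) < 2L) stop("'", path, "' has no data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric values in column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column identifiers in '", path, "'")
  }
  if (layout == "cells_by_genes") m <- t(m)
  .asGeneCellMatrix(m, what = path)
}

.readMtx <- function(path, featuresPath, barcodesPath) {
  dir <- dirname(path)
  if (is.null(featuresPath)) featuresPath <- file.path(dir, "features.tsv")
  if (is.null(barcodesPath)) barcodesPath <- file.path(dir, "barcodes.tsv")
  for (f in c(featuresPath, barcodesPath)) {
    if (!file.exists(f)) stop("identifier file not found: ", f)
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- utils::read.table(featuresPath, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(barcodesPath, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m)) {
    stop("features file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  }
  if (length(cells) != ncol(m)) {
    stop("barcodes file has ", length(cells), " entries but matrix has ",
         ncol(m), " columns")
  }
  dimnames(m) <- list(genes, cells)
  .asGeneCellMatrix(m, what = path)
}

#' Read a cell label table
#'
#' Reads a two-column CSV (\code{cell_id,label}) into a named character
#' vector, the input of [kncPreservation()].
#'
#' @param path path to the CSV file.
#' @return named character vector of labels.
#' @export
readCellLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns cell_id,label")
  if (anyDuplicated(df[[1L]])) stop("duplicate cell identifiers in ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @describeIn writeResults one row per cell: \code{cell_id},
#'   \code{reliability_score} (empty for undefined scores), \code{label}.
#' @export
setMethod("writeResults", "EmbeddingReliability", function(result, path) {
  df <- data.frame(
    cell_id = names(result@scores),
    reliability_score = result@scores,
    label = result@labels,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
})

#' @describeIn writeResults one row per evaluated hyperparameter setting.
#' @export
setMethod("writeResults", "EmbeddingOptimization", function(result, path) {
  utils::write.csv(result@results, path, row.names = FALSE, na = "")
  invisible(path)
})
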