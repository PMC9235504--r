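#' Construct a modality matrix
#'
#' A `modality_matrix` holds one modality's cell-by-feature matrix together
#' with cell barcodes, feature names, a modality tag and a processing stage.
#' Raw matrices are count-valued; `stage` tracks what normalization has been
#' applied so downstream operations can refuse inputs at the wrong stage.
#'
#' @param values Numeric matrix or sparse `Matrix` with cells in rows and
#'   features in columns.
#' @param cell_ids Character vector of unique cell barcodes, one per row.
#' @param feature_ids Character vector of unique feature names, one per column.
#' @param modality One of `"rna"`, `"protein"`, `"atac"`.
#' @param stage One of `"raw"`, `"normalized"`, `"scaled"`, `"tfidf"`.
#'   Raw matrices must be non-negative.
#' @return An object of class `modality_matrix`.
#' @export
modality_matrix <- function(values, cell_ids, feature_ids,
                            modality = c("rna", "protein", "atac"),
                            stage = c("raw", "normalized", "scaled", "tfidf")) {
  modality <- match.arg(modality)
  stage <- match.arg(stage)
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("`values` must be a base matrix or a Matrix object")
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values)) {
    stop(sprintf("length of cell_ids (%d) does not match row count (%d)",
                 length(cell_ids), nrow(values)))
  }
  if (length(feature_ids) != ncol(values)) {
    stop(sprintf("length of feature_ids (%d) does not match column count (%d)",
                 length(feature_ids), ncol(values)))
  }
  if (anyDuplicated(cell_ids)) stop("cell_ids contain duplicates")
  if (anyDuplicated(feature_ids)) stop("feature_ids contain duplicates")
  if (stage == "raw" && min_value(values) < 0) {
    stop("raw matrices must be non-negative")
  }
  rownames(values) <- cell_ids
  colnames(values) <- feature_ids
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality, stage = stage),
    class = "modality_matrix"
  )
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix> %s (%s): %d cells x %d features\n",
              x$modality, x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

#' Construct a reduced embedding
#'
#' A `reduced_embedding` is a cell-by-dimension score matrix produced by PCA
#' or LSI (or supplied externally), the form consumed by the CCA integration
#' step. `dropped_dims` records 1-based indices of original components that
#' were removed, e.g. the depth-correlated first LSI dimension.
#'
#' @param values Numeric cell-by-dimension matrix; all entries finite.
#' @param cell_ids Character vector of unique cell barcodes, one per row.
#' @param method One of `"pca"`, `"lsi"`, `"external"`.
#' @param dropped_dims Integer vector of removed original component indices.
#' @param loadings Optional feature-by-dimension loading matrix kept for
#'   diagnostics (reconstruction, sign conventions).
#' @param singular_values Optional per-component singular values.
#' @return An object of class `reduced_embedding`.
#' @export
reduced_embedding <- function(values, cell_ids, method = c("pca", "lsi", "external"),
                              dropped_dims = integer(), loadings = NULL,
                              singular_values = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length of cell_ids does not match row count")
  }
  if (anyDuplicated(cell_ids)) stop("cell_ids contain duplicates")
  if (ncol(values) < 2) stop("a reduced embedding needs at least 2 dimensions")
  if (!all(is.finite(values))) stop("embedding contains non-finite values")
  rownames(values) <- cell_ids
  if (is.null(colnames(values))) {
    prefix <- if (method == "lsi") "LSI_" else if (method == "pca") "PC_" else "DIM_"
    colnames(values) <- paste0(prefix, seq_len(ncol(values)))
  }
  structure(
    list(values = values, cell_ids = cell_ids, method = method,
         n_dims = ncol(values), dropped_dims = as.integer(dropped_dims),
         loadings = loadings, singular_values = singular_values),
    class = "reduced_embedding"
  )
}

#' @export
print.reduced_embedding <- function(x, ...) {
  cat(sprintf("<reduced_embedding> %s: %d cells x %d dims", x$method,
              nrow(x$values), x$n_dims))
  if (length(x$dropped_dims)) {
    cat(sprintf(" (dropped: %s)", paste(x$dropped_dims, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.reduced_embedding <- function(x) dim(x$values)

# minimum over dense or sparse values without densifying
min_value <- function(values) {
  if (methods::is(values, "sparseMatrix")) {
    x <- values@x
    if (length(x) < length(values)) min(0, x) else min(x)
  } else {
    min(values)
  }
}

# coerce a reduced_embedding or bare matrix to a plain matrix
as_matrix_input <- function(x) {
  if (inherits(x, "reduced_embedding")) x$values
  else if (inherits(x, "integrated_latent")) x$Z
  else as.matrix(x)
}

check_same_cells <- function(ids1, ids2, what = "inputs") {
  if (length(ids1) != length(ids2)) {
    stop(sprintf("%s have different cell counts: %d vs %d", what,
                 length(ids1), length(ids2)))
  }
  mism <- which(ids1 != ids2)
  if (length(mism)) {
    i <- mism[1]
    stop(sprintf("%s disagree on cell ids (first mismatch at position %d: '%s' vs '%s')",
                 what, i, ids1[i], ids2[i]))
  }
  invisible(TRUE)
}
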