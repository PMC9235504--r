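#' Read a Matrix Market count matrix with sidecar files
#'
#' Reads the conventional triplet layout: a feature-by-cell sparse MTX
#' matrix with one-barcode-per-line and one-feature-per-line sidecars
#' (gzipped files handled transparently), transposed to the in-memory
#' cell-by-feature orientation.
#'
#' @param matrix_path Path to the `.mtx` (or `.mtx.gz`) file.
#' @param barcodes_path Path to the barcodes file (one per line).
#' @param features_path Path to the features file (first tab-separated
#'   column is used as the feature id).
#' @param modality Modality tag for the result.
#' @param stage Processing stage of the stored values (default `"raw"`).
#' @return A `modality_matrix`.
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path,
                     modality = c("rna", "protein", "atac"), stage = "raw") {
  modality <- match.arg(modality)
  m <- Matrix::readMM(open_maybe_gz(matrix_path))
  barcodes <- read_lines_maybe_gz(barcodes_path)
  features <- vapply(strsplit(read_lines_maybe_gz(features_path), "\t"),
                     `[`, character(1), 1)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "matrix is %d features x %d cells but sidecars list %d features and %d barcodes",
      nrow(m), ncol(m), length(features), length(barcodes)))
  }
  modality_matrix(methods::as(Matrix::t(m), "CsparseMatrix"),
                  barcodes, features, modality, stage)
}

#' Write a modality matrix as Matrix Market plus sidecars
#'
#' @param mm A `modality_matrix`.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `barcodes.tsv`, `features.tsv`.
#' @return Invisibly, the directory path.
#' @export
write_mtx <- function(mm, dir) {
  stopifnot(inherits(mm, "modality_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::t(mm$values), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(mm$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(mm$feature_ids, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a dense CSV count matrix
#'
#' Expects cells in rows with a `cell_id` first column and feature names in
#' the header.
#'
#' @param path CSV path.
#' @inheritParams read_mtx
#' @return A `modality_matrix`.
#' @export
read_csv_matrix <- function(path, modality = c("rna", "protein", "atac"),
                            stage = "raw") {
  modality <- match.arg(modality)
  df <- utils::read.csv(path, check.names = FALSE)
  cell_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  modality_matrix(values, cell_ids, colnames(df)[-1], modality, stage)
}

#' Read a reduced embedding from CSV
#'
#' Expects a `cell_id` first column and one column per dimension.
#'
#' @param path CSV path.
#' @param method Embedding provenance tag (default `"external"`).
#' @return A `reduced_embedding`.
#' @export
read_embedding_csv <- function(path, method = "external") {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  reduced_embedding(values, as.character(df[[1]]), method)
}

#' Write a reduced embedding or latent matrix to CSV
#'
#' @param x A `reduced_embedding`, `integrated_latent` or matrix with cell
#'   ids as rownames.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_embedding_csv <- function(x, path) {
  values <- as_matrix_input(x)
  ids <- if (inherits(x, "reduced_embedding")) x$cell_ids else rownames(values)
  if (is.null(ids)) stop("no cell ids available to write")
  # 17 significant digits so doubles survive a write-read round trip exactly
  chr <- apply(values, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(cell_id = ids, chr, check.names = FALSE)
  colnames(df) <- c("cell_id", colnames(values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cell labels aligned to a cell order
#'
#' Reads a CSV with `cell_id` and `label` columns and returns the labels in
#' the order of `cell_ids`.
#'
#' @param path CSV path.
#' @param cell_ids Character vector giving the required cell order.
#' @return Character vector of labels aligned to `cell_ids`.
#' @export
read_labels <- function(path, cell_ids) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("cell_id", "label") %in% colnames(df))) {
    stop("labels file needs 'cell_id' and 'label' columns")
  }
  if (anyDuplicated(df$cell_id)) {
    stop(sprintf("duplicate barcode in labels file: '%s'",
                 df$cell_id[anyDuplicated(df$cell_id)]))
  }
  idx <- match(cell_ids, df$cell_id)
  if (anyNA(idx)) {
    missing <- utils::head(cell_ids[is.na(idx)], 10)
    stop(sprintf("%d cell(s) missing from labels file, e.g.: %s",
                 sum(is.na(idx)), paste(missing, collapse = ", ")))
  }
  as.character(df$label)[idx]
}

#' Write a synthetic dataset to a plain-text directory container
#'
#' One subdirectory per modality (MTX + sidecars) plus `labels.csv` when
#' population labels exist and `params.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$modalities)) {
    write_mtx(dataset$modalities[[nm]], file.path(dir, nm))
  }
  if (!is.null(dataset$labels)) {
    utils::write.csv(
      data.frame(cell_id = dataset$modalities[[1]]$cell_ids,
                 label = as.character(dataset$labels)),
      file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(dataset$params)) {
    jsonlite::write_json(dataset$params, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con)
}
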