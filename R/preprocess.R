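#' Log-normalize RNA counts
#'
#' Divides each cell's counts by that cell's total, multiplies by
#' `scale_factor` and applies `log1p` — the standard library-size
#' normalization for scRNA-seq counts.
#'
#' @param raw A raw RNA `modality_matrix`.
#' @param scale_factor Positive scaling constant applied after depth
#'   division; default 10000.
#' @return A `modality_matrix` at stage `"normalized"`.
#' @export
lognormalize_rna <- function(raw, scale_factor = 1e4) {
  stopifnot(inherits(raw, "modality_matrix"))
  if (raw$modality != "rna") stop("lognormalize_rna expects an RNA matrix")
  if (raw$stage != "raw") stop("input must be at stage 'raw'")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  totals <- Matrix::rowSums(raw$values)
  if (any(totals == 0)) {
    bad <- raw$cell_ids[which(totals == 0)[1]]
    stop(sprintf("cell '%s' has zero total counts; filter empty cells first", bad))
  }
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% raw$values
  if (methods::is(norm, "sparseMatrix")) {
    norm <- methods::as(norm, "CsparseMatrix")
    norm@x <- log1p(norm@x)
  } else {
    norm <- log1p(as.matrix(norm))
  }
  modality_matrix(norm, raw$cell_ids, raw$feature_ids, raw$modality, "normalized")
}

#' Select highly variable features
#'
#' Ranks features by standardized variance: a loess trend of log10 variance
#' against log10 mean predicts each feature's expected variance, values are
#' standardized by the predicted standard deviation and clipped at sqrt(n),
#' and the variance of the clipped values is the ranking criterion. The
#' returned matrix keeps the selected features in their original column order.
#'
#' @param normalized A normalized `modality_matrix`.
#' @param n_top Number of features to keep (default 3000).
#' @param loess_span Span of the mean-variance trend fit.
#' @return A `modality_matrix` restricted to the `n_top` most variable
#'   features.
#' @export
select_hvg <- function(normalized, n_top = 3000, loess_span = 0.3) {
  stopifnot(inherits(normalized, "modality_matrix"))
  if (normalized$stage != "normalized") stop("input must be at stage 'normalized'")
  p <- ncol(normalized$values)
  if (n_top > p) {
    stop(sprintf("n_top (%d) exceeds the number of features (%d)", n_top, p))
  }
  sv <- standardized_variance(normalized$values, loess_span = loess_span)
  keep_set <- order(-sv, seq_along(sv))[seq_len(n_top)]
  keep <- sort(keep_set)  # preserve original column order
  modality_matrix(normalized$values[, keep, drop = FALSE],
                  normalized$cell_ids, normalized$feature_ids[keep],
                  normalized$modality, normalized$stage)
}

# standardized (clipped) variance per feature, loess mean-variance trend
standardized_variance <- function(values, loess_span = 0.3) {
  n <- nrow(values)
  mu <- as.numeric(Matrix::colMeans(values))
  sq <- as.numeric(Matrix::colSums(values^2))
  v <- (sq - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  usable <- v > 0 & mu > 0
  expected_sd <- rep(0, length(v))
  if (sum(usable) >= 3) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = loess_span, degree = 2)
    expected_sd[usable] <- sqrt(10^stats::fitted(fit))
  } else {
    expected_sd[usable] <- sqrt(v[usable])
  }
  clip <- sqrt(n)
  out <- numeric(length(v))
  dense <- as.matrix(values)
  for (j in which(usable & expected_sd > 0)) {
    z <- (dense[, j] - mu[j]) / expected_sd[j]
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    out[j] <- stats::var(z)
  }
  out
}

#' Center, scale and run PCA
#'
#' Features are centered and scaled to unit variance (values clipped at +10),
#' then the cells are projected onto the top principal components. Component
#' signs follow a fixed convention: the largest-magnitude loading of each
#' component is positive, making results reproducible across runs.
#'
#' @param selected A normalized `modality_matrix` (typically after HVG
#'   selection for RNA; all features for protein).
#' @param n_components Number of principal components; defaults are 50 for
#'   RNA and 30 for protein.
#' @param clip_max Upper clip applied to scaled values (default +10).
#' @return A `reduced_embedding` with `method = "pca"`.
#' @export
scale_and_pca <- function(selected, n_components = if (selected$modality == "protein") 30 else 50,
                          clip_max = 10) {
  stopifnot(inherits(selected, "modality_matrix"))
  if (selected$stage != "normalized") stop("input must be at stage 'normalized'")
  n <- nrow(selected$values); p <- ncol(selected$values)
  if (n_components >= min(n, p)) {
    stop(sprintf("n_components (%d) must be < min(cells, features) = %d",
                 n_components, min(n, p)))
  }
  x <- as.matrix(selected$values)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sprintf("%d constant feature(s) scaled to zero", sum(const)))
    sdv[const] <- 1
  }
  x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  x[x > clip_max] <- clip_max
  dec <- truncated_svd(x, n_components)
  scores <- dec$u %*% diag(dec$d, n_components, n_components)
  fixed <- fix_component_signs(scores, dec$v)
  reduced_embedding(fixed$scores, selected$cell_ids, "pca",
                    loadings = `rownames<-`(fixed$loadings, selected$feature_ids),
                    singular_values = dec$d)
}

#' Centered log-ratio normalization for protein counts
#'
#' Applies the CLR transform per feature across cells (the margin-2
#' convention for antibody capture data): each value becomes
#' `log1p(x)` minus the mean of `log1p` over that feature's values across
#' all cells. A feature constant across cells maps to zero.
#'
#' @param raw A raw protein `modality_matrix`.
#' @return A `modality_matrix` at stage `"normalized"` (dense).
#' @export
clr_normalize_protein <- function(raw) {
  stopifnot(inherits(raw, "modality_matrix"))
  if (raw$modality != "protein") stop("clr_normalize_protein expects a protein matrix")
  if (raw$stage != "raw") stop("input must be at stage 'raw'")
  x <- as.matrix(raw$values)
  if (min(x) < 0) stop("protein counts must be non-negative")
  lx <- log1p(x)
  out <- sweep(lx, 2, colMeans(lx), "-")
  modality_matrix(out, raw$cell_ids, raw$feature_ids, raw$modality, "normalized")
}

#' TF-IDF weighting of ATAC peak counts
#'
#' Term frequency is each count divided by its cell's total; inverse document
#' frequency is the number of cells divided by the number of cells in which
#' the peak is detected; the stored value is `log1p(TF * IDF * 10000)`.
#' Peaks detected in no cell are dropped with a warning (the q0 cutoff keeps
#' every peak seen in at least one cell). Sparsity is preserved.
#'
#' @param raw A raw ATAC `modality_matrix`.
#' @param scale_factor Scaling constant inside the log (default 10000).
#' @return A `modality_matrix` at stage `"tfidf"`.
#' @export
tfidf <- function(raw, scale_factor = 1e4) {
  stopifnot(inherits(raw, "modality_matrix"))
  if (raw$modality != "atac") stop("tfidf expects an ATAC matrix")
  if (raw$stage != "raw") stop("input must be at stage 'raw'")
  x <- methods::as(methods::as(raw$values, "CsparseMatrix"), "generalMatrix")
  totals <- Matrix::rowSums(x)
  if (any(totals == 0)) {
    bad <- raw$cell_ids[which(totals == 0)[1]]
    stop(sprintf("cell '%s' has zero total counts", bad))
  }
  detected <- Matrix::colSums(x > 0)
  if (any(detected == 0)) {
    warning(sprintf("dropping %d peak(s) detected in no cell", sum(detected == 0)))
    keep <- detected > 0
    x <- x[, keep, drop = FALSE]
    detected <- detected[keep]
    features <- raw$feature_ids[keep]
  } else {
    features <- raw$feature_ids
  }
  tf <- Matrix::Diagonal(x = 1 / totals) %*% x
  val <- tf %*% Matrix::Diagonal(x = nrow(x) / detected)
  val <- methods::as(val, "CsparseMatrix")
  val@x <- log1p(val@x * scale_factor)
  modality_matrix(val, raw$cell_ids, features, raw$modality, "tfidf")
}

#' LSI reduction of a TF-IDF matrix
#'
#' Truncated SVD of the TF-IDF matrix (latent semantic indexing). By default
#' the first component is discarded: with count data it tracks per-cell
#' sequencing depth rather than biology. Component signs follow the
#' largest-loading-positive convention.
#'
#' @param tfidf_mat A `modality_matrix` at stage `"tfidf"`.
#' @param n_components Number of singular vectors to compute (default 50).
#' @param drop_first Drop component 1 (default TRUE); recorded in
#'   `dropped_dims`.
#' @return A `reduced_embedding` with `method = "lsi"`.
#' @export
lsi_reduce <- function(tfidf_mat, n_components = 50, drop_first = TRUE) {
  stopifnot(inherits(tfidf_mat, "modality_matrix"))
  if (tfidf_mat$stage != "tfidf") stop("input must be at stage 'tfidf'")
  n <- nrow(tfidf_mat$values); p <- ncol(tfidf_mat$values)
  if (n_components > min(n, p)) {
    stop(sprintf("n_components (%d) exceeds min(cells, peaks) = %d",
                 n_components, min(n, p)))
  }
  dec <- truncated_svd(tfidf_mat$values, n_components)
  scores <- dec$u %*% diag(dec$d, n_components, n_components)
  fixed <- fix_component_signs(scores, dec$v)
  scores <- fixed$scores; loadings <- fixed$loadings
  dropped <- integer()
  if (drop_first) {
    if (n_components < 3) stop("drop_first requires n_components >= 3")
    scores <- scores[, -1, drop = FALSE]
    loadings <- loadings[, -1, drop = FALSE]
    dropped <- 1L
  }
  reduced_embedding(scores, tfidf_mat$cell_ids, "lsi", dropped_dims = dropped,
                    loadings = `rownames<-`(loadings, tfidf_mat$feature_ids),
                    singular_values = if (drop_first) dec$d[-1] else dec$d)
}

# truncated SVD: exact LAPACK for small problems, irlba (with a fixed
# internal seed so results are reproducible) for large sparse ones
truncated_svd <- function(x, k) {
  n <- nrow(x); p <- ncol(x)
  if (min(n, p) <= 700 && !(methods::is(x, "sparseMatrix") && n * p > 5e7)) {
    dec <- svd(as.matrix(x), nu = k, nv = k)
    list(u = dec$u, d = dec$d[seq_len(k)], v = dec$v)
  } else {
    dec <- withr::with_seed(1L, irlba::irlba(x, nv = k, nu = k))
    list(u = dec$u, d = dec$d, v = dec$v)
  }
}

# flip each component so its largest-absolute loading is positive
fix_component_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Run the standard reduction recipe for one modality
#'
#' Convenience wrapper dispatching on the modality tag: log-normalize +
#' HVG + scaled PCA for RNA; CLR + PCA for protein; TF-IDF + LSI
#' (dropping the depth component) for ATAC.
#'
#' @param raw A raw `modality_matrix`.
#' @param n_dims Requested dimensionality (modality-specific default).
#' @param n_hvg Number of variable genes for RNA (default 3000, capped at
#'   the feature count).
#' @param drop_first Drop the first LSI dimension for ATAC (default TRUE).
#' @return A `reduced_embedding`.
#' @export
preprocess_modality <- function(raw, n_dims = NULL, n_hvg = 3000, drop_first = TRUE) {
  stopifnot(inherits(raw, "modality_matrix"))
  switch(raw$modality,
    rna = {
      if (is.null(n_dims)) n_dims <- 50
      norm <- lognormalize_rna(raw)
      hvg <- select_hvg(norm, min(n_hvg, ncol(norm$values)))
      scale_and_pca(hvg, n_dims)
    },
    protein = {
      if (is.null(n_dims)) n_dims <- 30
      scale_and_pca(clr_normalize_protein(raw), n_dims)
    },
    atac = {
      if (is.null(n_dims)) n_dims <- 50
      lsi_reduce(tfidf(raw), n_dims, drop_first = drop_first)
    }
  )
}
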