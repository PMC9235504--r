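#' Structure-preservation score between two embeddings
#'
#' Pearson correlation between pairwise Euclidean cell-cell distances in the
#' shared space `Z` and in a modality's reduced space `Y`. With many cells
#' the quadratic number of pairs is subsampled uniformly without replacement
#' (reproducibly, given `seed`); when the total pair count does not exceed
#' `n_pairs` all pairs are used and the score is deterministic.
#'
#' @param Z Shared latent matrix (or `integrated_latent`).
#' @param Y A `reduced_embedding` or matrix over the same cells.
#' @param n_pairs Maximum number of cell pairs (default 100000).
#' @param seed Seed for pair subsampling.
#' @return A single correlation in `[-1, 1]`.
#' @export
structure_score <- function(Z, Y, n_pairs = 1e5, seed = 1) {
  z <- as_matrix_input(Z); y <- as_matrix_input(Y)
  if (nrow(z) != nrow(y)) stop("Z and Y have different cell counts")
  n <- nrow(z)
  if (n < 3) stop("need at least 3 cells")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  total <- n * (n - 1) / 2
  if (total <= n_pairs) {
    dz <- as.numeric(stats::dist(z))
    dy <- as.numeric(stats::dist(y))
  } else {
    idx <- withr::with_seed(seed, sample_pair_indices(n, n_pairs))
    dz <- sqrt(rowSums((z[idx$i, , drop = FALSE] - z[idx$j, , drop = FALSE])^2))
    dy <- sqrt(rowSums((y[idx$i, , drop = FALSE] - y[idx$j, , drop = FALSE])^2))
  }
  stats::cor(dz, dy)
}

# sample k distinct unordered pairs from n items via linear pair indices;
# row-major upper-triangle enumeration inverted exactly with findInterval
sample_pair_indices <- function(n, k) {
  total <- n * (n - 1) / 2
  lin <- sample(total, k) - 1  # 0-based
  i0 <- 0:(n - 2)
  offsets <- i0 * n - i0 * (i0 + 1) / 2  # start of row i in the enumeration
  i <- findInterval(lin, offsets) - 1
  j <- lin - (i * n - i * (i + 1) / 2) + i + 1
  list(i = as.integer(i + 1), j = as.integer(j + 1))
}

#' Mean silhouette width of reference labels in a latent space
#'
#' Euclidean-distance silhouette of the given cell labels evaluated on `Z`,
#' averaged over cells.
#'
#' @param Z Latent matrix (or `integrated_latent`).
#' @param labels Vector of cluster/cell-type labels, one per cell, at least
#'   two distinct values.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(Z, labels) {
  z <- as_matrix_input(Z)
  if (length(labels) != nrow(z)) stop("labels and Z have different lengths")
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) stop("need at least two distinct labels")
  sil <- cluster::silhouette(cl, stats::dist(z))
  mean(sil[, "sil_width"])
}

#' Louvain clustering ARI across a resolution sweep
#'
#' Builds a k-nearest-neighbor graph on `Z` (Euclidean, default 20
#' neighbors), runs Louvain community detection at each resolution with a
#' fixed seed, and scores each clustering against reference labels with the
#' adjusted Rand index.
#'
#' @param Z Latent matrix (or `integrated_latent`).
#' @param labels Reference labels, one per cell.
#' @param resolutions Numeric vector of Louvain resolutions
#'   (default 0.1, 0.2, ..., 2.0).
#' @param n_neighbors Neighbors in the kNN graph (default 20).
#' @param seed Seed fixing the Louvain runs.
#' @return Named numeric vector mapping resolution to ARI.
#' @export
louvain_ari_sweep <- function(Z, labels, resolutions = seq(0.1, 2.0, by = 0.1),
                              n_neighbors = 20, seed = 1) {
  z <- as_matrix_input(Z)
  if (length(labels) != nrow(z)) stop("labels and Z have different lengths")
  if (length(resolutions) == 0) stop("resolutions must be non-empty")
  if (n_neighbors >= nrow(z)) stop("n_neighbors must be smaller than the cell count")
  g <- knn_graph(z, n_neighbors)
  ari <- vapply(resolutions, function(res) {
    cl <- withr::with_seed(seed,
      igraph::cluster_louvain(g, resolution = res)$membership)
    mclust::adjustedRandIndex(cl, labels)
  }, numeric(1))
  stats::setNames(ari, format(resolutions, trim = TRUE))
}

#' Cluster a latent space with Louvain at one resolution
#'
#' @inheritParams louvain_ari_sweep
#' @param resolution Single Louvain resolution.
#' @return Integer cluster membership vector.
#' @export
louvain_cluster <- function(Z, resolution = 1.0, n_neighbors = 20, seed = 1) {
  z <- as_matrix_input(Z)
  if (n_neighbors >= nrow(z)) stop("n_neighbors must be smaller than the cell count")
  g <- knn_graph(z, n_neighbors)
  withr::with_seed(seed, igraph::cluster_louvain(g, resolution = resolution)$membership)
}

knn_graph <- function(z, n_neighbors) {
  nn <- RANN::nn2(z, k = n_neighbors + 1)$nn.idx[, -1, drop = FALSE]
  edges <- cbind(rep(seq_len(nrow(z)), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Full benchmark report for one latent space
#'
#' Computes the three evaluation metrics against reference labels: the
#' structure score of the latent space against each modality embedding (and
#' its mean), the Euclidean silhouette of the labels, and the Louvain ARI
#' sweep.
#'
#' @param Z Latent matrix (or `integrated_latent`).
#' @param embeddings Named list of per-modality `reduced_embedding`s.
#' @param labels Reference labels, one per cell.
#' @param resolutions Louvain resolutions for the ARI sweep.
#' @param n_pairs Pair-sampling cap for the structure score.
#' @param n_neighbors kNN graph neighbors.
#' @param seed Seed for pair sampling and Louvain.
#' @param labels_name Provenance string stored in the report.
#' @return A `benchmark_report` list.
#' @export
benchmark_report <- function(Z, embeddings, labels,
                             resolutions = seq(0.1, 2.0, by = 0.1),
                             n_pairs = 1e5, n_neighbors = 20, seed = 1,
                             labels_name = "reference") {
  structure_per_modality <- vapply(embeddings, function(Y) {
    structure_score(Z, Y, n_pairs = n_pairs, seed = seed)
  }, numeric(1))
  n <- nrow(as_matrix_input(Z))
  structure(
    list(structure_per_modality = as.list(structure_per_modality),
         structure_mean = mean(structure_per_modality),
         silhouette = silhouette_score(Z, labels),
         ari_by_resolution = as.list(louvain_ari_sweep(
           Z, labels, resolutions, n_neighbors, seed)),
         labels_name = labels_name,
         n_pairs_sampled = as.integer(min(n_pairs, n * (n - 1) / 2)),
         n_neighbors = n_neighbors, seed = seed, schema_version = "1.0"),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> structure mean %.3f | silhouette %.3f | best ARI %.3f\n",
              x$structure_mean, x$silhouette,
              max(unlist(x$ari_by_resolution))))
  invisible(x)
}

#' Rank methods across benchmark reports
#'
#' Turns a set of benchmark reports (one per method, same cells and labels)
#' into per-metric ranks — 1 for the worst score, M for the best, average
#' ranks on ties — and a summed total. Metrics used: mean structure score,
#' silhouette, and the best ARI over the resolution sweep.
#'
#' @param reports Named list of `benchmark_report`s (at least two).
#' @return Data frame with one row per method, per-metric ranks and `total`,
#'   ordered best first.
#' @export
rank_methods <- function(reports) {
  if (length(reports) < 2) stop("need at least two methods to rank")
  ln <- unique(vapply(reports, function(r) r$labels_name, character(1)))
  if (length(ln) != 1) stop("reports use inconsistent label sets: ",
                            paste(ln, collapse = ", "))
  scores <- data.frame(
    structure = vapply(reports, function(r) r$structure_mean, numeric(1)),
    silhouette = vapply(reports, function(r) r$silhouette, numeric(1)),
    ari = vapply(reports, function(r) max(unlist(r$ari_by_resolution)), numeric(1))
  )
  ranks <- as.data.frame(lapply(scores, rank))
  ranks$total <- rowSums(ranks)
  out <- cbind(method = names(reports), ranks)
  rownames(out) <- NULL
  out[order(-out$total), ]
}
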