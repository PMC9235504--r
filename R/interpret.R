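#' Score original features against canonical components
#'
#' Links molecular features of one modality to the shared latent space by
#' the cross-product U = X' Z, where X is the normalized (RNA/protein) or
#' TF-IDF (ATAC) cell-by-feature matrix and Z the latent matrix with columns
#' standardized to unit variance so scores are comparable across components.
#' Column i of U scores every feature against canonical component i.
#'
#' @param X A `modality_matrix` at stage `"normalized"` or `"tfidf"`.
#' @param latent An `integrated_latent` (or plain latent matrix) over the
#'   same cells in the same order.
#' @return A `feature_score_matrix` with the features x k score matrix `U`.
#' @export
feature_scores <- function(X, latent) {
  stopifnot(inherits(X, "modality_matrix"))
  if (!X$stage %in% c("normalized", "tfidf")) {
    stop("feature scoring expects a normalized or TF-IDF matrix, not raw counts")
  }
  Z <- if (inherits(latent, "integrated_latent")) latent$Z else as.matrix(latent)
  if (!is.null(rownames(Z))) check_same_cells(X$cell_ids, rownames(Z), "matrix and latent")
  else if (nrow(Z) != nrow(X$values)) stop("matrix and latent have different cell counts")
  sdz <- apply(Z, 2, stats::sd)
  sdz[sdz == 0] <- 1  # all-zero component stays all-zero
  Zs <- sweep(Z, 2, sdz, "/")
  U <- as.matrix(Matrix::crossprod(X$values, Zs))
  cc_names <- colnames(Z)
  if (is.null(cc_names)) cc_names <- paste0("CC", seq_len(ncol(Z)))
  dimnames(U) <- list(X$feature_ids, cc_names)
  structure(
    list(U = U, feature_ids = X$feature_ids, modality = X$modality,
         cc_names = cc_names),
    class = "feature_score_matrix"
  )
}

#' @export
print.feature_score_matrix <- function(x, ...) {
  cat(sprintf("<feature_score_matrix> %s: %d features x %d components\n",
              x$modality, nrow(x$U), ncol(x$U)))
  invisible(x)
}

#' Top-ranked features for one canonical component
#'
#' @param scores A `feature_score_matrix`.
#' @param component Component index (1-based).
#' @param n_top Number of features to return (default 10); truncated with a
#'   warning if it exceeds the feature count.
#' @param direction `"positive"` for the largest scores, `"negative"` for
#'   the smallest. Ties break deterministically by feature id.
#' @return A data frame with `feature_id` and `score`, best first.
#' @export
top_features <- function(scores, component = 1, n_top = 10,
                         direction = c("positive", "negative")) {
  stopifnot(inherits(scores, "feature_score_matrix"))
  direction <- match.arg(direction)
  k <- ncol(scores$U)
  if (component < 1 || component > k) {
    stop(sprintf("component %d out of range 1..%d", component, k))
  }
  nf <- nrow(scores$U)
  if (n_top > nf) {
    warning(sprintf("n_top (%d) exceeds feature count (%d); truncating", n_top, nf))
    n_top <- nf
  }
  u <- scores$U[, component]
  ord <- if (direction == "positive") order(-u, scores$feature_ids)
         else order(u, scores$feature_ids)
  sel <- ord[seq_len(n_top)]
  data.frame(feature_id = scores$feature_ids[sel], score = unname(u[sel]),
             row.names = NULL)
}

#' Per-cell scores of one canonical component
#'
#' Extracts one latent dimension as a named vector (cell ids as names),
#' e.g. for coloring an embedding plot by component activity.
#'
#' @param latent An `integrated_latent`.
#' @param component Component index (1-based).
#' @return Named numeric vector of length n_cells.
#' @export
cell_scores <- function(latent, component = 1) {
  stopifnot(inherits(latent, "integrated_latent"))
  if (component < 1 || component > ncol(latent$Z)) {
    stop(sprintf("component %d out of range 1..%d", component, ncol(latent$Z)))
  }
  stats::setNames(latent$Z[, component], rownames(latent$Z))
}

#' Export top peaks of a component as BED
#'
#' Parses peak ids of the form `chr1:100-200` (or `chr1-100-200`) as 0-based
#' half-open intervals and writes the top `n_top` positive or negative peaks
#' for one component to a BED file with the score in column 5.
#'
#' @param scores A `feature_score_matrix` for the ATAC modality.
#' @param path Output BED path.
#' @inheritParams top_features
#' @return Invisibly, the data frame written.
#' @export
write_top_peaks_bed <- function(scores, path, component = 1, n_top = 10,
                                direction = c("positive", "negative")) {
  tf <- top_features(scores, component, n_top, direction)
  parts <- parse_peak_ids(tf$feature_id)
  bed <- data.frame(chrom = parts$chrom, start = parts$start, end = parts$end,
                    name = tf$feature_id, score = tf$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}

parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+?)[:-]([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop(sprintf("cannot parse peak id '%s' as chrom:start-end", ids[which(bad)[1]]))
  }
  list(chrom = vapply(m, `[`, character(1), 2),
       start = as.integer(vapply(m, `[`, character(1), 3)),
       end = as.integer(vapply(m, `[`, character(1), 4)))
}
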