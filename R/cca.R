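#' Fit canonical correlation analysis between two reduced embeddings
#'
#' Finds paired weight vectors w1, w2 maximizing the correlation of the
#' projected variates z1 = Y1 w1 and z2 = Y2 w2, each new pair orthogonal
#' (uncorrelated) to all previous ones. The solver works on column-centered
#' data and reduces the generalized eigenproblem
#'
#'   S12 S22^-1 S21 w = rho^2 S11 w
#'
#' to an ordinary symmetric eigenproblem through a Cholesky factor of S11.
#' A small ridge (1e-8 times the mean diagonal) is added to both within-block
#' covariances for numerical stability. Canonical variates are scaled to unit
#' variance so the two modalities contribute equally to the summed latent
#' space, and signs are fixed so each pair correlates positively and the
#' largest-magnitude entry of w1 is positive.
#'
#' @param Y1,Y2 `reduced_embedding` objects (or plain matrices with cell ids
#'   as rownames) over the same cells in the same order.
#' @param ridge Relative ridge added to the within-block covariance diagonals.
#' @return A `cca_model` with weight matrices `W1` (p1 x k_hat) and `W2`
#'   (p2 x k_hat), canonical `correlations` (non-increasing, in `[0, 1]`),
#'   column `centers1`/`centers2` used for centering, `n_cells` and
#'   `k_hat = min(p1, p2)`.
#' @export
fit_cca <- function(Y1, Y2, ridge = 1e-8) {
  y1 <- as_matrix_input(Y1); y2 <- as_matrix_input(Y2)
  ids1 <- embedding_ids(Y1, y1); ids2 <- embedding_ids(Y2, y2)
  check_same_cells(ids1, ids2, "embeddings")
  n <- nrow(y1); p1 <- ncol(y1); p2 <- ncol(y2)
  if (n <= max(p1, p2)) {
    stop(sprintf("need more cells (%d) than embedding dimensions (%d) for a full-rank covariance",
                 n, max(p1, p2)))
  }
  c1 <- colMeans(y1); c2 <- colMeans(y2)
  y1c <- sweep(y1, 2, c1, "-"); y2c <- sweep(y2, 2, c2, "-")
  S11 <- crossprod(y1c) / (n - 1)
  S22 <- crossprod(y2c) / (n - 1)
  S12 <- crossprod(y1c, y2c) / (n - 1)
  diag(S11) <- diag(S11) + ridge * mean(diag(S11))
  diag(S22) <- diag(S22) + ridge * mean(diag(S22))

  # B = S12 S22^-1 S21; whiten by chol(S11) and solve the symmetric problem
  B <- S12 %*% solve(S22, t(S12))
  R1 <- chol(S11)
  tmp <- forwardsolve(t(R1), B)            # R1^-T B
  M <- t(forwardsolve(t(R1), t(tmp)))      # R1^-T B R1^-1
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  k_hat <- min(p1, p2)
  lambda <- pmin(pmax(eig$values[seq_len(k_hat)], 0), 1)
  W1 <- backsolve(R1, eig$vectors[, seq_len(k_hat), drop = FALSE])

  Z1 <- y1c %*% W1
  sd1 <- apply(Z1, 2, stats::sd)
  sd1[sd1 == 0] <- 1
  W1 <- sweep(W1, 2, sd1, "/")

  W2 <- solve(S22, t(S12) %*% W1)
  Z2 <- y2c %*% W2
  sd2 <- apply(Z2, 2, stats::sd)
  sd2[sd2 == 0] <- 1
  W2 <- sweep(W2, 2, sd2, "/")

  # empirical canonical correlations on unit-variance variates
  Z1 <- y1c %*% W1; Z2 <- y2c %*% W2
  rho <- vapply(seq_len(k_hat), function(i) {
    s1 <- stats::sd(Z1[, i]); s2 <- stats::sd(Z2[, i])
    if (s1 == 0 || s2 == 0) 0 else stats::cor(Z1[, i], Z2[, i])
  }, numeric(1))
  flip2 <- rho < 0
  W2[, flip2] <- -W2[, flip2]
  rho <- abs(rho)
  # pairwise sign convention: largest |entry| of w1 positive, both flipped
  for (j in seq_len(k_hat)) {
    i <- which.max(abs(W1[, j]))
    if (W1[i, j] < 0) {
      W1[, j] <- -W1[, j]
      W2[, j] <- -W2[, j]
    }
  }
  rownames(W1) <- colnames(y1); rownames(W2) <- colnames(y2)
  colnames(W1) <- colnames(W2) <- paste0("CC", seq_len(k_hat))
  structure(
    list(W1 = W1, W2 = W2, correlations = rho, eigenvalues = lambda,
         centers1 = c1, centers2 = c2, n_cells = n, k_hat = k_hat,
         cell_ids = ids1),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> %d cells, k_hat = %d\n", x$n_cells, x$k_hat))
  cat("canonical correlations:",
      paste(sprintf("%.3f", utils::head(x$correlations, 8)), collapse = " "),
      if (x$k_hat > 8) "..." else "", "\n")
  invisible(x)
}

#' Project embeddings through a fitted CCA model
#'
#' Applies the model's centering and canonical weights to produce the
#' per-modality canonical variate matrices Z1 = Y1 W1 and Z2 = Y2 W2.
#'
#' @param model A `cca_model`.
#' @param Y1,Y2 Embeddings conforming to the model's dimensions.
#' @return A `projection_pair` with matrices `Z1`, `Z2` (cells x k_hat).
#' @export
project_cca <- function(model, Y1, Y2) {
  stopifnot(inherits(model, "cca_model"))
  y1 <- as_matrix_input(Y1); y2 <- as_matrix_input(Y2)
  if (ncol(y1) != nrow(model$W1)) {
    stop(sprintf("Y1 has %d dims but model expects %d", ncol(y1), nrow(model$W1)))
  }
  if (ncol(y2) != nrow(model$W2)) {
    stop(sprintf("Y2 has %d dims but model expects %d", ncol(y2), nrow(model$W2)))
  }
  if (nrow(y1) != nrow(y2)) stop("Y1 and Y2 have different cell counts")
  Z1 <- sweep(y1, 2, model$centers1, "-") %*% model$W1
  Z2 <- sweep(y2, 2, model$centers2, "-") %*% model$W2
  ids <- embedding_ids(Y1, y1)
  rownames(Z1) <- rownames(Z2) <- ids
  structure(list(Z1 = Z1, Z2 = Z2, cell_ids = ids, n_cells = nrow(y1),
                 p1 = ncol(y1), p2 = ncol(y2)),
            class = "projection_pair")
}

#' @export
print.projection_pair <- function(x, ...) {
  cat(sprintf("<projection_pair> %d cells x %d components\n",
              x$n_cells, ncol(x$Z1)))
  invisible(x)
}

#' Sum the two modality projections into one latent matrix
#'
#' The shared representation is the elementwise sum Z = Z1 + Z2 of the
#' unit-variance canonical variates of the two modalities.
#'
#' @param pair A `projection_pair`.
#' @return A cells x k_hat numeric matrix.
#' @export
sum_latent <- function(pair) {
  stopifnot(inherits(pair, "projection_pair"))
  if (!identical(dim(pair$Z1), dim(pair$Z2))) {
    stop("Z1 and Z2 have mismatched shapes")
  }
  pair$Z1 + pair$Z2
}

embedding_ids <- function(obj, values) {
  if (inherits(obj, "reduced_embedding")) obj$cell_ids
  else if (inherits(obj, "integrated_latent")) rownames(obj$Z)
  else if (!is.null(rownames(values))) rownames(values)
  else paste0("cell", seq_len(nrow(values)))
}
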