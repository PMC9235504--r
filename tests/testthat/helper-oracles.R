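# Independent oracles and small fixture builders shared across tests.
# These deliberately use different algorithms than the package code paths.

# canonical correlations via whitening + SVD: svd(S11^-1/2 S12 S22^-1/2)
cca_whitening_oracle <- function(Y1, Y2) {
  y1 <- scale(Y1, scale = FALSE)
  y2 <- scale(Y2, scale = FALSE)
  n <- nrow(y1)
  S11 <- crossprod(y1) / (n - 1)
  S22 <- crossprod(y2) / (n - 1)
  S12 <- crossprod(y1, y2) / (n - 1)
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  }
  d <- svd(inv_sqrt(S11) %*% S12 %*% inv_sqrt(S22))$d
  d[seq_len(min(ncol(Y1), ncol(Y2)))]
}

# structure score by explicit double loop over all cell pairs
structure_brute <- function(Z, Y) {
  n <- nrow(Z)
  dz <- c(); dy <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dz <- c(dz, sqrt(sum((Z[i, ] - Z[j, ])^2)))
      dy <- c(dy, sqrt(sum((Y[i, ] - Y[j, ])^2)))
    }
  }
  cor(dz, dy)
}

# textbook silhouette: a(i) mean within-cluster distance, b(i) smallest
# mean distance to another cluster, s = (b - a) / max(a, b)
silhouette_brute <- function(Z, labels) {
  n <- nrow(Z)
  d <- as.matrix(dist(Z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# adjusted Rand index from the contingency-table closed form
ari_brute <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(sum(tab))
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# quick builder for a raw modality_matrix from a dense count matrix
raw_mm <- function(counts, modality = "rna") {
  modality_matrix(counts, paste0("c", seq_len(nrow(counts))),
                  paste0("f", seq_len(ncol(counts))), modality, "raw")
}

# embedding over n cells with iid standard-normal scores
random_embedding <- function(n, p, seed) {
  withr::with_seed(seed,
    reduced_embedding(matrix(rnorm(n * p), n, p),
                      sprintf("cell%05d", seq_len(n)), "external"))
}

# projection_pair built directly from two variate matrices (for unit tests
# of the component filter, bypassing the CCA fit)
fake_pair <- function(Z1, Z2, p1 = ncol(Z1), p2 = ncol(Z2)) {
  rownames(Z1) <- rownames(Z2) <- paste0("c", seq_len(nrow(Z1)))
  structure(list(Z1 = Z1, Z2 = Z2, cell_ids = rownames(Z1),
                 n_cells = nrow(Z1), p1 = p1, p2 = p2),
            class = "projection_pair")
}

# bi-modal fixture with genes planted on a single shared factor: returns a
# normalized-stage RNA-like matrix whose first `n_planted` genes load on
# the factor, plus the factor itself and embeddings that share it
planted_loading_fixture <- function(n = 500, n_genes = 100, n_planted = 5,
                                    p1 = 8, p2 = 6, beta = 2, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    ids <- sprintf("cell%05d", seq_len(n))
    X <- matrix(rnorm(n * n_genes, sd = 1), n, n_genes)
    X[, seq_len(n_planted)] <- X[, seq_len(n_planted)] * 0.2 + outer(f, rep(beta, n_planted))
    Y1 <- matrix(rnorm(n * p1), n, p1); Y1[, 1] <- f + rnorm(n, sd = 0.2)
    Y2 <- matrix(rnorm(n * p2), n, p2); Y2[, 1] <- f + rnorm(n, sd = 0.2)
    Q1 <- qr.Q(qr(matrix(rnorm(p1 * p1), p1, p1)))
    Q2 <- qr.Q(qr(matrix(rnorm(p2 * p2), p2, p2)))
    list(
      X = modality_matrix(X, ids, sprintf("gene%03d", seq_len(n_genes)),
                          "rna", "normalized"),
      factor = f,
      Y1 = reduced_embedding(Y1 %*% Q1, ids, "external"),
      Y2 = reduced_embedding(Y2 %*% Q2, ids, "external"),
      planted = sprintf("gene%03d", seq_len(n_planted))
    )
  })
}
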