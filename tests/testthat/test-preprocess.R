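test_that("log-normalization matches the per-entry formula", {
  # equal counts with scale factor 2: both entries become log(2)
  mm <- raw_mm(matrix(c(1, 1), 1, 2))
  out <- lognormalize_rna(mm, scale_factor = 2)
  expect_equal(as.numeric(out$values), rep(log(2), 2))
  expect_identical(out$stage, "normalized")

  # general case against direct scalar evaluation of log1p(c * sf / total)
  withr::with_seed(5, counts <- matrix(rpois(12, 4) + 1, 3, 4))
  res <- lognormalize_rna(raw_mm(counts), scale_factor = 1e4)
  expected <- log1p(counts / rowSums(counts) * 1e4)
  expect_equal(unname(as.matrix(res$values)), expected, tolerance = 1e-12)

  # sparse and dense inputs give identical results
  sp <- lognormalize_rna(raw_mm(Matrix::Matrix(counts, sparse = TRUE)))
  dn <- lognormalize_rna(raw_mm(counts))
  expect_equal(as.matrix(sp$values), as.matrix(dn$values), tolerance = 1e-12)
})

test_that("log-normalization refuses empty cells, naming the barcode", {
  counts <- matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE)
  expect_error(lognormalize_rna(raw_mm(counts)), "c2")
})

test_that("HVG selection ranks planted overdispersed features first", {
  # count-like data with a real mean-variance trend; 5 planted genes share
  # the mean profile of their neighbors but are strongly overdispersed
  n <- 300; p <- 300
  withr::with_seed(7, {
    mu <- exp(runif(p, log(0.5), log(20)))
    counts <- sapply(seq_len(p), function(j) rnbinom(n, mu = mu[j], size = 5))
    planted <- sample(p, 5)
    mu_pl <- runif(5, 5, 20)
    counts[, planted] <- sapply(mu_pl, function(m) rnbinom(n, mu = m, size = 0.05))
  })
  counts[rowSums(counts) == 0, 1] <- 1
  norm <- lognormalize_rna(raw_mm(counts))
  top5 <- select_hvg(norm, 5)
  expect_setequal(top5$feature_ids, paste0("f", planted))
  mm <- norm; x <- as.matrix(norm$values)

  # constant features rank last: selecting all but one drops the constant
  x2 <- x; x2[, 3] <- 7
  mm2 <- modality_matrix(x2, paste0("c", 1:n), paste0("f", 1:p), "rna", "normalized")
  sel <- select_hvg(mm2, p - 1)
  expect_false("f3" %in% sel$feature_ids)

  # full selection preserves the original column order
  all_sel <- select_hvg(mm, p)
  expect_identical(all_sel$feature_ids, mm$feature_ids)
  expect_error(select_hvg(mm, p + 1), "exceeds")
})

test_that("scaled PCA reconstructs rank-2 data and centers scores", {
  n <- 60
  withr::with_seed(11, {
    basis <- matrix(rnorm(2 * 10), 2, 10)
    scores <- matrix(rnorm(n * 2), n, 2)
  })
  x <- scores %*% basis
  mm <- modality_matrix(x, paste0("c", 1:n), paste0("f", 1:10), "rna", "normalized")
  emb <- scale_and_pca(mm, n_components = 2)
  # reconstruction from 2 PCs equals the centered-scaled matrix exactly
  xs <- scale(x)
  recon <- emb$values %*% t(emb$loadings)
  expect_lt(max(abs(recon - xs)), 1e-8)
  expect_lt(max(abs(colMeans(emb$values))), 1e-8)
})

test_that("scaled PCA spreads variance evenly on isotropic input", {
  withr::with_seed(3, x <- matrix(rnorm(3000 * 8), 3000, 8) %*%
                     qr.Q(qr(matrix(rnorm(64), 8, 8))))
  mm <- modality_matrix(x, paste0("c", 1:3000), paste0("f", 1:8), "rna", "normalized")
  emb <- scale_and_pca(mm, 4)
  v <- apply(emb$values, 2, var)
  expect_lt(max(v) / min(v), 1.3)
})

test_that("constant features are scaled to zero with a warning, not an error", {
  withr::with_seed(2, x <- matrix(rnorm(40 * 6), 40, 6))
  x[, 4] <- 2.5
  mm <- modality_matrix(x, paste0("c", 1:40), paste0("f", 1:6), "rna", "normalized")
  expect_warning(emb <- scale_and_pca(mm, 2), "constant")
  expect_s3_class(emb, "reduced_embedding")
})

test_that("CLR transform matches log1p minus per-feature mean log1p", {
  counts <- matrix(c(1, 5, 0, 9, 3, 3, 2, 0), 4, 2)
  mm <- raw_mm(counts, "protein")
  out <- clr_normalize_protein(mm)
  expected <- apply(counts, 2, function(x) log1p(x) - mean(log1p(x)))
  expect_equal(unname(as.matrix(out$values)), expected, tolerance = 1e-12)

  # a feature constant across cells maps to zero
  const <- raw_mm(cbind(rep(4, 4), c(1, 2, 3, 4)), "protein")
  expect_equal(as.numeric(clr_normalize_protein(const)$values[, 1]), rep(0, 4))
})

test_that("CLR across cells does not remove per-cell scaling", {
  withr::with_seed(4, counts <- matrix(rpois(20, 5), 5, 4))
  base <- clr_normalize_protein(raw_mm(counts, "protein"))
  doubled <- counts; doubled[2, ] <- doubled[2, ] * 2
  out <- clr_normalize_protein(raw_mm(doubled, "protein"))
  # the doubled cell's transformed profile changes: margin-2 CLR is not a
  # per-cell compositional normalization
  expect_gt(max(abs(out$values[2, ] - base$values[2, ])), 0.1)
})

test_that("TF-IDF matches the scalar formula and applies the q0 peak filter", {
  counts <- matrix(c(2, 0, 1,
                     0, 3, 1,
                     1, 1, 0), 3, 3, byrow = TRUE)
  mm <- raw_mm(counts, "atac")
  out <- tfidf(mm)
  n <- nrow(counts)
  expected <- log1p(1e4 * (counts / rowSums(counts)) *
                    rep(n / colSums(counts > 0), each = n))
  expect_equal(unname(as.matrix(out$values)), expected, tolerance = 1e-12)
  expect_identical(out$stage, "tfidf")

  # peak detected in every cell with equal counts and totals: constant column
  sym <- raw_mm(matrix(1, 4, 3), "atac")
  vals <- as.matrix(tfidf(sym)$values)
  expect_equal(max(apply(vals, 2, function(col) diff(range(col)))), 0)

  # all-zero peak is dropped with a warning
  z <- counts; z <- cbind(z, 0)
  expect_warning(out2 <- tfidf(raw_mm(z, "atac")), "no cell")
  expect_identical(ncol(out2$values), 3L)
  # zero-count cell is an error
  z2 <- rbind(counts, 0)
  expect_error(suppressWarnings(tfidf(raw_mm(z2, "atac"))), "zero total")
})

test_that("LSI drops the depth component and keeps singular values ordered", {
  n <- 300; p <- 80
  withr::with_seed(21, {
    depth <- exp(rnorm(n, sd = 0.8))
    prob <- matrix(runif(n * p, 0.02, 0.3), n, p) * depth
    counts <- matrix(rbinom(n * p, 3, pmin(prob, 0.9)), n, p)
    counts[rowSums(counts) == 0, 1] <- 1
  })
  tf <- suppressWarnings(tfidf(raw_mm(counts, "atac")))
  full <- lsi_reduce(tf, n_components = 6, drop_first = FALSE)
  expect_true(all(diff(full$singular_values) <= 1e-8))

  dropped <- lsi_reduce(tf, n_components = 6, drop_first = TRUE)
  expect_identical(ncol(dropped$values), 5L)
  expect_identical(dropped$dropped_dims, 1L)

  # component 1 tracks per-cell totals more than any retained component
  totals <- rowSums(counts)
  cor1 <- abs(cor(full$values[, 1], totals))
  cor_rest <- apply(dropped$values, 2, function(z) abs(cor(z, totals)))
  expect_gt(cor1, max(cor_rest))
  expect_error(lsi_reduce(tf, n_components = 1000), "exceeds")
})

test_that("reduction recipes are deterministic and permutation-consistent", {
  withr::with_seed(31, counts <- matrix(rnbinom(150 * 40, mu = 3, size = 2), 150, 40))
  counts[rowSums(counts) == 0, 1] <- 1
  mm <- raw_mm(counts)
  e1 <- preprocess_modality(mm, n_dims = 5, n_hvg = 30)
  e2 <- preprocess_modality(mm, n_dims = 5, n_hvg = 30)
  expect_identical(e1$values, e2$values)

  # permuting feature columns leaves the cell-space embedding unchanged
  perm <- sample(ncol(counts))
  mmp <- modality_matrix(counts[, perm], mm$cell_ids, mm$feature_ids[perm],
                         "rna", "raw")
  ep <- preprocess_modality(mmp, n_dims = 5, n_hvg = 30)
  expect_equal(ep$values, e1$values, tolerance = 1e-8)
})
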