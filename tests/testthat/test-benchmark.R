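test_that("structure score equals the brute-force double loop on small data", {
  withr::with_seed(1, {
    Z <- matrix(rnorm(50 * 4), 50, 4)
    Y <- matrix(rnorm(50 * 6), 50, 6)
  })
  expect_equal(structure_score(Z, Y, n_pairs = 1e5),
               structure_brute(Z, Y), tolerance = 1e-10)
  expect_equal(structure_score(Z, Z), 1, tolerance = 1e-12)
  # proportional spaces have identical distance structure
  expect_equal(structure_score(Z, Z * 3.7), 1, tolerance = 1e-12)
})

test_that("structure score is invariant to rigid motions and reproducible when sampled", {
  withr::with_seed(2, {
    Z <- matrix(rnorm(600 * 5), 600, 5)
    Y <- Z[, c(2, 1, 3, 4, 5)] + matrix(rnorm(600 * 5, sd = 0.5), 600, 5)
    Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  })
  base <- structure_score(Z, Y, n_pairs = 2000, seed = 9)
  rot <- structure_score(Z %*% Q + 3, Y, n_pairs = 2000, seed = 9)
  expect_equal(base, rot, tolerance = 1e-10)
  expect_identical(base, structure_score(Z, Y, n_pairs = 2000, seed = 9))
  # a different sampling seed gives a close but not identical estimate
  other <- structure_score(Z, Y, n_pairs = 2000, seed = 10)
  expect_false(identical(base, other))
  expect_lt(abs(base - other), 0.1)
  expect_error(structure_score(Z[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("sampled pair indices are valid distinct pairs", {
  idx <- withr::with_seed(3, jointCCA:::sample_pair_indices(100, 500))
  expect_true(all(idx$i >= 1 & idx$i < idx$j & idx$j <= 100))
  expect_identical(anyDuplicated(paste(idx$i, idx$j)), 0L)
})

test_that("silhouette matches the textbook formula and expected extremes", {
  withr::with_seed(4, {
    Z <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, sd = 0.1) + 5, 10, 2))
    labels <- rep(c("a", "b"), each = 10)
  })
  expect_equal(silhouette_score(Z, labels), silhouette_brute(Z, labels),
               tolerance = 1e-10)
  expect_gt(silhouette_score(Z, labels), 0.9)

  # random labels on one blob have ~zero silhouette
  withr::with_seed(5, {
    blob <- matrix(rnorm(500 * 3), 500, 3)
    rnd <- sample(c("x", "y"), 500, replace = TRUE)
  })
  expect_lt(abs(silhouette_score(blob, rnd)), 0.1)
  expect_error(silhouette_score(blob, rep("x", 500)), "two distinct")
})

test_that("ARI agrees with the contingency closed form", {
  expect_equal(mclust::adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_brute(c(1, 1, 2, 2), c(1, 2, 1, 2)), tolerance = 1e-12)
  withr::with_seed(6, {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
  })
  expect_equal(mclust::adjustedRandIndex(a, b), ari_brute(a, b),
               tolerance = 1e-12)
  expect_equal(ari_brute(a, a), 1)
})

test_that("Louvain sweep agrees with its own clustering and rejects bad inputs", {
  withr::with_seed(7, {
    Z <- rbind(matrix(rnorm(300 * 4), 300, 4),
               matrix(rnorm(300 * 4) + 4, 300, 4))
    labels <- rep(1:2, each = 300)
  })
  own <- louvain_cluster(Z, resolution = 0.5, seed = 11)
  ari <- louvain_ari_sweep(Z, own, resolutions = 0.5, seed = 11)
  expect_equal(unname(ari), 1)
  sweep_res <- louvain_ari_sweep(Z, labels, resolutions = c(0.1, 0.5, 1), seed = 11)
  expect_identical(names(sweep_res), c("0.1", "0.5", "1.0"))
  expect_gt(max(sweep_res), 0.95)

  # random labels give ~zero ARI against any clustering
  withr::with_seed(8, rnd <- sample(1:5, 600, replace = TRUE))
  expect_lt(max(abs(louvain_ari_sweep(Z, rnd, resolutions = c(0.5, 1), seed = 11))),
            0.05)
  expect_error(louvain_ari_sweep(Z, labels, n_neighbors = 600), "smaller")
  expect_error(louvain_ari_sweep(Z, labels, resolutions = numeric()), "non-empty")
})

test_that("benchmark report aggregates all three metrics", {
  withr::with_seed(9, {
    Z <- rbind(matrix(rnorm(200 * 3), 200, 3),
               matrix(rnorm(200 * 3) + 3, 200, 3))
    labels <- rep(c("p1", "p2"), each = 200)
  })
  ids <- sprintf("c%04d", 1:400); rownames(Z) <- ids
  emb <- list(m1 = reduced_embedding(Z + matrix(rnorm(1200, sd = 0.2), 400, 3),
                                     ids, "external"),
              m2 = reduced_embedding(Z + matrix(rnorm(1200, sd = 0.4), 400, 3),
                                     ids, "external"))
  rep <- benchmark_report(Z, emb, labels, resolutions = c(0.5, 1), seed = 2)
  expect_named(rep$structure_per_modality, c("m1", "m2"))
  expect_equal(rep$structure_mean,
               mean(unlist(rep$structure_per_modality)), tolerance = 1e-12)
  expect_true(rep$silhouette >= -1 && rep$silhouette <= 1)
  expect_true(all(unlist(rep$ari_by_resolution) <= 1))
})

test_that("method ranking follows per-metric ranks with tie averaging", {
  mk_report <- function(st, sil, ari) {
    structure(list(structure_per_modality = list(m = st), structure_mean = st,
                   silhouette = sil, ari_by_resolution = list(`1` = ari),
                   labels_name = "labels.csv", n_pairs_sampled = 10L),
              class = "benchmark_report")
  }
  reports <- list(good = mk_report(0.9, 0.5, 0.95),
                  mid = mk_report(0.5, 0.5, 0.60),
                  bad = mk_report(0.1, 0.2, 0.20))
  rk <- rank_methods(reports)
  expect_identical(rk$method, c("good", "mid", "bad"))
  # hand-computed: good 3 + 2.5 + 3, mid 2 + 2.5 + 2, bad 1 + 1 + 1
  expect_equal(rk$total, c(8.5, 6.5, 3))

  reports$bad$labels_name <- "other.csv"
  expect_error(rank_methods(reports), "inconsistent")
  expect_error(rank_methods(reports["good"]), "at least two")
})
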