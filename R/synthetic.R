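#' Simulate a multimodal single-cell dataset with shared structure
#'
#' Generates count matrices for two or more modalities measured on the same
#' cells, all driven by one shared low-dimensional latent space: population
#' centers are drawn in latent space, each cell is its population center
#' plus Gaussian jitter, and modality-specific linear loadings map the
#' latent factors to log-rates. RNA and protein counts are negative
#' binomial (overdispersed); ATAC counts are sparse near-binary
#' (Bernoulli detection with Poisson thickening). Per-cell depth factors
#' are lognormal. Everything is reproducible from `seed`.
#'
#' @param n_cells Number of cells (default 2000).
#' @param n_populations Number of discrete populations (default 3).
#' @param latent_dim Shared latent dimensionality (default 10); must be at
#'   least `n_populations - 1`.
#' @param modality_specs Named list; each element a list with `n_features`
#'   and `family` (`"nb"` for RNA/protein, `"bp"` for ATAC). Default: a
#'   bi-modal RNA (1500 genes) + ATAC (3000 peaks) design.
#' @param noise_sd Within-population jitter of latent factors (default 1).
#' @param depth_variation Lognormal sd of per-cell depth factors
#'   (default 0.3).
#' @param pop_separation Pairwise Euclidean distance between population
#'   centers, in units of the within-population jitter when
#'   `noise_sd = 1` (default 5.5). Centers form a regular simplex in a
#'   randomly oriented `n_populations - 1` dimensional subspace of the
#'   latent space, so every pair of populations is equally separated.
#' @param loading_sd Sd of loading entries mapping factors to log-rates.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion;
#'   default dispersion 0.5).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`: `modalities` (named list of raw
#'   `modality_matrix`), `labels` (population per cell), `latent_true`,
#'   `loadings`, `params`.
#' @export
generate_multimodal <- function(n_cells = 2000, n_populations = 3,
                                latent_dim = 10,
                                modality_specs = default_modality_specs(),
                                noise_sd = 1, depth_variation = 0.3,
                                pop_separation = 5.5, loading_sd = 0.2,
                                nb_dispersion = 0.5, seed = 1) {
  check_specs(modality_specs, latent_dim)
  if (latent_dim < n_populations - 1) {
    stop("latent_dim must be at least n_populations - 1")
  }
  withr::with_seed(seed, {
    centers <- simplex_centers(n_populations, latent_dim, pop_separation)
    labels <- sample(rep_len(seq_len(n_populations), n_cells))
    factors <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * latent_dim, sd = noise_sd), n_cells, latent_dim)
    build_dataset(factors, labels, modality_specs, depth_variation,
                  loading_sd, nb_dispersion,
                  params = list(n_cells = n_cells, n_populations = n_populations,
                                latent_dim = latent_dim, noise_sd = noise_sd,
                                depth_variation = depth_variation,
                                pop_separation = pop_separation,
                                loading_sd = loading_sd,
                                nb_dispersion = nb_dispersion, seed = seed,
                                null = FALSE))
  })
}

#' Simulate multimodal data with no shared structure
#'
#' Same count families and depth model as [generate_multimodal()], but each
#' modality is driven by its own independent latent factors, so the true
#' number of shared canonical components is zero. Used to calibrate the
#' component significance filter. No population labels are generated.
#'
#' @inheritParams generate_multimodal
#' @return A `synthetic_dataset` with `labels = NULL` and per-modality
#'   independent `latent_true` matrices.
#' @export
generate_null_multimodal <- function(n_cells = 2000,
                                     modality_specs = default_modality_specs(),
                                     latent_dim = 10, noise_sd = 1,
                                     depth_variation = 0.3, loading_sd = 0.2,
                                     nb_dispersion = 0.5, seed = 1) {
  check_specs(modality_specs, latent_dim)
  if (length(modality_specs) < 2) stop("need at least two modalities")
  withr::with_seed(seed, {
    mods <- list(); latents <- list(); loadings <- list()
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    for (nm in names(modality_specs)) {
      factors <- matrix(stats::rnorm(n_cells * latent_dim), n_cells, latent_dim)
      one <- build_dataset(factors, labels = NULL,
                           modality_specs[nm], depth_variation,
                           loading_sd, nb_dispersion, params = NULL)
      mods[[nm]] <- one$modalities[[nm]]
      latents[[nm]] <- factors
      loadings[[nm]] <- one$loadings[[nm]]
    }
    structure(
      list(modalities = mods, labels = NULL, latent_true = latents,
           loadings = loadings,
           params = list(n_cells = n_cells, latent_dim = latent_dim,
                         noise_sd = noise_sd,
                         depth_variation = depth_variation,
                         loading_sd = loading_sd,
                         nb_dispersion = nb_dispersion, seed = seed,
                         null = TRUE)),
      class = "synthetic_dataset"
    )
  })
}

# K population centers with equal pairwise distance `separation`, lying in
# a randomly oriented (K-1)-dimensional subspace of the d-dim latent space
simplex_centers <- function(K, d, separation) {
  E <- diag(K)
  E <- sweep(E, 2, colMeans(E))            # regular simplex, pairwise sqrt(2)
  dec <- svd(E, nu = K - 1, nv = 0)
  V <- dec$u %*% diag(dec$d[seq_len(K - 1)], K - 1, K - 1)  # K x (K-1) coords
  V <- V / sqrt(2) * separation
  Q <- qr.Q(qr(matrix(stats::rnorm(d * (K - 1)), d, K - 1)))
  V %*% t(Q)
}

default_modality_specs <- function() {
  list(rna = list(n_features = 1500, family = "nb"),
       atac = list(n_features = 3000, family = "bp"))
}

check_specs <- function(specs, latent_dim) {
  if (!is.list(specs) || is.null(names(specs)) || length(specs) < 1) {
    stop("modality_specs must be a named list")
  }
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (is.null(s$n_features) || is.null(s$family)) {
      stop(sprintf("modality_specs$%s needs n_features and family", nm))
    }
    if (!s$family %in% c("nb", "bp")) {
      stop(sprintf("unknown count family '%s' (use 'nb' or 'bp')", s$family))
    }
    if (s$n_features < latent_dim) {
      stop(sprintf("modality '%s': feature count (%d) below latent_dim (%d)",
                   nm, s$n_features, latent_dim))
    }
  }
  invisible(TRUE)
}

# draw counts for each modality from shared (or per-modality) factors;
# assumes the RNG is already seeded by the caller
build_dataset <- function(factors, labels, modality_specs, depth_variation,
                          loading_sd, nb_dispersion, params) {
  n_cells <- nrow(factors); d <- ncol(factors)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  mods <- list(); loadings <- list()
  for (nm in names(modality_specs)) {
    spec <- modality_specs[[nm]]
    s <- spec$n_features
    L <- matrix(stats::rnorm(d * s, sd = loading_sd), d, s)
    lograte <- factors %*% L
    depth <- stats::rlnorm(n_cells, meanlog = 0, sdlog = depth_variation)
    if (spec$family == "nb") {
      base <- log(2)
      mu <- depth * exp(base + sweep(lograte, 2, colMeans(lograte), "-"))
      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / nb_dispersion),
                       n_cells, s)
      feat <- sprintf("%s_feat%05d", nm, seq_len(s))
      values <- Matrix::Matrix(counts, sparse = TRUE)
    } else {
      # sparse near-binary accessibility: Bernoulli detection with a
      # logistic link, depth entering as a logit offset, Poisson thickening
      logit <- -3.5 + sweep(lograte, 2, colMeans(lograte), "-") + log(depth)
      p <- stats::plogis(logit)
      det <- matrix(stats::rbinom(length(p), 1, p), n_cells, s)
      extra <- matrix(stats::rpois(length(p), 0.3), n_cells, s)
      counts <- det * (1 + extra)
      feat <- sprintf("chr1:%d-%d", seq_len(s) * 1000L, seq_len(s) * 1000L + 500L)
      values <- Matrix::Matrix(counts, sparse = TRUE)
    }
    # integration requires every cell to be observed in every modality
    empty <- which(Matrix::rowSums(values) == 0)
    if (length(empty)) values[cbind(empty, (empty %% s) + 1L)] <- 1
    mods[[nm]] <- modality_matrix(values, cell_ids, feat,
                                  modality = if (spec$family == "bp") "atac"
                                             else if (nm == "protein") "protein"
                                             else "rna",
                                  stage = "raw")
    loadings[[nm]] <- L
  }
  structure(
    list(modalities = mods,
         labels = if (is.null(labels)) NULL else factor(paste0("pop", labels)),
         latent_true = factors, loadings = loadings, params = params),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d cells, modalities: %s%s\n",
              nrow(x$modalities[[1]]$values),
              paste(sprintf("%s (%d)", names(x$modalities),
                            vapply(x$modalities, function(m) ncol(m$values),
                                   integer(1))), collapse = ", "),
              if (is.null(x$labels)) " [null model]"
              else sprintf(", %d populations", nlevels(x$labels))))
  invisible(x)
}

#' Simulate a pair of reduced embeddings with planted canonical structure
#'
#' Draws two embedding matrices sharing `shared_rank` latent directions with
#' specified population canonical correlations; all remaining dimensions are
#' independent standard normal. Each modality is optionally mixed by a
#' random orthogonal rotation (which leaves canonical correlations
#' unchanged). This gives ground truth for calibrating the CCA solver and
#' the component retention filter directly at the embedding level.
#'
#' @param n Number of cells.
#' @param p1,p2 Embedding dimensionalities.
#' @param cors Vector of planted canonical correlations (its length is the
#'   shared rank; must not exceed `min(p1, p2)`).
#' @param rotate Mix each modality with a random orthogonal rotation
#'   (default TRUE).
#' @param seed Integer seed.
#' @return List with `reduced_embedding`s `Y1`, `Y2` and the planted `cors`.
#' @export
simulate_shared_embeddings <- function(n, p1, p2, cors = c(0.9, 0.7),
                                       rotate = TRUE, seed = 1) {
  r <- length(cors)
  if (r > min(p1, p2)) stop("length(cors) must not exceed min(p1, p2)")
  if (any(cors < 0 | cors >= 1)) stop("planted correlations must be in [0, 1)")
  withr::with_seed(seed, {
    f <- matrix(stats::rnorm(n * r), n, r)
    Y1 <- matrix(stats::rnorm(n * p1), n, p1)
    Y2 <- matrix(stats::rnorm(n * p2), n, p2)
    if (r > 0) {
      Y1[, seq_len(r)] <- f
      noise <- matrix(stats::rnorm(n * r), n, r)
      Y2[, seq_len(r)] <- sweep(f, 2, cors, "*") +
        sweep(noise, 2, sqrt(1 - cors^2), "*")
    }
    if (rotate) {
      Y1 <- Y1 %*% qr.Q(qr(matrix(stats::rnorm(p1 * p1), p1, p1)))
      Y2 <- Y2 %*% qr.Q(qr(matrix(stats::rnorm(p2 * p2), p2, p2)))
    }
    ids <- sprintf("cell%05d", seq_len(n))
    list(Y1 = reduced_embedding(Y1, ids, "external"),
         Y2 = reduced_embedding(Y2, ids, "external"),
         cors = sort(cors, decreasing = TRUE))
  })
}
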