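#' Test canonical component pairs for significant correlation
#'
#' For each canonical component pair (z1_i, z2_i), computes the Pearson
#' correlation r, its Student t statistic `r * sqrt((n-2)/(1-r^2))` with
#' n - 2 degrees of freedom (two-sided), and Benjamini-Hochberg adjusted
#' p-values over all component pairs. Because canonical correlations are
#' non-increasing, the retained set is the longest prefix of components
#' whose adjusted p-value falls below `alpha`.
#'
#' Canonical correlations are maximized over weight vectors, so even
#' independent modalities show sizeable sample correlations (of order
#' `sqrt(p1/n) + sqrt(p2/n)`), which a bivariate correlation test mistakes
#' for signal. Retention therefore defaults to the Bartlett-Lawley
#' sequential test for the number of nonzero canonical correlations — a
#' chi-square statistic on the residual correlations with dimension-aware
#' degrees of freedom `(p1 - i + 1)(p2 - i + 1)` — BH-adjusted over the
#' component tests. `method = "ttest"` switches retention to the plain
#' correlation t-test. Both sets of p-values are reported either way.
#'
#' @param pair A `projection_pair`.
#' @param alpha Significance level on the BH-adjusted p-values (default 0.05).
#' @param method Retention rule: `"bartlett"` (dimension-aware, default) or
#'   `"ttest"` (bivariate correlation t-test).
#' @return A data frame with one row per component: `component`, `r`,
#'   `t_stat`, `p`, `p_adj` (correlation t-test), `p_dim`, `p_dim_adj`
#'   (Bartlett-Lawley) and `retained`.
#' @export
test_components <- function(pair, alpha = 0.05,
                            method = c("bartlett", "ttest")) {
  stopifnot(inherits(pair, "projection_pair"))
  method <- match.arg(method)
  n <- pair$n_cells
  if (n < 4) stop("need at least 4 cells for the correlation t-test")
  k <- ncol(pair$Z1)
  r <- vapply(seq_len(k), function(i) {
    s1 <- stats::sd(pair$Z1[, i]); s2 <- stats::sd(pair$Z2[, i])
    if (s1 == 0 || s2 == 0) return(0)
    stats::cor(pair$Z1[, i], pair$Z2[, i])
  }, numeric(1))
  eps <- 1e-12
  t_stat <- ifelse(abs(r) >= 1 - eps, Inf * sign(r),
                   r * sqrt((n - 2) / (1 - r^2)))
  p <- ifelse(is.infinite(t_stat), 0, 2 * stats::pt(-abs(t_stat), df = n - 2))
  p_adj <- stats::p.adjust(p, method = "BH")

  p1 <- pair$p1 %||% k; p2 <- pair$p2 %||% k
  p_dim <- bartlett_lawley(r, n, p1, p2)
  p_dim_adj <- stats::p.adjust(p_dim, method = "BH")

  crit <- if (method == "bartlett") p_dim_adj else p_adj
  retained <- as.logical(cumprod(crit < alpha))
  data.frame(component = seq_len(k), r = r, t_stat = t_stat,
             p = p, p_adj = p_adj, p_dim = p_dim, p_dim_adj = p_dim_adj,
             retained = retained)
}

# sequential chi-square p-values for H0: canonical correlations i..k are
# zero; statistic -(n - 1 - (p1 + p2 + 1)/2) * sum_{j >= i} log(1 - r_j^2)
# with (p1 - i + 1)(p2 - i + 1) degrees of freedom
bartlett_lawley <- function(r, n, p1, p2) {
  k <- length(r)
  r2 <- pmin(r^2, 1)
  scale <- max(n - 1 - (p1 + p2 + 1) / 2, 1)
  logterms <- log1p(-r2)  # -Inf when r = 1, giving p = 0
  vapply(seq_len(k), function(i) {
    stat <- -scale * sum(logterms[i:k])
    df <- (p1 - i + 1) * (p2 - i + 1)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }, numeric(1))
}

#' Integrate two modalities into a shared latent space
#'
#' Fits CCA between the two reduced embeddings, sums the per-modality
#' canonical variates, and truncates to the prefix of components whose
#' cross-modality correlation passes the BH-adjusted t-test at `alpha`.
#'
#' @param Y1,Y2 `reduced_embedding` objects over identical cells.
#' @param alpha Significance level for component retention (default 0.05).
#' @param method Retention rule passed to [test_components()].
#' @return An `integrated_latent` with the cells x k latent matrix `Z`,
#'   retained component count `k`, the per-component test table, the
#'   fitted `cca_model` and per-modality projections.
#' @export
integrate_pair <- function(Y1, Y2, alpha = 0.05,
                           method = c("bartlett", "ttest")) {
  method <- match.arg(method)
  step <- integrate_step(Y1, Y2, alpha, method, label = c("modality1", "modality2"))
  structure(
    list(Z = step$Z, k = step$k, component_tests = step$tests,
         modality_order = step$label, history = list(step$k),
         model = step$model, projections = step$pair),
    class = "integrated_latent"
  )
}

# one CCA + filter + truncate step shared by pairwise and multimodal paths
integrate_step <- function(Y1, Y2, alpha, method, label) {
  model <- fit_cca(Y1, Y2)
  pair <- project_cca(model, Y1, Y2)
  tests <- test_components(pair, alpha, method)
  k <- sum(tests$retained)
  if (k == 0) {
    stop(sprintf(
      "no significantly correlated canonical components between %s and %s (no shared structure); correlations: %s",
      label[1], label[2],
      paste(sprintf("%.3f", tests$r), collapse = " ")))
  }
  Z <- sum_latent(pair)[, seq_len(k), drop = FALSE]
  colnames(Z) <- paste0("CC", seq_len(k))
  list(Z = Z, k = k, tests = tests, model = model, pair = pair, label = label)
}

#' Integrate two or more modalities sequentially
#'
#' Implements the sequential heuristic for more than two modalities: the
#' embeddings are ordered by non-increasing dimensionality (unless
#' `keep_order = TRUE`), the current shared space is initialized to the
#' widest embedding, and each remaining modality is folded in by a CCA
#' against the current shared space followed by summation and truncation to
#' the significantly correlated prefix.
#'
#' @param embeddings Named list of `reduced_embedding` objects over identical
#'   cells (two or more).
#' @param alpha Significance level for component retention (default 0.05).
#' @param keep_order Use the list order as given instead of sorting by
#'   dimensionality.
#' @param method Retention rule passed to [test_components()].
#' @return An `integrated_latent`; `history` holds the retained k after each
#'   pairwise step and `modality_order` the order of integration.
#' @export
integrate_multi <- function(embeddings, alpha = 0.05, keep_order = FALSE,
                            method = c("bartlett", "ttest")) {
  method <- match.arg(method)
  if (!is.list(embeddings) || length(embeddings) < 2) {
    stop("need a list of at least two embeddings")
  }
  if (is.null(names(embeddings)) || any(names(embeddings) == "")) {
    names(embeddings) <- paste0("modality", seq_along(embeddings))
  }
  for (e in embeddings) stopifnot(inherits(e, "reduced_embedding"))
  ids <- embeddings[[1]]$cell_ids
  for (i in seq_along(embeddings)[-1]) {
    check_same_cells(ids, embeddings[[i]]$cell_ids,
                     sprintf("embeddings 1 and %d", i))
  }
  if (!keep_order) {
    dims <- vapply(embeddings, function(e) e$n_dims, integer(1))
    embeddings <- embeddings[order(-dims, seq_along(dims))]
  }
  order_names <- names(embeddings)

  # intermediate shared spaces are carried as plain matrices so that a
  # single retained component does not violate embedding invariants
  current <- embeddings[[1]]
  history <- integer()
  tests <- NULL; model <- NULL; pair <- NULL
  for (i in seq_along(embeddings)[-1]) {
    step <- integrate_step(current, embeddings[[i]], alpha, method,
                           label = c(paste(order_names[seq_len(i - 1)], collapse = "+"),
                                     order_names[i]))
    history <- c(history, step$k)
    tests <- step$tests; model <- step$model; pair <- step$pair
    current <- step$Z
  }
  structure(
    list(Z = current, k = ncol(current),
         component_tests = tests, modality_order = order_names,
         history = as.list(history), model = model, projections = pair),
    class = "integrated_latent"
  )
}

#' @export
print.integrated_latent <- function(x, ...) {
  cat(sprintf("<integrated_latent> %d cells x %d components (%s)\n",
              nrow(x$Z), x$k, paste(x$modality_order, collapse = " + ")))
  invisible(x)
}

#' @export
dim.integrated_latent <- function(x) dim(x$Z)
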