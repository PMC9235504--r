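#' Run the full integration pipeline from a configuration
#'
#' Reads raw modality matrices, applies the standard per-modality reduction
#' recipes, integrates them into a shared latent space, and optionally
#' scores the result against reference labels and ranks top features per
#' component. All outputs are plain text (CSV/JSON) under `config$out`.
#'
#' The configuration is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{modalities}{Named list; each element has `path` (an MTX directory
#'     with `matrix.mtx`, `barcodes.tsv`, `features.tsv`, or a CSV file, or
#'     an embedding CSV), `format` (`"mtx"`, `"csv"` or `"embedding"`), and
#'     optionally `n_dims`. Names must be `rna`, `protein`, `atac` or any
#'     tag when `format = "embedding"`.}
#'   \item{alpha}{Component retention level (default 0.05).}
#'   \item{labels}{Optional path to a labels CSV; enables benchmarking.}
#'   \item{interpret}{Optional list with `n_top` to export top features.}
#'   \item{seed}{Seed for benchmark sampling/clustering (default 1).}
#'   \item{out}{Output directory.}
#' }
#'
#' @param config List or path to a YAML configuration file.
#' @return Invisibly, a list with the `integrated_latent`, the per-modality
#'   embeddings, and the benchmark report (if labels were given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$modalities) || length(config$modalities) < 2) {
    stop("config must list at least two modalities")
  }
  if (is.null(config$out)) stop("config must give an output directory 'out'")
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  embeddings <- list()
  normalized <- list()
  for (nm in names(config$modalities)) {
    spec <- config$modalities[[nm]]
    if (is.null(spec$path)) stop(sprintf("modality '%s' has no path", nm))
    fmt <- spec$format %||% "mtx"
    message(sprintf("[preprocess] %s (%s) from %s", nm, fmt, spec$path))
    if (fmt == "embedding") {
      embeddings[[nm]] <- read_embedding_csv(spec$path)
      next
    }
    raw <- switch(fmt,
      mtx = read_mtx(file.path(spec$path, "matrix.mtx"),
                     file.path(spec$path, "barcodes.tsv"),
                     file.path(spec$path, "features.tsv"),
                     modality = nm),
      csv = read_csv_matrix(spec$path, modality = nm),
      stop(sprintf("unknown format '%s' for modality '%s'", fmt, nm)))
    embeddings[[nm]] <- preprocess_modality(raw, n_dims = spec$n_dims)
    normalized[[nm]] <- switch(nm,
      rna = lognormalize_rna(raw),
      protein = clr_normalize_protein(raw),
      atac = tfidf(raw))
  }

  message(sprintf("[integrate] %s (alpha = %g)",
                  paste(names(embeddings), collapse = " + "), alpha))
  latent <- integrate_multi(embeddings, alpha = alpha)
  message(sprintf("[integrate] retained %d canonical components", latent$k))
  write_embedding_csv(latent, file.path(config$out, "latent.csv"))
  utils::write.csv(latent$component_tests,
                   file.path(config$out, "component_tests.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- NULL
  if (!is.null(config$labels)) {
    labels <- read_labels(config$labels, rownames(latent$Z))
    message("[benchmark] scoring latent space against labels")
    report <- benchmark_report(latent, embeddings, labels, seed = seed,
                               labels_name = basename(config$labels))
    jsonlite::write_json(unclass(report), file.path(config$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(config$interpret)) {
    n_top <- config$interpret$n_top %||% 10
    for (nm in names(normalized)) {
      sc <- feature_scores(normalized[[nm]], latent)
      tops <- do.call(rbind, lapply(seq_len(latent$k), function(cc) {
        rbind(cbind(component = cc, direction = "positive",
                    top_features(sc, cc, min(n_top, nrow(sc$U)))),
              cbind(component = cc, direction = "negative",
                    top_features(sc, cc, min(n_top, nrow(sc$U)), "negative")))
      }))
      utils::write.csv(tops, file.path(config$out, sprintf("top_features_%s.csv", nm)),
                       row.names = FALSE, quote = FALSE)
    }
  }

  invisible(list(latent = latent, embeddings = embeddings, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
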