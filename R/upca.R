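# Unsupervised pattern-cognition analysis: PCA over similarity profiles.
# Each site is described by its row of the Tanimoto matrix (its similarity
# to every reference site); rows are mean-centered, not variance-scaled,
# and decomposed into principal components. New structures are projected
# into the fitted map through their similarity row alone — the model is
# never refitted, so the reference map acts as a fixed roadmap.

#' Fit a PCA model on a similarity matrix
#'
#' Rows of the selected Tanimoto matrix are the feature vectors. Columns
#' are mean-centered and decomposed; the returned variance ratios span all
#' components (they sum to 1 and are non-increasing). Eigenvector signs
#' follow a deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param m A `biogps_simmat` (or a plain symmetric numeric matrix).
#' @param which Which matrix to analyze: `"H"`, `"O"`, `"N1"`, `"DRY"` or
#'   `"global"`. Ignored when `m` is a plain matrix.
#' @param n_components Components retained in the embedding (default 2).
#' @return A `biogps_upca` model: `ids`, `which`, `means`, `loadings`
#'   (all components), `evr` (explained-variance ratios), `scores` (fit-time
#'   coordinates, all components), `n_components`, and `embedding` — a data
#'   frame `id`, `PC1`..`PCk`.
#' @export
fit_upca <- function(m, which = "global", n_components = 2L) {
  if (inherits(m, "biogps_simmat")) {
    which <- match.arg(which, c(PROBE_TYPES, "global"))
    X <- m[[which]]
  } else {
    X <- as.matrix(m)
  }
  n <- nrow(X)
  stopifnot(n >= 3L, ncol(X) == n)
  if (max(abs(X - t(X))) > 1e-6) stop("fit_upca: matrix not symmetric")
  if (anyNA(X)) {
    warning("fit_upca: NA similarities treated as 0")
    X[is.na(X)] <- 0
  }
  if (n_components > n) stop("fit_upca: n_components exceeds matrix size")
  ids <- rownames(X) %||% sprintf("obj%02d", seq_len(n))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(load))) {       # deterministic sign convention
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  v <- pc$sdev^2
  evr <- v / sum(v)
  emb <- data.frame(id = ids, scores[, seq_len(n_components), drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  names(emb)[-1] <- paste0("PC", seq_len(n_components))
  structure(list(ids = ids, which = which, means = unname(pc$center),
                 loadings = unname(load), evr = unname(evr),
                 scores = unname(scores),
                 n_components = as.integer(n_components), embedding = emb),
            class = "biogps_upca")
}

#' @export
print.biogps_upca <- function(x, ...) {
  cat(sprintf("<biogps_upca> %d references (%s score); PC1 = %.1f%%, PC2 = %.1f%%\n",
              length(x$ids), x$which, 100 * x$evr[1],
              100 * x$evr[min(2, length(x$evr))]))
  invisible(x)
}

#' Project a similarity row into a fitted model
#'
#' @param model A `biogps_upca`.
#' @param sims Numeric vector of similarities to the model's references, in
#'   reference order.
#' @return Numeric vector of coordinates on the retained components.
#' @export
project_row <- function(model, sims) {
  stopifnot(length(sims) == length(model$ids))
  as.numeric((sims - model$means) %*%
               model$loadings[, seq_len(model$n_components), drop = FALSE])
}

#' Project a new structure into a fitted map
#'
#' Computes the new site's similarity to each reference site with the full
#' comparison machinery, centers it with the model's stored means and
#' multiplies by the loadings. The model is not refitted: a mutant never
#' becomes a reference.
#'
#' @param model A `biogps_upca`.
#' @param new_site Site description from [characterize_site()].
#' @param reference_sites List of the reference site descriptions, in model
#'   order.
#' @param m_max,max_poses Passed to [compare_pair()].
#' @return One-row data frame: `id`, `PC1`..`PCk`.
#' @export
project_site <- function(model, new_site, reference_sites,
                         m_max = 500L, max_poses = 15L) {
  if (length(reference_sites) != length(model$ids))
    stop("project_site: need one reference site per model reference")
  ref_ids <- vapply(reference_sites, `[[`, "", "id")
  if (!identical(ref_ids, model$ids))
    stop("project_site: reference sites do not match model references")
  sims <- vapply(reference_sites, function(ref) {
    sc <- compare_pair(new_site, ref, m_max, max_poses)$scores[[model$which]]
    if (is.na(sc)) 0 else sc
  }, numeric(1))
  co <- project_row(model, sims)
  out <- data.frame(id = new_site$id, t(co), row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("PC", seq_len(model$n_components))
  out
}

#' Classical MDS embedding of an RMSD matrix
#'
#' Baseline projection by whole-fold similarity: classical multidimensional
#' scaling (double-centering of squared distances, top eigenpairs) of a
#' backbone RMSD matrix. A warning flag is raised when more than 30% of the
#' eigenvalue mass is negative, i.e. the distances are far from Euclidean.
#'
#' @param r Symmetric distance matrix with zero diagonal (e.g. from
#'   [backbone_rmsd_matrix()]).
#' @param n_components Embedding dimension (default 2).
#' @return Data frame `id`, `PC1`..`PCk`, with eigenvalues in the `eig`
#'   attribute and `negative_mass_warning` flag.
#' @export
baseline_rmsd_mds <- function(r, n_components = 2L) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8 || max(abs(diag(r))) > 1e-8)
    stop("baseline_rmsd_mds: need a symmetric matrix with zero diagonal")
  mds <- stats::cmdscale(r, k = min(n_components, nrow(r) - 1L), eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < n_components)          # degenerate: pad with zeros
    pts <- cbind(pts, matrix(0, nrow(pts), n_components - ncol(pts)))
  neg <- sum(abs(mds$eig[mds$eig < 0])) / max(sum(abs(mds$eig)), 1e-300)
  out <- data.frame(id = rownames(r) %||% sprintf("obj%02d", seq_len(nrow(r))),
                    pts, row.names = NULL, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("PC", seq_len(n_components))
  attr(out, "eig") <- mds$eig
  attr(out, "negative_mass_warning") <- neg > 0.3
  if (neg > 0.3)
    warning(sprintf("baseline_rmsd_mds: %.0f%% of eigenvalue mass is negative",
                    100 * neg))
  out
}

#' Plot a 2-D embedding
#' @param emb Data frame with `PC1`, `PC2` columns (and `id`).
#' @param labels Optional factor of class labels for coloring.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `emb`.
#' @export
plot_embedding <- function(emb, labels = NULL, main = "UPCA map", ...) {
  col <- if (is.null(labels)) "black" else as.integer(factor(labels)) + 1L
  graphics::plot(emb$PC1, emb$PC2, col = col, pch = 19,
                 xlab = "PC1", ylab = "PC2", main = main, ...)
  graphics::text(emb$PC1, emb$PC2, emb$id, pos = 3, cex = 0.6, col = col)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19,
                     cex = 0.8)
  invisible(emb)
}

#' Serialize a fitted model to JSON
#' @param model A `biogps_upca`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_upca <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  if (is.null(path)) return(invisible(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a fitted model from JSON
#' @param path File written by [write_upca()].
#' @return A `biogps_upca`.
#' @export
read_upca <- function(path) {
  o <- jsonlite::fromJSON(path)
  o$loadings <- matrix(unlist(o$loadings), nrow = length(o$ids))
  o$scores <- matrix(unlist(o$scores), nrow = length(o$ids))
  o$embedding <- as.data.frame(o$embedding, stringsAsFactors = FALSE)
  structure(o, class = "biogps_upca")
}
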