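#' Per-node candidate-feature count for the supervised forest
#'
#' The conventional square-root rule: `floor(sqrt(n_features))`, never
#' below 1. With the 567-CNVR map this gives the 23 features per node used
#' by the population model.
#'
#' @param n_features Number of features (CNVRs) available to the model.
#' @return An integer.
#' @examples
#' mtry_rule(567) # 23
#' @export
mtry_rule <- function(n_features) {
  assert_scalar_number(n_features, "n_features", 1)
  max(1L, as.integer(floor(sqrt(n_features))))
}

# Replace missing cells by the locus modal state (ties to the smaller
# state); tree ensembles need complete feature vectors.
impute_modal <- function(states) {
  for (i in seq_len(nrow(states))) {
    miss <- is.na(states[i, ])
    if (!any(miss)) next
    obs <- states[i, !miss]
    if (length(obs) == 0L) {
      states[i, ] <- 2L
      next
    }
    tab <- table(obs)
    states[i, miss] <- as.integer(names(tab)[which.max(tab)])
  }
  states
}

#' Supervised random-forest proximity among samples
#'
#' Fits an ensemble of classification trees predicting each sample's
#' population from its CNVR copy-number states, and returns the proximity
#' matrix (the fraction of trees in which two samples land in the same
#' terminal node) together with the out-of-bag confusion matrix and
#' accuracy. `1 - proximity` is the sample-to-sample distance used for
#' multidimensional scaling.
#'
#' @param features Loci x samples numeric matrix (states or dosages), or a
#'   `cnvr_set`. Missing cells are imputed to the locus modal state.
#' @param labels Population label per sample, or a manifest tibble.
#' @param n_trees Number of trees; the full-scale model uses 50,000,
#'   desk-scale analyses several hundred to a few thousand.
#' @param mtry Features tried per node; default [mtry_rule()].
#' @param seed Integer seed for the ensemble.
#' @param oob_prox Measure proximity only on out-of-bag pairs rather than
#'   over all trees and samples (default `FALSE`).
#' @return A `forest_proximity` object: `proximity` (samples x samples,
#'   symmetric, unit diagonal), `confusion` (true x predicted count
#'   matrix from out-of-bag votes), `accuracy`, `n_trees`, `mtry`, `seed`.
#' @export
fit_forest_proximity <- function(features, labels, n_trees = 50000L,
                                 mtry = NULL, seed = 1L, oob_prox = FALSE) {
  if (inherits(features, "cnvr_set")) features <- features$states
  if (is_tibble(labels) || is.data.frame(labels)) {
    labels <- labels$population[match(colnames(features), labels$sample_id)]
  }
  if (length(labels) != ncol(features)) {
    abort("need one population label per sample.")
  }
  y <- factor(labels)
  if (nlevels(y) < 2L) abort("supervised proximity needs at least 2 populations.")
  if (ncol(features) < 2L) abort("need at least 2 samples.")
  x <- t(impute_modal(features))
  mtry <- mtry %||% mtry_rule(ncol(x))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(n_trees), mtry = mtry,
    proximity = TRUE, oob.prox = oob_prox
  )
  prox <- (rf$proximity + t(rf$proximity)) / 2
  diag(prox) <- 1
  dimnames(prox) <- list(colnames(features), colnames(features))
  conf <- table(true = y, predicted = rf$predicted)
  conf <- unclass(conf)[levels(y), levels(y), drop = FALSE]
  structure(list(
    proximity = prox, confusion = conf,
    accuracy = sum(diag(conf)) / sum(conf),
    n_trees = as.integer(n_trees), mtry = mtry, seed = seed,
    labels = setNames(as.character(y), colnames(features))
  ), class = "forest_proximity")
}

#' @export
print.forest_proximity <- function(x, ...) {
  cat(sprintf("<forest_proximity> %d samples, %d trees, mtry = %d, OOB accuracy %.3f\n",
              nrow(x$proximity), x$n_trees, x$mtry, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
glance.forest_proximity <- function(x, ...) {
  tibble(n_samples = nrow(x$proximity), n_trees = x$n_trees, mtry = x$mtry,
         oob_accuracy = x$accuracy)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, eigendecomposes it, and
#' returns the top-`dims` coordinates scaled by the square roots of the
#' positive eigenvalues. Negative eigenvalues (non-Euclidean input, e.g.
#' 1 - proximity) are truncated and reported. For exactly
#' Euclidean-embeddable input the embedded pairwise distances reproduce the
#' input to numerical precision.
#'
#' @param distance Symmetric distance matrix with zero diagonal, or a
#'   `forest_proximity` (uses `1 - proximity`).
#' @param dims Number of embedding dimensions (default 3).
#' @return A `cnv_mds` object: `points` (tibble `sample_id`, `dim1..dimd`),
#'   `eigenvalues` (all, non-increasing), `positive_mass` (fraction of
#'   positive-eigenvalue mass captured by the retained dimensions).
#' @export
classical_mds <- function(distance, dims = 3L) {
  if (inherits(distance, "forest_proximity")) distance <- 1 - distance$proximity
  if (!is.matrix(distance) || nrow(distance) != ncol(distance)) {
    abort("`distance` must be a square matrix.")
  }
  if (max(abs(distance - t(distance))) > 1e-8) abort("distance matrix must be symmetric.")
  n <- nrow(distance)
  dims <- min(as.integer(dims), n - 1L)
  d2 <- distance^2
  # Torgerson double centering: B = -1/2 * J d2 J
  rm <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (sweep(sweep(d2, 1L, rm), 2L, rm) + gm)
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos <- vals > max(vals[1L], 0) * 1e-12
  use <- seq_len(dims)
  lam <- pmax(vals[use], 0)
  coords <- eig$vectors[, use, drop = FALSE] %*% diag(sqrt(lam), dims)
  coords <- sweep(coords, 2L, colMeans(coords)) # centre exactly
  pts <- as_tibble(coords, .name_repair = ~paste0("dim", seq_len(dims)))
  pts <- dplyr::bind_cols(
    tibble(sample_id = rownames(distance) %||% sprintf("S%03d", seq_len(n))),
    pts
  )
  structure(list(
    points = pts, eigenvalues = vals,
    positive_mass = sum(lam) / max(sum(vals[pos]), .Machine$double.eps)
  ), class = "cnv_mds")
}

#' @export
print.cnv_mds <- function(x, ...) {
  cat(sprintf("<cnv_mds> %d samples in %d dimensions (%.1f%% of positive eigenvalue mass)\n",
              nrow(x$points), ncol(x$points) - 1L, 100 * x$positive_mass))
  print(head(x$points))
  invisible(x)
}

#' @export
tidy.cnv_mds <- function(x, ...) x$points

#' Population-structure analysis in one call
#'
#' Chains [fit_forest_proximity()] and [classical_mds()] and attaches
#' population labels to the embedding.
#'
#' @inheritParams fit_forest_proximity
#' @param manifest Sample manifest (labels and plot grouping).
#' @param dims Embedding dimensions.
#' @return A list: `forest` (`forest_proximity`), `mds` (`cnv_mds`),
#'   `points` (MDS tibble with a `population` column).
#' @export
population_structure <- function(features, manifest, n_trees = 5000L,
                                 dims = 3L, seed = 1L, mtry = NULL) {
  forest <- fit_forest_proximity(features, manifest, n_trees = n_trees,
                                 mtry = mtry, seed = seed)
  mds <- classical_mds(forest, dims = dims)
  points <- dplyr::left_join(
    mds$points,
    manifest[, c("sample_id", "population")],
    by = "sample_id"
  )
  list(forest = forest, mds = mds, points = points)
}

#' Scatter plot of an MDS embedding
#'
#' @param object A `cnv_mds` object.
#' @param labels Optional population label per sample (vector or manifest).
#' @param dims Which two dimensions to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_mds <- function(object, labels = NULL, dims = c(1L, 2L), ...) {
  pts <- object$points
  if (is_tibble(labels) || is.data.frame(labels)) {
    labels <- labels$population[match(pts$sample_id, labels$sample_id)]
  }
  pts$population <- labels %||% "all"
  dx <- paste0("dim", dims[1L]); dy <- paste0("dim", dims[2L])
  ggplot2::ggplot(pts, ggplot2::aes(.data[[dx]], .data[[dy]],
                                    colour = .data$population)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(x = sprintf("MDS dimension %d", dims[1L]),
                  y = sprintf("MDS dimension %d", dims[2L]),
                  colour = "Population") +
    ggplot2::theme_minimal()
}
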