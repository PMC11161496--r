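# Survey reduction: PCA of the 12-item experience battery on the item
# correlation matrix, with the retained component count decided by parallel
# analysis and component signs anchored so that "reward" (pleasure-positive)
# and "challenge" (difficulty-positive) are reproducible labels.

#' Parallel analysis for component retention
#'
#' Compares the observed eigenvalues of the item correlation matrix against
#' the chosen percentile of eigenvalues from `n_iter` standard-normal matrices
#' of the same shape. Components are retained while each successive observed
#' eigenvalue exceeds its reference percentile; retention stops at the first
#' failure.
#'
#' @param responses Numeric matrix or data frame, trials x items.
#' @param n_iter Number of random reference matrices.
#' @param percentile Reference percentile (0.95 keeps the chance of retaining
#'   a component from pure noise near 5%).
#' @param seed Optional integer seed for the reference simulation.
#' @return A list with `n_components`, `eigenvalues` (observed) and
#'   `thresholds` (reference percentiles), class `parallel_analysis`.
#' @export
parallel_analysis <- function(responses, n_iter = 1000, percentile = 0.95,
                              seed = NULL) {
  X <- as.matrix(responses)
  if (!is.numeric(X)) abort("parallel_analysis: responses must be numeric")
  p <- ncol(X); n <- nrow(X)
  if (n <= p) abort("parallel_analysis: need more rows than items")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    abort(sprintf("parallel_analysis: zero-variance item '%s'",
                  colnames(X)[which(sds == 0)[1]] %||% which(sds == 0)[1]))
  obs <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  if (!is.null(seed)) set.seed(seed)
  ref <- matrix(NA_real_, n_iter, p)
  for (i in seq_len(n_iter)) {
    R <- matrix(rnorm(n * p), n, p)
    ref[i, ] <- eigen(cor(R), symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(ref, 2, quantile, probs = percentile)
  exceeds <- obs > thr
  k <- if (!exceeds[1]) 0L else {
    runs <- rle(exceeds)
    as.integer(runs$lengths[1])
  }
  structure(list(n_components = k, eigenvalues = obs, thresholds = thr),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("<parallel_analysis: %d component(s) retained>\n", x$n_components))
  invisible(x)
}

#' Principal component analysis of survey responses
#'
#' Eigendecomposition of the item correlation matrix (items share the 1-5
#' scale but differ in variance). Scores are the standardized-item
#' projections, rescaled to unit variance per component; variance-explained
#' fractions over the full decomposition sum to 1.
#'
#' @param responses Numeric matrix/data frame, trials x items.
#' @param n_components Number of components to keep (from
#'   [parallel_analysis()]).
#' @return A `component_model`: `loadings` (items x k, orthonormal columns),
#'   `scores` (trials x k, unit variance), `var_explained` (k fractions),
#'   `var_explained_full` (all fractions), `n_components`.
#' @export
fit_pca <- function(responses, n_components) {
  X <- as.matrix(responses)
  stopifnot(n_components >= 1)
  p <- ncol(X)
  if (n_components > p) abort("fit_pca: more components than items")
  C <- cor(X)
  if (anyNA(C)) abort("fit_pca: undefined correlations (zero-variance item?)")
  e <- eigen(C, symmetric = TRUE)
  if (e$values[p] < -1e-8) abort("fit_pca: correlation matrix not PSD")
  rank_def <- sum(e$values < 1e-10)
  load <- e$vectors[, seq_len(n_components), drop = FALSE]
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(n_components))
  Z <- scale(X)
  scores <- Z %*% load
  scores <- sweep(scores, 2, apply(scores, 2, sd), "/")
  structure(
    list(loadings = load, scores = scores,
         var_explained = e$values[seq_len(n_components)] / p,
         var_explained_full = e$values / p,
         eigenvalues = e$values,
         n_components = as.integer(n_components),
         rank_deficient = rank_def > 0L,
         labels = colnames(load)),
    class = "component_model"
  )
}

#' Fix component signs and attach substantive labels
#'
#' PCA is determined only up to column sign; this anchors the first component
#' so the pleasure item loads positively (labelled "reward") and the second so
#' the difficulty item loads positively (labelled "challenge"). An anchor
#' loading near zero leaves the orientation unchanged with a warning.
#'
#' @param model A `component_model` with at least 2 components.
#' @param anchors Named character vector mapping labels to anchor items, in
#'   component order.
#' @param min_loading Anchor loadings below this magnitude trigger a warning.
#' @return The relabelled `component_model`.
#' @export
orient_and_label <- function(model,
                             anchors = c(reward = "pleasure",
                                         challenge = "difficulty"),
                             min_loading = 0.05) {
  stopifnot(inherits(model, "component_model"))
  if (model$n_components < length(anchors))
    abort("orient_and_label: model has fewer components than anchors")
  for (j in seq_along(anchors)) {
    item <- anchors[[j]]
    if (!item %in% rownames(model$loadings))
      abort(sprintf("orient_and_label: anchor item '%s' not found", item))
    l <- model$loadings[item, j]
    if (abs(l) < min_loading) {
      warn(sprintf("anchor item '%s' loads near zero on component %d; orientation unchanged",
                   item, j))
      next
    }
    if (l < 0) {
      model$loadings[, j] <- -model$loadings[, j]
      model$scores[, j] <- -model$scores[, j]
    }
  }
  model$labels[seq_along(anchors)] <- names(anchors)
  colnames(model$loadings) <- model$labels
  colnames(model$scores) <- model$labels
  model
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model: %d component(s) (%s), variance %s>\n",
              x$n_components, paste(x$labels, collapse = ", "),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " / ")))
  invisible(x)
}

#' @export
tidy.component_model <- function(x, ...) {
  as_tibble(x$loadings, rownames = "item") |>
    tidyr::pivot_longer(-"item", names_to = "component", values_to = "loading")
}

#' @export
glance.component_model <- function(x, ...) {
  tibble(n_components = x$n_components,
         var_explained_pc1 = x$var_explained[1],
         var_explained_pc2 = if (x$n_components >= 2) x$var_explained[2] else NA_real_,
         rank_deficient = x$rank_deficient)
}

#' Plot component loadings
#'
#' Item loadings on the first two components, biplot style.
#'
#' @param object A `component_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_model <- function(object, ...) {
  stopifnot(object$n_components >= 2)
  d <- as_tibble(object$loadings[, 1:2], rownames = "item")
  names(d)[2:3] <- c("c1", "c2")
  ggplot(d, aes(x = .data$c1, y = .data$c2, label = .data$item)) +
    geom_segment(aes(xend = 0, yend = 0), linewidth = 0.2, colour = "grey60") +
    geom_point() +
    ggplot2::geom_text(nudge_y = 0.03, size = 3) +
    labs(x = sprintf("%s (%.1f%%)", object$labels[1],
                     100 * object$var_explained[1]),
         y = sprintf("%s (%.1f%%)", object$labels[2],
                     100 * object$var_explained[2])) +
    theme_minimal()
}
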