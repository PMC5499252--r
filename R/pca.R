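# Principal-component score reduction of the wavelet feature matrix.
# Components come from the singular value decomposition of the centred
# matrix (via stats::prcomp), so the features x features covariance is
# never materialised; at most n - 1 components carry variance.

#' Fit a PCA model to a feature matrix
#'
#' Centres each column (optionally also scales to unit variance) and
#' computes the principal directions and per-component variances by a
#' rank-revealing SVD of the centred matrix.  Each component's sign is
#' fixed so its largest-magnitude loading is positive, making outputs
#' reproducible across numerical backends.
#'
#' @param x Numeric matrix (subjects x features) or a `cad_features`
#'   object.
#' @param scale. Scale columns to unit variance before the SVD
#'   (default `FALSE`: wavelet features share a scale, so only centring
#'   is applied).
#' @param variance_threshold If non-`NULL`, run [select_components()]
#'   at this cumulative-variance fraction and store the result in
#'   `k_selected`.
#' @return Object of class `cad_pca`: `column_means`, `column_scales`
#'   (or `NULL`), `components` (features x k_max, orthonormal columns),
#'   `explained_variance` (descending), `k_max = min(n - 1, p)`,
#'   `k_selected`, `variance_threshold`.
#' @export
fit_pca <- function(x, scale. = FALSE, variance_threshold = NULL) {
  if (inherits(x, "cad_features")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 2L)
    stop("PCA needs at least 2 rows; got ", nrow(x), call. = FALSE)
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k_max <- min(nrow(x) - 1L, ncol(x))
  comp <- pr$rotation[, seq_len(k_max), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(k_max), function(j) {
    v <- comp[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  comp <- sweep(comp, 2L, flip, `*`)
  model <- structure(list(
    column_means = pr$center,
    column_scales = if (is.numeric(pr$scale)) pr$scale else NULL,
    components = comp,
    explained_variance = pr$sdev[seq_len(k_max)]^2,
    k_max = k_max,
    k_selected = NULL,
    variance_threshold = NULL
  ), class = "cad_pca")
  if (!is.null(variance_threshold)) {
    model$k_selected <- select_components(model, variance_threshold)
    model$variance_threshold <- variance_threshold
  }
  model
}

#' Smallest component count reaching a cumulative-variance threshold
#'
#' @param x A `cad_pca` model, or a numeric vector of per-component
#'   variances (absolute variances or fractions; only their relative
#'   sizes matter).
#' @param threshold Required cumulative fraction of total variance, in
#'   (0, 1].
#' @return Integer: the smallest `k` whose first `k` components hold at
#'   least `threshold` of the total variance.
#' @examples
#' select_components(c(0.9, 0.1), 0.85)  # 1
#' @export
select_components <- function(x, threshold = 0.90) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be a fraction in (0, 1]", call. = FALSE)
  ev <- if (inherits(x, "cad_pca")) x$explained_variance else as.numeric(x)
  if (any(ev < 0)) stop("variances must be non-negative", call. = FALSE)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= threshold - 1e-12)[1L])
}

#' Project data onto the leading principal components
#'
#' @param model A `cad_pca` model.
#' @param x Matrix (or `cad_features`) with the same columns the model
#'   was fitted on.
#' @param k Number of components (default the model's `k_selected`,
#'   falling back to `k_max`); `k = 0` returns a subjects x 0 matrix.
#' @return Score matrix (subjects x k).
#' @export
pca_transform <- function(model, x, k = NULL) {
  stopifnot(inherits(model, "cad_pca"))
  if (inherits(x, "cad_features")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$column_means))
    stop(sprintf("x has %d columns but the model was fitted on %d",
                 ncol(x), length(model$column_means)), call. = FALSE)
  if (is.null(k)) k <- if (!is.null(model$k_selected)) model$k_selected else model$k_max
  if (k < 0L || k > model$k_max)
    stop(sprintf("k must lie in 0..%d", model$k_max), call. = FALSE)
  xc <- sweep(x, 2L, model$column_means, `-`)
  if (!is.null(model$column_scales)) xc <- sweep(xc, 2L, model$column_scales, `/`)
  xc %*% model$components[, seq_len(k), drop = FALSE]
}

#' Map scores back to the feature space
#'
#' Inverse of [pca_transform()] for the components used; at `k = k_max`
#' the round trip reproduces the data to numerical precision.
#'
#' @param model A `cad_pca` model.
#' @param scores Score matrix (subjects x k).
#' @return Matrix in the original feature space.
#' @export
pca_reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "cad_pca"))
  k <- ncol(scores)
  x <- scores %*% t(model$components[, seq_len(k), drop = FALSE])
  if (!is.null(model$column_scales)) x <- sweep(x, 2L, model$column_scales, `*`)
  sweep(x, 2L, model$column_means, `+`)
}

#' @export
print.cad_pca <- function(x, ...) {
  frac <- cumsum(x$explained_variance) / sum(x$explained_variance)
  cat(sprintf("PCA model: %d features, %d components\n",
              length(x$column_means), x$k_max))
  if (!is.null(x$k_selected))
    cat(sprintf("  selected k = %d (%.2f%% of variance at threshold %.2f)\n",
                x$k_selected, 100 * frac[x$k_selected], x$variance_threshold))
  invisible(x)
}
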