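#' Abundance transformations
#'
#' `sqrt_transform()` takes the elementwise square root, the classical
#' down-weighting of abundant species before a Bray-Curtis ordination.
#' `hellinger_transform()` maps each entry to the square root of its
#' row-relative abundance (via [vegan::decostand()]), which preserves
#' proportionality while damping dominant groups; every non-zero row then
#' has unit sum of squares. All-zero rows map to all-zero rows with a
#' warning.
#'
#' @param x Non-negative numeric matrix (rows = objects such as years,
#'   columns = species or groups).
#' @return A matrix of the same shape.
#' @examples
#' hellinger_transform(rbind(c(1, 3), c(2, 2)))
#' @export
sqrt_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entries not allowed", call. = FALSE)
  sqrt(x)
}

#' @rdname sqrt_transform
#' @export
hellinger_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entries not allowed", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero))
    warning(sum(zero), " all-zero row(s) left at zero", call. = FALSE)
  out <- suppressWarnings(vegan::decostand(x, method = "hellinger"))
  out <- as.matrix(out)
  out[zero, ] <- 0
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), bounded in [0, 1], computed
#' with [vegan::vegdist()]. A pair of all-zero rows has no defined
#' dissimilarity; it is set to 0 with a warning (identical emptiness).
#'
#' @param x Non-negative numeric matrix, rows = objects.
#' @return A symmetric matrix of dissimilarities with zero diagonal.
#' @examples
#' bray_curtis(rbind(a = c(1, 2), b = c(2, 2)))["a", "b"]  # 1/7
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entries not allowed", call. = FALSE)
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero row pair(s): dissimilarity set to 0", call. = FALSE)
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

# deterministic sign convention: flip each axis so its largest-magnitude
# loading (or score, when no loadings exist) is positive
fix_signs <- function(scores, loadings = NULL) {
  ref <- if (is.null(loadings)) scores else loadings
  flip <- apply(ref, 2L, function(v) {
    j <- which.max(abs(v))
    if (v[j] < 0) -1 else 1
  })
  scores <- sweep(scores, 2L, flip, "*")
  if (!is.null(loadings)) loadings <- sweep(loadings, 2L, flip, "*")
  list(scores = scores, loadings = loadings)
}

new_ordination <- function(scores, eigenvalues, loadings = NULL,
                           negative_eigenvalues = NULL, method = "pca") {
  if (is.null(negative_eigenvalues)) negative_eigenvalues <- numeric(0)
  tot <- sum(eigenvalues) + sum(abs(negative_eigenvalues))
  out <- list(scores = scores,
              loadings = loadings,
              eigenvalues = eigenvalues,
              proportion_explained = if (tot > 0) eigenvalues / tot
                                     else rep(0, length(eigenvalues)),
              negative_eigenvalues = negative_eigenvalues,
              method = method)
  class(out) <- "ordination"
  out
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d objects, %d axes\n", toupper(x$method),
              nrow(x$scores), ncol(x$scores)))
  k <- min(4L, length(x$eigenvalues))
  cat("  proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained[seq_len(k)]),
            collapse = " "), if (length(x$eigenvalues) > k) "..." else "",
      "\n")
  if (!is.null(x$negative_eigenvalues) && length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalue(s), |share| %.3f\n",
                length(x$negative_eigenvalues),
                sum(abs(x$negative_eigenvalues)) /
                  (sum(x$eigenvalues) + sum(abs(x$negative_eigenvalues)))))
  invisible(x)
}

#' Principal components analysis
#'
#' A thin wrapper around [stats::prcomp()] returning a common
#' `"ordination"` structure with a deterministic sign convention (the
#' largest-magnitude loading of each axis is positive) so runs are
#' reproducible across platforms. With `scale = TRUE`, constant columns are
#' dropped with a warning.
#'
#' @param x Numeric matrix, rows = objects.
#' @param center,scale Passed to [stats::prcomp()].
#' @return An `"ordination"` with `scores`, `loadings`, `eigenvalues`
#'   (variances along axes, non-increasing) and `proportion_explained`.
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 objects and 2 variables", call. = FALSE)
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(x, center = center, scale. = scale)
  sgn <- fix_signs(p$x, p$rotation)
  new_ordination(scores = sgn$scores,
                 eigenvalues = p$sdev^2,
                 loadings = sgn$loadings,
                 method = "pca")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a symmetric dissimilarity matrix into coordinates by
#' double-centering -D^2/2 and eigendecomposition ([stats::cmdscale()]).
#' Axes with positive eigenvalues carry coordinates scaled by the square
#' root of the eigenvalue; negative eigenvalues (non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but no Lingoes or
#' Cailliez correction is applied.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @return An `"ordination"` with `scores`, positive `eigenvalues`,
#'   `proportion_explained` (relative to the total absolute eigenvalue
#'   mass) and `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig, 0) * 1e-12
  scores <- fit$points
  # cmdscale may return fewer than requested columns when eigenvalues vanish
  keep <- seq_len(min(ncol(scores), sum(pos)))
  scores <- scores[, keep, drop = FALSE]
  colnames(scores) <- paste0("Axis", keep)
  rownames(scores) <- rownames(d)
  scores <- fix_signs(scores)$scores
  new_ordination(scores = scores,
                 eigenvalues = eig[pos][keep],
                 negative_eigenvalues = eig[eig < 0],
                 method = "pcoa")
}

#' Broken-stick axis retention
#'
#' Retains the leading ordination axes whose proportion of variance exceeds
#' the broken-stick expectation b_k = (1/p) * sum_{i=k..p} 1/i, stopping at
#' the first axis that fails.
#'
#' @param eigenvalues Non-negative, non-increasing eigenvalues.
#' @return Integer count of retained axes.
#' @examples
#' broken_stick(c(0.8, 0.2))  # 1
#' @export
broken_stick <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be >= 0", call. = FALSE)
  tot <- sum(eigenvalues)
  if (tot == 0) return(0L)
  p <- length(eigenvalues)
  prop <- eigenvalues / tot
  bk <- rev(cumsum(1 / rev(seq_len(p)))) / p
  ok <- prop > bk
  if (!ok[1L]) return(0L)
  if (all(ok)) return(p)
  which.min(ok) - 1L
}

#' Scree elbow axis retention
#'
#' Retains the axes before the largest successive eigenvalue drop (the
#' elbow). Used as a secondary check; when it disagrees with
#' [broken_stick()] the broken-stick count takes precedence (see
#' `retain_axes()`).
#'
#' @inheritParams broken_stick
#' @return Integer count of retained axes.
#' @export
scree_elbow <- function(eigenvalues) {
  if (length(eigenvalues) < 2L) return(length(eigenvalues))
  drops <- -diff(eigenvalues)
  which.max(drops)
}

#' @rdname scree_elbow
#' @export
retain_axes <- function(eigenvalues) {
  broken_stick(eigenvalues)
}
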