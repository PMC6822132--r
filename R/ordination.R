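# Principal coordinates analysis (metric MDS) of a dissimilarity matrix:
# Gower double-centring of -D^2/2 followed by eigendecomposition.
# Sorensen-family dissimilarities are generally non-Euclidean, so negative
# eigenvalues are expected; their share is reported and a Lingoes additive
# correction is available.

#' Principal coordinates analysis
#'
#' Eigendecomposes the Gower-centred matrix `-1/2 J D^2 J` (J the centring
#' operator). Coordinates are eigenvectors scaled by the square root of
#' their (positive) eigenvalues; axis signs are canonicalized so the
#' largest-magnitude loading on each axis is positive, making repeated runs
#' and alternate eigensolvers agree. With `correction = "lingoes"` and
#' negative eigenvalues present, the constant `c = -lambda_min` is added to
#' all squared off-diagonal dissimilarities before re-decomposition, which
#' makes the configuration Euclidean.
#'
#' @param d symmetric, non-negative dissimilarity matrix with zero diagonal
#'   (e.g. from [beta_pairwise()]).
#' @param correction `"none"` (default; negative eigenvalues reported) or
#'   `"lingoes"`.
#' @param n_axes number of axes to retain (default 2, for planar plots);
#'   `NULL` retains all positive axes.
#' @return a `pcoa_result` list: `labels`, `coordinates` (areas x axes),
#'   `eigenvalues` (full spectrum, descending), `variance_explained`
#'   (fraction of the positive-eigenvalue total per retained axis),
#'   `correction`, `negative_eigenvalue_share` (sum of |negative| over sum
#'   of |all|, before any correction).
#' @export
pcoa <- function(d, correction = c("none", "lingoes"), n_axes = 2) {
  correction <- match.arg(correction)
  d <- check_dissimilarity(d)
  n <- nrow(d)
  tol <- 1e-9 * max(1, max(d))
  decomp <- function(dm) {
    D2 <- dm^2
    # J (-D2/2) J = -1/2 (D2 - rowmean - colmean + grandmean)
    G <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, n)) -
                   outer(rep(1, n), colMeans(D2)) + mean(D2))
    eigen(G, symmetric = TRUE)
  }
  e <- decomp(d)
  ev <- e$values
  neg_share <- if (sum(abs(ev)) > 0) sum(abs(ev[ev < -tol])) / sum(abs(ev)) else 0
  if (correction == "lingoes" && any(ev < -tol)) {
    cc <- -min(ev)
    d2 <- d^2 + 2 * cc
    diag(d2) <- 0
    e <- decomp(sqrt(d2))
    ev <- e$values
  }
  pos <- which(ev > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  # canonical axis signs: largest-magnitude loading positive
  for (k in seq_len(ncol(coords))) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  keep <- if (is.null(n_axes)) seq_along(pos) else seq_len(min(n_axes, length(pos)))
  coords <- coords[, keep, drop = FALSE]
  dimnames(coords) <- list(rownames(d), paste0("Axis", keep, recycle0 = TRUE))
  structure(list(
    labels = rownames(d),
    coordinates = coords,
    eigenvalues = ev,
    variance_explained = if (length(pos)) ev[pos][keep] / sum(ev[pos]) else numeric(),
    correction = correction,
    negative_eigenvalue_share = neg_share
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA of %d objects: %d positive axes retained (%s correction)\n",
              length(x$labels), ncol(x$coordinates), x$correction))
  if (length(x$variance_explained))
    cat("variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  if (x$negative_eigenvalue_share > 0)
    cat(sprintf("negative eigenvalue share: %.3f\n", x$negative_eigenvalue_share))
  invisible(x)
}

#' Scatter plot of the first two principal coordinates
#'
#' @param x a `pcoa_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pcoa_result <- function(x, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) stop_fb("need at least 2 retained axes to plot")
  lab <- if (length(x$variance_explained) >= 2)
    sprintf("Axis %d (%.1f%%)", 1:2, 100 * x$variance_explained[1:2])
  else paste("Axis", 1:2)
  graphics::plot(co[, 1], co[, 2], xlab = lab[1], ylab = lab[2], pch = 19, ...)
  graphics::text(co[, 1], co[, 2], labels = x$labels, pos = 3, cex = 0.8)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  invisible(x)
}
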