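# Permutation Mantel tests between dissimilarity matrices and geographical
# driver matrices. The null distribution is built by applying a common
# random row/column permutation to the second matrix and recomputing the
# correlation of the upper-triangle vectors; Spearman (midrank ties) is the
# default, matching common practice for checklist data.

#' Pairwise driver matrix from per-area scalars
#'
#' Builds the |value_i - value_j| matrix used to test scalar geographical
#' drivers (drainage area, annual runoff) against compositional
#' dissimilarity. Distance matrices measured directly should be passed to
#' [mantel_test()] as-is.
#'
#' @param values named numeric vector, one finite value per area.
#' @return symmetric matrix of absolute differences, zero diagonal.
#' @export
driver_to_matrix <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop_fb("driver values must be named by area")
  if (anyNA(values) || any(!is.finite(values)))
    stop_fb("missing or non-finite driver value(s) for: ",
            paste(names(values)[!is.finite(values)], collapse = ", "))
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(names(values), names(values))
  if (all(d == 0))
    warn_fb("constant driver: zero matrix (Mantel correlation undefined against it)")
  d
}

# all permutations of 1:n (n <= 8 guard), identity first
all_permutations <- function(n) {
  if (n > 8) stop_fb("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {        # position of n... build by inserting n
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = n - k)
    }
  }
  out
}

#' Permutation Mantel test
#'
#' Correlates the upper-triangle vectors of two labelled symmetric matrices
#' and assesses significance by permuting the object labels of `d2`. The
#' Monte-Carlo p-value uses the +1 correction `p = (k + 1) / (B + 1)` where
#' `k` counts permuted statistics as or more extreme than the observed one,
#' so `p` is never zero. With `exact = TRUE` all `n!` relabelings are
#' enumerated (n <= 8) and `p` is the exact proportion.
#'
#' @param d1,d2 symmetric matrices with matching labels (same order).
#' @param method `"spearman"` (default; midrank ties) or `"pearson"`.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`. Two-sided
#'   is the default because compositional gradients can correlate
#'   negatively with drivers.
#' @param n_permutations Monte-Carlo permutation count (default 9999).
#' @param seed optional integer seed for the permutation draws.
#' @param exact enumerate all relabelings instead of sampling.
#' @return a `mantel_result` list: `r`, `p`, `n_permutations`, `method`,
#'   `tail`, `seed`, `exact`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        tail = c("two_sided", "greater", "less"),
                        n_permutations = 9999, seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  d1 <- check_dissimilarity(as.matrix(d1), "d1")
  d2 <- check_dissimilarity(as.matrix(d2), "d2")
  n <- nrow(d1)
  if (n < 3) stop_fb("Mantel test needs at least 3 objects")
  if (nrow(d2) != n || !identical(rownames(d1), rownames(d2)))
    stop_fb("d1 and d2 must share the same labels in the same order")
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop_fb("constant off-diagonal values: correlation undefined")
  if (method == "spearman") { v1 <- rank(v1); v2 <- rank(v2) }
  m <- length(v1)
  z1 <- (v1 - mean(v1)) / (sd(v1) * sqrt(m - 1))
  z2 <- (v2 - mean(v2)) / (sd(v2) * sqrt(m - 1))
  r_obs <- sum(z1 * z2)

  # pair -> vector-position lookup so a relabeling permutes z2 in O(m)
  posm <- matrix(0L, n, n)
  posm[ut] <- seq_len(m)
  posm <- posm + t(posm)
  pr <- which(ut, arr.ind = TRUE)
  perm_stat <- function(p) {
    sum(z1 * z2[posm[cbind(p[pr[, 1L]], p[pr[, 2L]])]])
  }
  tol <- 1e-12
  extreme <- switch(tail,
    two_sided = function(r) abs(r) >= abs(r_obs) - tol,
    greater   = function(r) r >= r_obs - tol,
    less      = function(r) r <= r_obs + tol)

  if (exact) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, perm_stat)
    p <- mean(extreme(stats))
    n_perm <- nrow(perms)
  } else {
    draw <- function() {
      k <- 0L
      for (b in seq_len(n_permutations))
        if (extreme(perm_stat(sample.int(n)))) k <- k + 1L
      k
    }
    k <- if (is.null(seed)) draw() else with_seed(seed, draw())
    p <- (k + 1) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(list(r = r_obs, p = p, n_permutations = n_perm,
                 method = method, tail = tail, seed = seed, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.3f, p = %.4g (%s%d permutations)\n",
              x$method, x$tail, x$r, x$p, if (x$exact) "exact, " else "",
              x$n_permutations))
  invisible(x)
}

#' Mantel test grid: beta indices x geographical drivers
#'
#' Runs [mantel_test()] for every combination of dissimilarity matrix and
#' driver matrix, producing the familiar drivers table (rows = index,
#' columns = driver r/p).
#'
#' @param betas named list of dissimilarity matrices (e.g.
#'   [beta_decompose()] output).
#' @param drivers named list of driver matrices (scalars are passed through
#'   [driver_to_matrix()] automatically).
#' @param ... passed to [mantel_test()].
#' @param seed optional integer; per-cell seeds are derived from it so each
#'   cell is independently reproducible.
#' @return `data.frame` with one row per (index, driver): `index`, `driver`,
#'   `r`, `p`, `seed`.
#' @export
mantel_grid <- function(betas, drivers, ..., seed = NULL) {
  drivers <- lapply(drivers, function(d) {
    if (is.matrix(d)) d else driver_to_matrix(d)
  })
  cells <- expand.grid(index = names(betas), driver = names(drivers),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell_seed <- if (is.null(seed)) NULL else seed + i
    b <- betas[[cells$index[i]]]
    dr <- drivers[[cells$driver[i]]][rownames(b), rownames(b)]
    res <- tryCatch(mantel_test(b, dr, ..., seed = cell_seed),
                    error = function(e) NULL)
    data.frame(index = cells$index[i], driver = cells$driver[i],
               r = if (is.null(res)) NA_real_ else res$r,
               p = if (is.null(res)) NA_real_ else res$p,
               seed = if (is.null(cell_seed)) NA_integer_ else cell_seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
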