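# Pairwise Sorensen dissimilarity and its Baselga-style decomposition into
# spatial turnover (Simpson dissimilarity) and nestedness-resultant
# components:
#
#   beta_sor = (b + c) / (2a + b + c)
#   beta_sim = min(b, c) / (a + min(b, c))
#   beta_sne = |b - c| / (2a + b + c) * a / (a + min(b, c))
#
# a = species shared by the two areas, b and c = species unique to each.
# The absolute value in beta_sne keeps the component non-negative and makes
# the additive identity beta_sor = beta_sim + beta_sne exact.

#' Matching components of a pair of assemblages
#'
#' @param x,y presence vectors (0/1 or logical) over the same species axis;
#'   if both are named, the names must agree.
#' @return a `pair_components` list with counts `a` (shared), `b` (unique to
#'   `x`), `c` (unique to `y`).
#' @export
pair_components <- function(x, y) {
  if (length(x) != length(y))
    stop_fb("presence vectors must share a species axis (lengths differ)")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y)))
    stop_fb("presence vectors must share a species axis (names differ)")
  x <- as.logical(x); y <- as.logical(y)
  structure(list(a = sum(x & y), b = sum(x & !y), c = sum(!x & y)),
            class = "pair_components")
}

#' Sorensen dissimilarity of a pair
#'
#' `(b + c) / (2a + b + c)`: 0 when the two assemblages are identical, 1
#' when they share no species.
#'
#' @param p a [pair_components()] (or list with `a`, `b`, `c`).
#' @return dissimilarity in \[0, 1\].
#' @export
sorensen <- function(p) {
  with(p, {
    if (a + b + c == 0) stop_fb("Sorensen undefined for two empty assemblages")
    (b + c) / (2 * a + b + c)
  })
}

#' Simpson (spatial turnover) dissimilarity of a pair
#'
#' `min(b, c) / (a + min(b, c))`: the richness-independent replacement
#' component; 0 whenever one assemblage is a subset of the other. When one
#' assemblage is empty (`a = min(b,c) = 0` with species on the other side)
#' the pair is pure nestedness in the vanishing-subset limit and 0 is
#' returned with a warning.
#'
#' @inheritParams sorensen
#' @return dissimilarity in \[0, 1\].
#' @export
simpson_turnover <- function(p) {
  with(p, {
    if (a + min(b, c) == 0) {
      if (b + c == 0) stop_fb("Simpson turnover undefined for two empty assemblages")
      warn_fb("one assemblage is empty: turnover taken as 0 (pure nestedness)")
      return(0)
    }
    min(b, c) / (a + min(b, c))
  })
}

#' Nestedness-resultant dissimilarity of a pair
#'
#' `|b - c| / (2a + b + c) * a / (a + min(b, c))`, i.e. the part of Sorensen
#' dissimilarity not due to turnover, so `sorensen(p) == simpson_turnover(p)
#' + nestedness_component(p)` exactly. For a pair with one empty assemblage
#' the value is `sorensen - simpson = 1` (with the same warning as
#' [simpson_turnover()]).
#'
#' @inheritParams sorensen
#' @return dissimilarity in \[0, 1\].
#' @export
nestedness_component <- function(p) {
  with(p, {
    if (a + min(b, c) == 0) {
      if (b + c == 0) stop_fb("nestedness undefined for two empty assemblages")
      warn_fb("one assemblage is empty: pair treated as pure nestedness")
      return(1)
    }
    abs(b - c) / (2 * a + b + c) * a / (a + min(b, c))
  })
}

#' Pairwise dissimilarity matrix over the areas of an incidence matrix
#'
#' Evaluates one of the three indices for every unordered pair of areas.
#'
#' @param inc an `incidence` object or binary area x species matrix.
#' @param index `"sor"`, `"sim"` or `"sne"`.
#' @return symmetric matrix with zero diagonal, area labels, and attributes
#'   `index` and `period` (taken from `inc` if present).
#' @export
beta_pairwise <- function(inc, index = c("sor", "sim", "sne")) {
  index <- match.arg(index)
  beta_decompose(inc)[[index]]
}

#' All three dissimilarity matrices at once
#'
#' @inheritParams beta_pairwise
#' @return named list of symmetric matrices `sor`, `sim`, `sne` satisfying
#'   `sor == sim + sne` elementwise.
#' @export
beta_decompose <- function(inc) {
  m <- unclass(inc)
  if (nrow(m) < 2) stop_fb("need at least 2 areas")
  storage.mode(m) <- "double"
  A <- tcrossprod(m)                      # shared species a_ij
  rich <- rowSums(m)
  B <- matrix(rich, nrow(m), nrow(m)) - A # unique to row area
  C <- t(B)
  minbc <- pmin(B, C)
  if (any(rich == 0))
    warn_fb("empty assemblage(s): ",
            paste(rownames(m)[rich == 0], collapse = ", "),
            "; affected pairs treated as pure nestedness (sor = sne = 1, sim = 0)")
  tot <- 2 * A + B + C
  if (any(tot[upper.tri(tot)] == 0))
    stop_fb("pair of two empty assemblages: dissimilarity undefined")
  sor <- (B + C) / tot
  sim <- ifelse(A + minbc == 0, 0, minbc / (A + minbc))
  sne <- sor - sim
  diag(sor) <- diag(sim) <- diag(sne) <- 0
  per <- attr(inc, "period")
  out <- list(sor = sor, sim = sim, sne = sne)
  for (i in names(out)) {
    dimnames(out[[i]]) <- list(rownames(m), rownames(m))
    attr(out[[i]], "index") <- i
    attr(out[[i]], "period") <- per
  }
  out
}

#' Area-focal summary of dissimilarity matrices
#'
#' For each area, the mean and sample SD (n-1 denominator) of the pairwise
#' values over the pairs involving that area, for each index; plus a grand
#' `Mean` row holding the unweighted mean of the per-area means (its SD
#' column is the SD of those means).
#'
#' @param betas named list of dissimilarity matrices (as from
#'   [beta_decompose()]), or an `incidence` object (decomposed internally).
#' @return `data.frame` with columns `area`, then `<index>_mean` and
#'   `<index>_sd` per index.
#' @export
beta_area_summary <- function(betas) {
  if (inherits(betas, "incidence")) betas <- beta_decompose(betas)
  areas <- rownames(betas[[1]])
  rows <- lapply(areas, function(a) {
    vals <- lapply(betas, function(d) d[a, setdiff(areas, a)])
    out <- data.frame(area = a, stringsAsFactors = FALSE)
    for (i in names(vals)) {
      out[[paste0(i, "_mean")]] <- mean(vals[[i]])
      out[[paste0(i, "_sd")]] <- sd(vals[[i]])
    }
    out
  })
  out <- do.call(rbind, rows)
  grand <- data.frame(area = "Mean", stringsAsFactors = FALSE)
  for (i in names(betas)) {
    grand[[paste0(i, "_mean")]] <- mean(out[[paste0(i, "_mean")]])
    grand[[paste0(i, "_sd")]] <- sd(out[[paste0(i, "_mean")]])
  }
  out <- rbind(out, grand)
  rownames(out) <- NULL
  out
}

#' Species-subset summary of beta diversity
#'
#' Recomputes the pairwise decomposition on a species subset (e.g. one
#' family, natives only, exotics only) and summarises mean and sample SD
#' over all area pairs. Pairs where both assemblages are empty are dropped;
#' a subset empty everywhere is omitted with a warning.
#'
#' @param inc an `incidence` object.
#' @param subsets named list of species character vectors, **or** provide
#'   `attrs` + `by` to build subsets from an attribute column.
#' @param attrs attribute `data.frame`.
#' @param by attribute column to split on (e.g. `"family"`, `"origin"`).
#' @return `data.frame` with columns `group`, `n_species`, then
#'   `<index>_mean`, `<index>_sd` per index.
#' @export
beta_subset_summary <- function(inc, subsets = NULL, attrs = NULL, by = NULL) {
  if (is.null(subsets)) {
    if (is.null(attrs) || is.null(by))
      stop_fb("provide 'subsets' or both 'attrs' and 'by'")
    at <- match_attributes(colnames(inc), attrs, warn = FALSE)
    subsets <- split(at$species, at[[by]])
  }
  rows <- lapply(names(subsets), function(g) {
    sp <- intersect(subsets[[g]], colnames(inc))
    sub <- unclass(inc)[, sp, drop = FALSE]
    # evaluate pair by pair: pairs of two empty assemblages are undefined
    # and dropped; pairs with one empty assemblage take the pure-nestedness
    # limit (sor = sne = 1, sim = 0)
    pr <- which(upper.tri(diag(nrow(sub))), arr.ind = TRUE)
    vals <- apply(pr, 1L, function(ij) {
      p <- pair_components(sub[ij[1L], ], sub[ij[2L], ])
      if (p$a + p$b + p$c == 0) return(c(NA_real_, NA_real_, NA_real_))
      suppressWarnings(c(sorensen(p), simpson_turnover(p),
                         nestedness_component(p)))
    })
    vals <- matrix(vals, nrow = 3L)
    vals <- vals[, !is.na(vals[1L, ]), drop = FALSE]
    if (length(sp) == 0L || ncol(vals) == 0L) {
      warn_fb("subset '", g, "' has no defined area pairs; omitted")
      return(NULL)
    }
    out <- data.frame(group = g, n_species = length(sp), stringsAsFactors = FALSE)
    for (k in seq_along(c("sor", "sim", "sne"))) {
      i <- c("sor", "sim", "sne")[k]
      v <- vals[k, ]
      out[[paste0(i, "_mean")]] <- mean(v)
      out[[paste0(i, "_sd")]] <- if (length(v) > 1) sd(v) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_fb("no subset with at least 2 non-empty assemblages")
  rownames(out) <- NULL
  out
}

#' Export a dissimilarity matrix as labelled CSV
#'
#' @param d symmetric dissimilarity matrix.
#' @param file output path.
#' @param long also write `<file>` in long pair-list format instead of the
#'   square layout.
#' @return `file`, invisibly.
#' @export
write_dissimilarity <- function(d, file, long = FALSE) {
  if (long) {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    utils::write.csv(data.frame(area1 = rownames(d)[ut[, 1]],
                                area2 = colnames(d)[ut[, 2]],
                                value = d[ut]),
                     file, row.names = FALSE)
  } else {
    utils::write.csv(cbind(area = rownames(d),
                           as.data.frame(d, check.names = FALSE)),
                     file, row.names = FALSE)
  }
  invisible(file)
}
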