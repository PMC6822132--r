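# internal helpers shared across modules

#' Round half-up to one decimal place
#'
#' All printed percentages in the package's reports go through this single
#' rounding rule (round-half-up, one decimal), so that e.g. 6.25 -> 6.3.
#' Base `round()` rounds half-to-even and would give 6.2.
#'
#' @param x numeric vector.
#' @return `x` rounded to one decimal, halves away from zero.
#' @export
#' @examples
#' round1(c(6.25, 29.605, 37.7))
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

# evaluate `code` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# collapse internal whitespace and trim; case is preserved (binomial epithets
# are case-sensitive)
squish <- function(x) gsub("\\s+", " ", trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fb <- function(...) stop(..., call. = FALSE)
warn_fb <- function(...) warning(..., call. = FALSE)

# check a square symmetric zero-diagonal non-negative matrix
check_dissimilarity <- function(d, arg = "d", tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_fb(arg, " must be square")
  if (nrow(d) < 2) stop_fb(arg, " must have at least 2 objects")
  if (any(!is.finite(d))) stop_fb(arg, " contains non-finite values")
  if (max(abs(d - t(d))) > tol) stop_fb(arg, " must be symmetric")
  if (any(abs(diag(d)) > tol)) stop_fb(arg, " must have a zero diagonal")
  if (any(d < -tol)) stop_fb(arg, " must be non-negative")
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  if (is.null(rownames(d))) rownames(d) <- colnames(d) %||% as.character(seq_len(nrow(d)))
  colnames(d) <- rownames(d)
  d
}
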