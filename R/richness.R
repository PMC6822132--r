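# Chao richness estimation, sampling completeness, bootstrap confidence
# intervals, and rarefaction/extrapolation of species accumulation.
#
# Checklist data are presence/absence over repeated survey lists, so the
# incidence form (Q1 = species in exactly one sampling unit, Q2 = in exactly
# two) is the documented default; the abundance form (f1 = singletons,
# f2 = doubletons) uses the same formulas with counts in place of
# incidence frequencies.

#' Chao richness estimate from observed richness and rare-species counts
#'
#' Classic form: `S_obs + q1^2 / (2 q2)` (falls back to the bias-corrected
#' form when `q2 = 0`); bias-corrected form: `S_obs + q1 (q1 - 1) /
#' (2 (q2 + 1))`. `q1`/`q2` are singletons/doubletons for abundance data or
#' uniques/duplicates (species in exactly 1 or 2 sampling units) for
#' incidence data.
#'
#' @param s_obs observed richness.
#' @param q1,q2 rare-species counts (`q1 + q2 <= s_obs`).
#' @param variant `"classic"` or `"bias_corrected"`.
#' @return estimated asymptotic richness (>= `s_obs`).
#' @export
chao_estimate <- function(s_obs, q1, q2, variant = c("classic", "bias_corrected")) {
  variant <- match.arg(variant)
  if (any(c(s_obs, q1, q2) < 0)) stop_fb("counts must be non-negative")
  if (q1 + q2 > s_obs) stop_fb("q1 + q2 cannot exceed s_obs")
  if (q1 == 0) return(s_obs)
  if (variant == "classic" && q2 > 0) return(s_obs + q1^2 / (2 * q2))
  s_obs + q1 * (q1 - 1) / (2 * (q2 + 1))
}

#' Sampling completeness
#'
#' The fraction of the estimated asymptotic richness that was observed,
#' `s_obs / estimate`.
#'
#' @param s_obs observed richness (> 0).
#' @param estimate asymptotic richness estimate (>= `s_obs`).
#' @return completeness in (0, 1].
#' @export
completeness <- function(s_obs, estimate) {
  if (estimate <= 0) stop_fb("estimate must be positive")
  if (s_obs <= 0) stop_fb("s_obs must be positive")
  if (estimate < s_obs) stop_fb("estimate cannot be below s_obs")
  s_obs / estimate
}

#' Chao richness and completeness from an incidence-by-sample matrix
#'
#' Computes observed richness, uniques/duplicates (incidence) or
#' singletons/doubletons (abundance), the Chao estimate with the standard
#' `(T - 1) / T` small-sample factor for incidence data, completeness, and
#' (optionally) a percentile bootstrap CI over resampled sampling units.
#'
#' @param x matrix with sampling units as rows and species as columns;
#'   0/1 incidence (default) or abundance counts.
#' @param type `"incidence"` or `"abundance"` (abundance sums the unit
#'   counts per species and uses f1/f2).
#' @param variant passed to [chao_estimate()].
#' @param n_bootstrap bootstrap replications for the CI (0 = no CI).
#' @param level CI level.
#' @param seed RNG seed for the bootstrap.
#' @return a `richness_estimate` list: `s_obs`, `q1`, `q2`, `estimate`,
#'   `completeness`, `ci_low`, `ci_high`, `n_bootstrap`, `level`, `type`.
#' @export
richness_estimate <- function(x, type = c("incidence", "abundance"),
                              variant = c("classic", "bias_corrected"),
                              n_bootstrap = 100, level = 0.95, seed = NULL) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  x <- as.matrix(x)
  point <- function(m) {
    if (type == "incidence") {
      Ti <- nrow(m)
      Y <- colSums(m > 0)
      s <- sum(Y > 0); q1 <- sum(Y == 1); q2 <- sum(Y == 2)
      corr <- if (Ti > 1) (Ti - 1) / Ti else 1
      est <- if (q1 == 0) s
             else if (variant == "classic" && q2 > 0) s + corr * q1^2 / (2 * q2)
             else s + corr * q1 * (q1 - 1) / (2 * (q2 + 1))
    } else {
      n_i <- colSums(m)
      s <- sum(n_i > 0); q1 <- sum(n_i == 1); q2 <- sum(n_i == 2)
      est <- chao_estimate(s, q1, q2, variant)
    }
    list(s = s, q1 = q1, q2 = q2, est = est)
  }
  pt <- point(x)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (nrow(x) < 2) stop_fb("bootstrap needs at least 2 sampling units")
    reps <- function() vapply(seq_len(n_bootstrap), function(i) {
      point(x[sample.int(nrow(x), replace = TRUE), , drop = FALSE])$est
    }, numeric(1))
    est_b <- if (is.null(seed)) reps() else with_seed(seed, reps())
    ci <- unname(quantile(est_b, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(list(s_obs = pt$s, q1 = pt$q1, q2 = pt$q2, estimate = pt$est,
                 completeness = if (pt$s > 0) completeness(pt$s, pt$est) else NA_real_,
                 ci_low = ci[1], ci_high = ci[2],
                 n_bootstrap = n_bootstrap, level = level, type = type),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "Chao richness (%s): S_obs = %d, Q1 = %d, Q2 = %d, estimate = %.1f, completeness = %.3f\n",
    x$type, x$s_obs, x$q1, x$q2, x$estimate, x$completeness))
  if (!is.na(x$ci_low))
    cat(sprintf("%d%% bootstrap CI (%d reps): [%.1f, %.1f]\n",
                round(100 * x$level), x$n_bootstrap, x$ci_low, x$ci_high))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a statistic
#'
#' Resamples the rows (sampling units) of `x` with replacement, evaluates
#' `statistic` on each resample, and returns the percentile interval of the
#' replicates.
#'
#' @param x matrix/data.frame (rows resampled) or vector (elements
#'   resampled).
#' @param statistic function of a resample returning a single number.
#' @param n_bootstrap number of resamples (default 100).
#' @param level interval level (default 0.95).
#' @param seed RNG seed.
#' @return named vector `c(ci_low, ci_high)` with the replicate vector as
#'   attribute `replicates`.
#' @export
bootstrap_ci <- function(x, statistic, n_bootstrap = 100, level = 0.95,
                         seed = NULL) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n < 2) stop_fb("bootstrap needs at least 2 resampling units")
  one <- if (is.null(dim(x))) function() statistic(x[sample.int(n, replace = TRUE)])
         else function() statistic(x[sample.int(n, replace = TRUE), , drop = FALSE])
  reps <- function() vapply(seq_len(n_bootstrap), function(i) one(), numeric(1))
  r <- if (is.null(seed)) reps() else with_seed(seed, reps())
  ci <- unname(quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(setNames(ci, c("ci_low", "ci_high")), replicates = r)
}

#' Sample-based rarefaction and extrapolation curve
#'
#' Interpolation uses the exact hypergeometric formula for the expected
#' richness in `t` of `T` sampling units,
#' `S(t) = S_obs - sum_i C(T - Y_i, t) / C(T, t)` with `Y_i` the incidence
#' frequency of species `i`. Extrapolation beyond `T` follows the
#' Chao-estimator asymptote,
#' `S(T + t*) = S_obs + f0 (1 - (1 - Q1 / (Q1 + T f0))^t*)` with
#' `f0` the estimated number of undetected species; efforts beyond `2T` are
#' dropped with a warning (the standard practical bound for asymptotic
#' estimators).
#'
#' @param x incidence matrix, sampling units as rows, species as columns.
#' @param grid integer vector of efforts (numbers of units); default
#'   `1:T`.
#' @return `data.frame` with `t`, `richness`, `method`
#'   (`"interpolated"`/`"observed"`/`"extrapolated"`).
#' @export
rarefaction_curve <- function(x, grid = NULL) {
  x <- as.matrix(x) > 0
  Tn <- nrow(x)
  if (Tn < 1) stop_fb("need at least one sampling unit")
  if (is.null(grid)) grid <- seq_len(Tn)
  if (any(grid <= 0)) stop_fb("efforts must be positive")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid > 2 * Tn)) {
    warn_fb("efforts beyond 2T dropped (extrapolation capped at twice the sample)")
    grid <- grid[grid <= 2 * Tn]
  }
  Y <- colSums(x)
  Y <- Y[Y > 0]
  s_obs <- length(Y)
  q1 <- sum(Y == 1); q2 <- sum(Y == 2)
  corr <- if (Tn > 1) (Tn - 1) / Tn else 1
  f0 <- if (q1 == 0) 0
        else if (q2 > 0) corr * q1^2 / (2 * q2)
        else corr * q1 * (q1 - 1) / (2 * (q2 + 1))
  rich <- vapply(grid, function(t) {
    if (t <= Tn) {
      s_obs - sum(exp(lchoose(Tn - Y, t) - lchoose(Tn, t)))
    } else if (f0 == 0 || q1 == 0) {
      s_obs
    } else {
      s_obs + f0 * (1 - (1 - q1 / (q1 + Tn * f0))^(t - Tn))
    }
  }, numeric(1))
  data.frame(t = grid, richness = rich,
             method = ifelse(grid < Tn, "interpolated",
                             ifelse(grid == Tn, "observed", "extrapolated")),
             stringsAsFactors = FALSE)
}

#' Per-area completeness report over survey-unit matrices
#'
#' @param surveys named list (per area) of unit-by-species incidence
#'   matrices, e.g. one period of the `survey` element of a
#'   [generate_metacommunity()] truth.
#' @param ... passed to [richness_estimate()].
#' @return `data.frame` with one row per area: `area`, `s_obs`, `q1`, `q2`,
#'   `estimate`, `completeness`, `ci_low`, `ci_high`.
#' @export
completeness_report <- function(surveys, ...) {
  rows <- lapply(names(surveys), function(a) {
    est <- richness_estimate(surveys[[a]], ...)
    data.frame(area = a, s_obs = est$s_obs, q1 = est$q1, q2 = est$q2,
               estimate = est$estimate, completeness = est$completeness,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
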