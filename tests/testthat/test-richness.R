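# Chao estimation, completeness, bootstrap, rarefaction/extrapolation

test_that("Chao estimates match hand-computed cases", {
  expect_equal(chao_estimate(10, 0, 3), 10)                       # saturated
  expect_equal(chao_estimate(10, 0, 3, "bias_corrected"), 10)
  expect_equal(chao_estimate(4, 2, 1), 6)                         # classic
  expect_equal(chao_estimate(5, 3, 0), 8)                         # f2 = 0 branch
  expect_equal(chao_estimate(5, 3, 0, "bias_corrected"), 8)
  expect_equal(chao_estimate(10, 4, 2, "bias_corrected"), 10 + 4 * 3 / 6)
  expect_error(chao_estimate(5, -1, 0), "non-negative")
  expect_error(chao_estimate(3, 2, 2), "exceed")
})

test_that("classic Chao dominates the bias-corrected form", {
  for (q2 in 1:6) for (q1 in 0:8) {
    s <- q1 + q2 + 5
    expect_gte(chao_estimate(s, q1, q2, "classic"),
               chao_estimate(s, q1, q2, "bias_corrected"))
  }
  # and both coincide when there are no singletons
  for (q2 in 0:4) expect_equal(chao_estimate(9, 0, q2, "classic"),
                               chao_estimate(9, 0, q2, "bias_corrected"))
})

test_that("completeness is observed over estimated richness", {
  expect_equal(completeness(100, 100), 1)
  expect_equal(completeness(95, 100), 0.95)
  expect_error(completeness(10, 9), "below")
  expect_error(completeness(0, 5), "positive")
})

test_that("incidence-based estimates agree with vegan::specpool", {
  x <- withr::with_seed(3, matrix(rbinom(8 * 40, 1, 0.35), nrow = 8))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  est <- richness_estimate(x, n_bootstrap = 0)
  sp <- vegan::specpool(x)
  expect_equal(est$s_obs, sp$Species)
  expect_equal(est$estimate, sp$chao, tolerance = 1e-10)
})

test_that("a saturated survey forces completeness 1", {
  t <- generate_metacommunity(synthetic_config(
    n_areas = 3, pool_size = 60, richness_gradient = c(0.8, 0.6, 0.4),
    detection_prob = 1, survey_units = 4, seed = 13))
  rep <- completeness_report(t$survey$historical, n_bootstrap = 0)
  expect_true(all(rep$q1 == 0))
  expect_true(all(rep$completeness == 1))
  expect_equal(rep$estimate, rep$s_obs)
})

test_that("bootstrap intervals are deterministic under a seed and collapse for constants", {
  x <- matrix(1, 6, 4)
  ci <- bootstrap_ci(x, function(m) sum(colSums(m) > 0), seed = 1)
  expect_equal(unname(ci["ci_low"]), unname(ci["ci_high"]))

  y <- withr::with_seed(2, rnorm(30))
  a <- bootstrap_ci(y, mean, n_bootstrap = 200, seed = 7)
  b <- bootstrap_ci(y, mean, n_bootstrap = 200, seed = 7)
  expect_identical(a, b)
  expect_lt(a["ci_low"], a["ci_high"])
  expect_error(bootstrap_ci(1, mean), "at least 2")
})

test_that("percentile bootstrap of a normal mean covers the truth at ~95%", {
  hits <- withr::with_seed(17, {
    sum(vapply(1:200, function(i) {
      y <- rnorm(100)
      ci <- bootstrap_ci(y, mean, n_bootstrap = 400)
      ci["ci_low"] <= 0 && 0 <= ci["ci_high"]
    }, logical(1)))
  })
  # 95% nominal; percentile bootstrap runs slightly narrow, so accept a
  # generous binomial band around 0.93-0.95
  expect_gte(hits, 175)
  expect_lte(hits, 200)
})

test_that("rarefaction endpoints and closed forms are exact", {
  x <- withr::with_seed(5, matrix(rbinom(5 * 30, 1, 0.4), nrow = 5))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  curve <- rarefaction_curve(x)
  Tn <- nrow(x)
  s_obs <- sum(colSums(x) > 0)
  expect_equal(curve$richness[curve$t == Tn], s_obs)
  expect_equal(curve$method[curve$t == Tn], "observed")
  expect_equal(curve$richness[curve$t == 1], mean(rowSums(x)))
  # monotone non-decreasing, concave on the interpolation range
  expect_true(all(diff(curve$richness) >= -1e-12))
  d2 <- diff(diff(curve$richness[curve$t <= Tn]))
  expect_true(all(d2 <= 1e-12))
  expect_error(rarefaction_curve(x, grid = 0), "positive")
})

test_that("interpolated richness matches a Monte-Carlo subsampling oracle", {
  x <- withr::with_seed(6, matrix(rbinom(5 * 40, 1, 0.35), nrow = 5))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  curve <- rarefaction_curve(x, grid = 3)
  reps <- withr::with_seed(61, vapply(1:10000, function(i) {
    sum(colSums(x[sample.int(5, 3), , drop = FALSE]) > 0)
  }, numeric(1)))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(curve$richness - mean(reps)), 3 * se)
})

test_that("rarefaction interpolation matches vegan::specaccum exactly", {
  x <- withr::with_seed(8, matrix(rbinom(7 * 50, 1, 0.3), nrow = 7))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  curve <- rarefaction_curve(x)
  sa <- vegan::specaccum(x, method = "exact")
  expect_equal(curve$richness[curve$t <= 7], as.numeric(sa$richness),
               tolerance = 1e-10)
})

test_that("extrapolation rises toward the Chao asymptote and caps at 2T", {
  x <- withr::with_seed(9, matrix(rbinom(5 * 60, 1, 0.2), nrow = 5))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  expect_warning(curve <- rarefaction_curve(x, grid = 1:20), "2T")
  expect_equal(max(curve$t), 10)
  expect_true(all(diff(curve$richness) >= -1e-12))
  est <- richness_estimate(x, n_bootstrap = 0)
  expect_lte(max(curve$richness), est$estimate + 1e-9)
  expect_true(all(curve$method[curve$t > 5] == "extrapolated"))
})

test_that("the point estimate lies inside its own bootstrap interval in most runs", {
  x <- withr::with_seed(12, matrix(rbinom(10 * 80, 1, 0.25), nrow = 10))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  inside <- vapply(1:40, function(s) {
    est <- richness_estimate(x, n_bootstrap = 100, seed = s)
    est$ci_low <= est$estimate && est$estimate <= est$ci_high
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
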