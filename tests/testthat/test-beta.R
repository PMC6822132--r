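# Sorensen decomposition: scalar formulas, matrix forms, summaries

test_that("pair components match a set-operation oracle", {
  x <- setNames(c(1, 1, 1, 0, 0), paste0("s", 1:5))
  y <- setNames(c(0, 1, 1, 1, 1), paste0("s", 1:5))
  p <- pair_components(x, y)
  expect_equal(p$a, 2); expect_equal(p$b, 1); expect_equal(p$c, 2)

  ident <- pair_components(x, x)
  expect_equal(ident$a, 3); expect_equal(ident$b, 0); expect_equal(ident$c, 0)

  withr::with_seed(21, {
    for (i in 1:500) {
      n <- sample(3:40, 1)
      a <- setNames(rbinom(n, 1, runif(1, 0.2, 0.8)), paste0("s", 1:n))
      b <- setNames(rbinom(n, 1, runif(1, 0.2, 0.8)), paste0("s", 1:n))
      expect_equal(unclass(pair_components(a, b))[c("a", "b", "c")],
                   oracle_components(a, b))
    }
  })
  expect_error(pair_components(1:3, 1:4), "lengths differ")
  expect_error(pair_components(setNames(c(1, 0), c("x", "y")),
                               setNames(c(1, 0), c("x", "z"))), "names differ")
})

test_that("scalar indices evaluate the printed formulas", {
  p <- list(a = 2, b = 1, c = 3)
  expect_equal(sorensen(p), 0.5)
  expect_equal(simpson_turnover(p), 1 / 3)
  expect_equal(nestedness_component(p), 0.5 - 1 / 3)

  # nested pair: no turnover, nestedness equals the whole Sorensen value
  nest <- list(a = 2, b = 0, c = 3)
  expect_equal(simpson_turnover(nest), 0)
  expect_equal(nestedness_component(nest), 3 / 7)
  expect_equal(nestedness_component(nest), sorensen(nest))

  # balanced uniques carry no nestedness
  bal <- list(a = 3, b = 2, c = 2)
  expect_equal(nestedness_component(bal), 0)

  expect_equal(sorensen(list(a = 4, b = 0, c = 0)), 0)       # identical
  expect_equal(sorensen(list(a = 0, b = 2, c = 3)), 1)       # disjoint
  expect_equal(simpson_turnover(list(a = 0, b = 2, c = 3)), 1)

  # degenerate cases
  empty2 <- list(a = 0, b = 0, c = 0)
  expect_error(sorensen(empty2), "empty")
  expect_error(simpson_turnover(empty2), "empty")
  one_empty <- list(a = 0, b = 0, c = 5)
  expect_warning(expect_equal(simpson_turnover(one_empty), 0), "empty")
  expect_warning(expect_equal(nestedness_component(one_empty), 1), "empty")
})

test_that("the additive identity and bounds hold on random pairs", {
  withr::with_seed(33, {
    for (i in 1:1000) {
      a <- sample(0:30, 1); b <- sample(0:30, 1); c_ <- sample(0:30, 1)
      if (a + b + c_ == 0 || a + min(b, c_) == 0) next
      p <- list(a = a, b = b, c = c_)
      sor <- sorensen(p); sim <- simpson_turnover(p); sne <- nestedness_component(p)
      expect_lt(abs(sor - sim - sne), 1e-12)
      expect_gte(sim, 0); expect_lte(sim, sor); expect_lte(sor, 1)
      if (b == 0 || c_ == 0) expect_equal(sim, 0)
      if (b == c_) expect_equal(sne, 0)
    }
  })
})

test_that("pairwise matrices are symmetric, additive and match the scalar path", {
  inc <- random_incidence(5, 60, p = 0.4, seed = 14)
  b <- beta_decompose(inc)
  for (i in names(b)) {
    expect_equal(b[[i]], t(b[[i]]))
    expect_equal(unname(diag(b[[i]])), rep(0, 5))
    expect_true(all(b[[i]] >= 0 & b[[i]] <= 1))
  }
  expect_lt(max(abs(b$sor - b$sim - b$sne)), 1e-12)

  m <- unclass(inc)
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    p <- pair_components(m[pair[1], ], m[pair[2], ])
    expect_equal(b$sor[pair[1], pair[2]], sorensen(p))
    expect_equal(b$sim[pair[1], pair[2]], simpson_turnover(p))
    expect_equal(b$sne[pair[1], pair[2]], nestedness_component(p))
  }

  expect_equal(beta_pairwise(inc, "sim"), b$sim)
  expect_equal(attr(beta_pairwise(inc, "sor"), "index"), "sor")
})

test_that("pairwise matrices agree with vegan's incidence indices", {
  inc <- random_incidence(6, 80, p = 0.45, seed = 19)
  b <- beta_decompose(inc)
  v_sor <- as.matrix(vegan::betadiver(unclass(inc), "w"))
  v_sim <- as.matrix(vegan::betadiver(unclass(inc), "sim"))
  expect_equal(unclass(b$sor), v_sor, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(b$sim), v_sim, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("nested area chains give an all-zero turnover matrix", {
  m <- matrix(0L, 3, 10, dimnames = list(c("A", "B", "C"), paste0("s", 1:10)))
  m[1, 1:10] <- 1L; m[2, 1:6] <- 1L; m[3, 1:3] <- 1L
  b <- beta_decompose(new_incidence(m, "historical"))
  expect_true(all(b$sim == 0))
  expect_equal(b$sne, b$sor, ignore_attr = TRUE)
})

test_that("relabeling permutes matrices; absent species never matter", {
  inc <- random_incidence(5, 40, seed = 23)
  perm <- c(3, 1, 5, 2, 4)
  inc_p <- new_incidence(unclass(inc)[perm, ], "historical")
  b <- beta_decompose(inc); bp <- beta_decompose(inc_p)
  expect_equal(bp$sor, b$sor[perm, perm], ignore_attr = TRUE)
  expect_equal(bp$sne, b$sne[perm, perm], ignore_attr = TRUE)

  extra <- cbind(unclass(inc), extra1 = 0L, extra2 = 0L)
  b2 <- beta_decompose(new_incidence(extra, "historical"))
  expect_equal(unname(b2$sor), unname(b$sor))
})

test_that("empty assemblages take the pure-nestedness limit with a warning", {
  m <- matrix(c(1, 1, 0, 1, 1, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  m["B", ] <- 0L
  expect_warning(b <- beta_decompose(new_incidence(m, "current")), "empty")
  expect_equal(b$sor["A", "B"], 1)
  expect_equal(b$sim["A", "B"], 0)
  expect_equal(b$sne["A", "B"], 1)
})

test_that("area-focal summaries match brute-force enumeration", {
  inc <- random_incidence(4, 50, seed = 31)
  b <- beta_decompose(inc)
  s <- beta_area_summary(b)
  areas <- rownames(b$sor)
  for (a in areas) {
    vals <- sapply(setdiff(areas, a), function(o) b$sor[a, o])
    expect_equal(s$sor_mean[s$area == a], mean(vals))
    expect_equal(s$sor_sd[s$area == a], sd(vals))
  }
  expect_equal(s$sor_mean[s$area == "Mean"],
               mean(s$sor_mean[s$area != "Mean"]))

  const <- matrix(0.4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(const) <- 0
  sc <- beta_area_summary(list(sor = const))
  expect_true(all(sc$sor_mean == 0.4))
  expect_true(all(sc$sor_sd[sc$area != "Mean"] == 0))
})

test_that("subset summaries recompute on species subsets and omit empty ones", {
  t <- generate_metacommunity(synthetic_config(seed = 12))
  s <- beta_subset_summary(t$current, attrs = t$attributes, by = "origin")
  expect_setequal(s$group, c("native", "introduced"))
  nat_sp <- t$attributes$species[t$attributes$origin == "native"]
  sub <- unclass(t$current)[, intersect(nat_sp, colnames(t$current))]
  b <- beta_decompose(new_incidence(sub, "current"))
  expect_equal(s$sor_mean[s$group == "native"], mean(b$sor[upper.tri(b$sor)]))
  expect_equal(s$sor_sd[s$group == "native"], sd(b$sor[upper.tri(b$sor)]))
  # a subset absent everywhere is omitted with a warning
  expect_warning(
    expect_error(beta_subset_summary(t$current,
                                     subsets = list(ghost = c("no such sp"))),
                 "no subset"),
    "omitted")
})
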