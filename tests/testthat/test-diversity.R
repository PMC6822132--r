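# alpha/gamma richness, extirpation accounting, ecotype loss, red-list tally

test_that("alpha and gamma richness count rows and the species union", {
  m <- new_incidence(matrix(c(1, 1, 0, 0, 0, 1), 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), c("s1", "s2", "s3"))),
                     "historical")
  expect_equal(alpha_richness(m), c(A = 2, B = 1))
  expect_equal(gamma_richness(m), 3)

  zero <- new_incidence(matrix(0L, 2, 3, dimnames = list(c("A", "B"),
                                                         c("s1", "s2", "s3"))),
                        "historical")
  expect_equal(alpha_richness(zero), c(A = 0, B = 0))
  expect_equal(gamma_richness(zero), 0)
})

test_that("gamma is at least max alpha on random matrices", {
  for (s in 1:20) {
    inc <- random_incidence(5, 40, p = 0.3, seed = s)
    expect_gte(gamma_richness(inc), max(alpha_richness(inc)))
  }
  # disjoint areas: gamma is the sum
  m <- new_incidence(cbind(matrix(c(1, 0), 2, 3), matrix(c(0, 1), 2, 4)) * 1L,
                     "historical")
  rownames(m) <- c("A", "B"); colnames(m) <- paste0("s", 1:7)
  expect_equal(gamma_richness(m), 7)
})

test_that("round1 rounds halves up to one decimal", {
  expect_equal(round1(6.25), 6.3)
  expect_equal(round1(3.64), 3.6)
  expect_equal(round1(29.605), 29.6)
  expect_equal(round1(c(0.05, 0.04999)), c(0.1, 0.0))
})

test_that("extirpation summary reproduces published per-area percentages", {
  fx <- table1_fixture()
  hist <- build_incidence(fx$records, "historical", fx$areas)
  curr <- build_incidence(fx$records, "current", fx$areas)
  s <- extirpation_summary(hist, curr, fx$attrs, fx$areas)
  poyang <- s[s$area == "Poyang Lake", ]
  expect_equal(poyang$n_hist_native, 152)
  expect_equal(poyang$n_curr_native, 107)
  expect_equal(poyang$n_extirpated, 45)
  expect_equal(poyang$pct_extirpated, 29.6)
  expect_equal(poyang$pct_introduced, 3.6)
  xiuhe <- s[s$area == "Xiuhe River", ]
  expect_equal(xiuhe$pct_extirpated, 7.2)
  expect_equal(xiuhe$pct_introduced, 8.3)
  # conservation of species accounting
  expect_equal(s$n_extirpated + s$n_curr_native, s$n_hist_native)
})

test_that("extirpation summary handles the no-change and empty-area cases", {
  inc <- random_incidence(3, 15, seed = 4)
  curr <- new_incidence(unclass(inc), "current")
  s <- extirpation_summary(inc, curr)
  expect_true(all(s$n_extirpated == 0))
  expect_true(all(s$pct_extirpated == 0))
  expect_true(all(s$pct_introduced == 0))

  m <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "s1"))
  h <- new_incidence(m, "historical")
  c_ <- new_incidence(m, "current")
  expect_warning(s2 <- extirpation_summary(h, c_), "no historical natives")
  expect_true(is.na(s2$pct_extirpated[s2$area == "B"]))
})

test_that("mean extirpation percentage averages the defined areas", {
  expect_equal(mean_extirpation_pct(c(10.0, 30.0)), 20.0)
  expect_equal(mean_extirpation_pct(c(37.7)), 37.7)
  expect_equal(mean_extirpation_pct(c(25.0, NA, 35.0)), 30.0)
  expect_error(mean_extirpation_pct(numeric()), "no defined")
  s <- data.frame(pct_extirpated = c(29.6, 24.9, 55.1, 62.3, 47.1, 7.2))
  expect_equal(mean_extirpation_pct(s), 37.7)
})

test_that("ecotype loss is basin-wide and excludes unknown categories", {
  at <- data.frame(
    species = paste0("s", 1:6),
    origin = c(rep("native", 5), "introduced"),
    life_habit = c("migration", "migration", "settlement", "settlement", NA,
                   "settlement"),
    stringsAsFactors = FALSE)
  m <- matrix(1L, 2, 6, dimnames = list(c("A", "B"), paste0("s", 1:6)))
  hist <- new_incidence(m, "historical")
  mc <- m
  mc[, c("s1", "s2")] <- 0L   # both migratory natives lost basin-wide
  mc["A", "s3"] <- 0L         # s3 persists in B: not extirpated
  curr <- new_incidence(mc, "current")
  expect_warning(loss <- ecotype_loss(hist, curr, at, "life_habit"),
                 "unknown life_habit")
  expect_equal(loss$pct_extirpated[loss$category == "migration"], 100)
  expect_equal(loss$pct_extirpated[loss$category == "settlement"], 0)
  expect_equal(loss$n_historical[loss$category == "settlement"], 2) # natives only
  expect_error(suppressWarnings(ecotype_loss(hist, curr, at[0, ], "life_habit")),
               "no species")
})

test_that("trait-dependent extirpation rates are recovered across seeds", {
  # demersal-only loss probability 0.35: the pooled basin-wide loss over many
  # generations must sit inside the binomial 95% band around 0.35
  n_hist <- 0L; n_lost <- 0L
  for (s in 1:100) {
    cfg <- synthetic_config(n_areas = 4, pool_size = 80,
                            richness_gradient = c(0.8, 0.65, 0.5, 0.4),
                            extirpation_prob = c(demersal = 0.35),
                            n_introduced = 0, seed = s)
    t <- generate_metacommunity(cfg)
    dem <- t$attributes$species[t$attributes$water_layer == "demersal"]
    dem <- intersect(dem, colnames(t$historical))
    lost <- setdiff(dem, colnames(t$current))
    n_hist <- n_hist + length(dem)
    n_lost <- n_lost + length(lost)
  }
  band <- qbinom(c(0.025, 0.975), n_hist, 0.35)
  expect_gte(n_lost, band[1])
  expect_lte(n_lost, band[2])
})

test_that("red-list tally counts every class, including zeros", {
  at <- data.frame(species = paste0("s", 1:4),
                   red_list = c("CR", "CR", "VU", "LC"),
                   stringsAsFactors = FALSE)
  tab <- redlist_tally(at, at$species)
  expect_equal(unname(tab[c("CR", "VU", "LC", "EN")]), c(2L, 1L, 1L, 0L))
  expect_equal(sum(redlist_tally(at, character())), 0L)
  expect_error(redlist_tally(at, "s9"), "not in attribute table")

  t <- generate_metacommunity(synthetic_config(seed = 6))
  tab2 <- redlist_tally(t$attributes, t$attributes$species)
  expect_equal(sum(tab2), nrow(t$attributes))
  expect_equal(unname(tab2["NE"]),
               sum(t$attributes$red_list == "NE"))
})

test_that("table1_report formats bracketed percentages and its own totals", {
  fx <- table1_fixture()
  hist <- build_incidence(fx$records, "historical", fx$areas)
  curr <- build_incidence(fx$records, "current", fx$areas)
  rep <- table1_report(hist, curr, fx$attrs, fx$areas)
  expect_equal(rep$extirpated[rep$area == "Raohe River"], "40 (47.1%)")
  expect_equal(rep$introduced[rep$area == "Xiuhe River"], "7 (8.3%)")
  tot <- rep[rep$area == "Total", ]
  # totals computed from the table's own columns (gamma over the fixture's
  # area-disjoint pools: sums)
  expect_equal(tot$n_hist_native, sum(c(152, 181, 127, 138, 85, 83)))
  expect_equal(tot$n_introduced, 24)
})
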