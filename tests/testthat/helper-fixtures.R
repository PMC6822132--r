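# fixtures built in code: no data files

# random binary incidence matrix with no empty areas
random_incidence <- function(n_areas, n_species, p = 0.5, seed = NULL,
                             period = "historical") {
  draw <- function() {
    m <- matrix(rbinom(n_areas * n_species, 1L, p), n_areas, n_species,
                dimnames = list(sprintf("A%02d", seq_len(n_areas)),
                                sprintf("sp%03d", seq_len(n_species))))
    empty <- rowSums(m) == 0L
    m[cbind(which(empty), sample.int(n_species, sum(empty), replace = TRUE))] <- 1L
    # no all-zero species columns either (a checklist only lists recorded
    # species, and the long-format round trip relies on that)
    gone <- colSums(m) == 0L
    m[cbind(sample.int(n_areas, sum(gone), replace = TRUE), which(gone))] <- 1L
    m
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_incidence(m, period)
}

# checklist + attributes whose per-area native/extirpated/introduced counts
# equal the published six-unit basin table (hist natives 152/181/127/138/85/83,
# current natives 107/136/57/52/45/77, exotics 4/8/1/1/3/7)
table1_fixture <- function() {
  areas <- c("Poyang Lake", "Ganjiang River", "Fuhe River",
             "Xinjiang River", "Raohe River", "Xiuhe River")
  hist_n <- c(152, 181, 127, 138, 85, 83)
  curr_n <- c(107, 136, 57, 52, 45, 77)
  intro  <- c(4, 8, 1, 1, 3, 7)
  rec <- list(); at <- list()
  for (i in seq_along(areas)) {
    nat <- sprintf("%s native %03d", areas[i], seq_len(hist_n[i]))
    exo <- if (intro[i] > 0) sprintf("%s exotic %02d", areas[i], seq_len(intro[i]))
           else character()
    rec[[i]] <- rbind(
      data.frame(species = nat, area = areas[i], period = "historical",
                 stringsAsFactors = FALSE),
      data.frame(species = nat[seq_len(curr_n[i])], area = areas[i],
                 period = "current", stringsAsFactors = FALSE),
      if (length(exo)) data.frame(species = exo, area = areas[i],
                                  period = "current", stringsAsFactors = FALSE)
    )
    at[[i]] <- data.frame(species = c(nat, exo),
                          origin = c(rep("native", length(nat)),
                                     rep("introduced", length(exo))),
                          stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rec), attrs = do.call(rbind, at),
       areas = areas,
       expected = data.frame(area = areas, pct_extirpated =
                               c(29.6, 24.9, 55.1, 62.3, 47.1, 7.2),
                             pct_introduced = c(3.6, 5.6, 1.7, 1.9, 6.3, 8.3)))
}

# independent set-operation oracle for matching components
oracle_components <- function(x, y) {
  sx <- names(x)[as.logical(x)]
  sy <- names(y)[as.logical(y)]
  list(a = length(intersect(sx, sy)),
       b = length(setdiff(sx, sy)),
       c = length(setdiff(sy, sx)))
}

# independent enumeration of all permutations of 1:n (recursive, test-local)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# Euclidean distance matrix of a random point configuration
random_euclidean <- function(n, dim = 3, seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * dim), n, dim)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
    d
  })
}
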