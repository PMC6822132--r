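# Alpha/gamma richness, extirpation and introduction accounting, and
# ecotype-loss summaries for a two-period incidence pair.

#' Alpha richness: species count per area
#'
#' @param inc an `incidence` object (or binary area x species matrix).
#' @return named integer vector of per-area richness.
#' @export
alpha_richness <- function(inc) {
  rowSums(unclass(inc) == 1L)
}

#' Gamma richness: total species count over all areas
#'
#' @param inc an `incidence` object.
#' @return number of species present in at least one area.
#' @export
gamma_richness <- function(inc) {
  sum(colSums(unclass(inc)) > 0L)
}

# presence of `species` (anywhere / in one area) in an incidence matrix whose
# species axis may not contain all of them (absent column = absent)
present_in <- function(inc, species, area = NULL) {
  m <- unclass(inc)
  idx <- match(species, colnames(m))
  if (is.null(area)) {
    out <- colSums(m)[idx] > 0L
  } else {
    out <- m[area, idx] == 1L
  }
  out[is.na(out)] <- FALSE
  setNames(out, species)
}

#' Per-area extirpation and introduction summary
#'
#' For each area, counts native species recorded historically, natives still
#' recorded currently, extirpated natives (recorded historically, absent
#' currently), and introduced exotics recorded currently. Percentages follow
#' the conventions of published basin summaries: extirpation relative to the
#' historical natives of that area, introduction relative to the current
#' total assemblage (current natives + exotics); both rounded half-up to one
#' decimal via [round1()].
#'
#' @param hist,curr `incidence` objects for the two periods.
#' @param attrs species attribute `data.frame` (needs `species`, `origin`);
#'   species missing from it are treated as native (with a warning).
#' @param areas areas to report; default the union of the two matrices' rows,
#'   in `hist` order.
#' @return `data.frame` with one row per area: `area`, `n_hist_native`,
#'   `n_curr_native`, `n_extirpated`, `pct_extirpated`, `n_introduced`,
#'   `pct_introduced`. Percentages are `NA` (with a warning) where the
#'   denominator is zero.
#' @export
extirpation_summary <- function(hist, curr, attrs = NULL, areas = NULL) {
  if (is.null(areas)) areas <- union(rownames(hist), rownames(curr))
  all_sp <- union(colnames(hist), colnames(curr))
  at <- match_attributes(all_sp, attrs)
  native <- at$species[at$origin == "native"]
  exotic <- at$species[at$origin == "introduced"]
  rows <- lapply(areas, function(a) {
    h_nat <- if (a %in% rownames(hist)) sum(present_in(hist, native, a)) else 0L
    c_nat <- if (a %in% rownames(curr)) sum(present_in(curr, native, a)) else 0L
    n_ext <- h_nat - c_nat
    if (n_ext < 0) {
      warn_fb("area '", a, "': more current than historical natives; ",
              "native colonization present, extirpation count floored at 0")
      n_ext <- 0L
    }
    n_int <- if (a %in% rownames(curr)) sum(present_in(curr, exotic, a)) else 0L
    pct_ext <- if (h_nat > 0) round1(100 * n_ext / h_nat) else NA_real_
    pct_int <- if (c_nat + n_int > 0) round1(100 * n_int / (c_nat + n_int)) else NA_real_
    data.frame(area = a, n_hist_native = h_nat, n_curr_native = c_nat,
               n_extirpated = n_ext, pct_extirpated = pct_ext,
               n_introduced = n_int, pct_introduced = pct_int,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$pct_extirpated))
    warn_fb("area(s) with no historical natives: extirpation percentage undefined")
  rownames(out) <- NULL
  out
}

#' Mean per-area extirpation percentage
#'
#' Arithmetic mean of the per-area extirpation percentages from
#' [extirpation_summary()], rounded half-up to one decimal.
#'
#' @param summary `data.frame` from [extirpation_summary()], or a numeric
#'   vector of percentages.
#' @return a single percentage.
#' @export
mean_extirpation_pct <- function(summary) {
  pct <- if (is.data.frame(summary)) summary$pct_extirpated else summary
  pct <- pct[!is.na(pct)]
  if (length(pct) == 0L) stop_fb("no defined extirpation percentages to average")
  round1(mean(pct))
}

#' Basin-wide ecotype loss along one ecological axis
#'
#' A species counts as extirpated only if it was recorded somewhere
#' historically and is absent from every area currently (basin-wide loss).
#' Species without a category on the chosen axis are excluded (with a
#' warning). Only native species enter the tally.
#'
#' @param hist,curr `incidence` objects.
#' @param attrs attribute `data.frame` with the axis column.
#' @param axis one of `"life_habit"`, `"feeding"`, `"water_layer"`.
#' @return `data.frame` per category: `category`, `n_historical`,
#'   `n_extirpated`, `pct_extirpated` (round-half-up, 1 decimal). Categories
#'   with no historical species are omitted.
#' @export
ecotype_loss <- function(hist, curr, attrs, axis = c("life_habit", "feeding",
                                                     "water_layer")) {
  axis <- match.arg(axis)
  all_sp <- union(colnames(hist), colnames(curr))
  at <- match_attributes(all_sp, attrs)
  at <- at[at$origin == "native", , drop = FALSE]
  unknown <- is.na(at[[axis]])
  if (any(unknown))
    warn_fb(sum(unknown), " species with unknown ", axis,
            " excluded from the ecotype summary")
  at <- at[!unknown, , drop = FALSE]
  if (nrow(at) == 0L) stop_fb("no species classified on axis '", axis, "'")
  h <- present_in(hist, at$species)
  c_ <- present_in(curr, at$species)
  cats <- intersect(ATTR_LEVELS[[axis]], unique(at[[axis]]))
  rows <- lapply(cats, function(k) {
    in_cat <- at[[axis]] == k
    n_hist <- sum(h & in_cat)
    if (n_hist == 0L) return(NULL)
    n_ext <- sum(h & !c_ & in_cat)
    data.frame(category = k, n_historical = n_hist, n_extirpated = n_ext,
               pct_extirpated = round1(100 * n_ext / n_hist),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally red-list categories over a species set
#'
#' @param attrs attribute `data.frame` with a `red_list` column.
#' @param species character vector of species to tally (must all appear in
#'   `attrs`).
#' @return named integer vector over all seven classes (CR, EN, VU, NT, LC,
#'   DD, NE); classes with no species report 0.
#' @export
redlist_tally <- function(attrs, species) {
  missing <- setdiff(species, attrs$species)
  if (length(missing))
    stop_fb("species not in attribute table: ", paste(head(missing, 5), collapse = ", "))
  rl <- attrs$red_list[match(species, attrs$species)]
  tab <- table(factor(rl, levels = ATTR_LEVELS$red_list))
  setNames(as.integer(tab), names(tab))
}

#' Basin summary table: per-area counts with bracketed percentages
#'
#' Formats [extirpation_summary()] as the familiar published layout, with a
#' `Total` row computed from the table's own columns (basin-wide gamma
#' richness for natives, column sums for counts of introduced exotics).
#'
#' @inheritParams extirpation_summary
#' @return `data.frame` with per-area rows plus a `Total` row; the
#'   `extirpated` and `introduced` columns carry "n (p%)" strings alongside
#'   the numeric columns.
#' @export
table1_report <- function(hist, curr, attrs = NULL, areas = NULL) {
  s <- extirpation_summary(hist, curr, attrs, areas)
  all_sp <- union(colnames(hist), colnames(curr))
  at <- match_attributes(all_sp, attrs, warn = FALSE)
  native <- at$species[at$origin == "native"]
  exotic <- at$species[at$origin == "introduced"]
  tot_h <- sum(present_in(hist, native))
  tot_c <- sum(present_in(curr, native))
  tot_i <- sum(present_in(curr, exotic))
  fmt <- function(n, p) ifelse(is.na(p), as.character(n),
                               sprintf("%d (%.1f%%)", n, p))
  s$extirpated <- fmt(s$n_extirpated, s$pct_extirpated)
  s$introduced <- fmt(s$n_introduced, s$pct_introduced)
  total <- data.frame(area = "Total", n_hist_native = tot_h,
                      n_curr_native = tot_c, n_extirpated = tot_h - tot_c,
                      pct_extirpated = NA_real_, n_introduced = tot_i,
                      pct_introduced = NA_real_,
                      extirpated = as.character(tot_h - tot_c),
                      introduced = as.character(tot_i),
                      stringsAsFactors = FALSE)
  rbind(s, total)
}
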