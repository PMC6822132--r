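# Checklist / attribute input and incidence-matrix construction.
#
# The central object is the incidence matrix: a binary area x species table
# for one survey period. Everything downstream (richness, beta partitioning,
# ordination, Mantel) consumes it.

PERIODS <- c("historical", "current")

ATTR_LEVELS <- list(
  origin      = c("native", "introduced"),
  life_habit  = c("migration", "settlement", "mountain_stream"),
  feeding     = c("carnivorous", "herbivorous", "omnivorous"),
  water_layer = c("upper", "lower", "demersal"),
  red_list    = c("CR", "EN", "VU", "NT", "LC", "DD", "NE")
)

#' Map a survey year to a period label
#'
#' Records dated before 2000 belong to the historical period (1980--2000
#' surveys), records from 2000 onwards to the current period (2000--2017).
#' The boundary year 2000 appears in both published ranges; it is assigned to
#' the current period.
#'
#' @param year integer vector of survey years.
#' @return character vector, `"historical"` or `"current"`.
#' @export
period_from_year <- function(year) {
  ifelse(year < 2000, "historical", "current")
}

# parse one period column value: accepts the two labels (case-insensitive),
# or any string containing a 4-digit year, mapped through `rule`
parse_period <- function(x, rule = period_from_year) {
  x <- tolower(squish(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% PERIODS] <- x[x %in% PERIODS]
  pending <- is.na(out)
  if (any(pending)) {
    yr <- regmatches(x[pending], regexpr("\\b(1[89]|20)\\d{2}\\b", x[pending]))
    has_yr <- grepl("\\b(1[89]|20)\\d{2}\\b", x[pending])
    out[pending][has_yr] <- rule(as.integer(yr))
  }
  out
}

#' Read a long-format species checklist
#'
#' Reads a delimited text file with one record per row giving a species, the
#' area it was recorded in, and the survey period (or a year, mapped through
#' `period_rule`). Species and area names are whitespace-normalized; case is
#' preserved. Extra columns are ignored.
#'
#' @param file path or connection to a CSV/TSV file with a header row.
#' @param schema named list mapping the roles `species`, `area`, `period`,
#'   `year`, `source` to column names in the file. `species`, `area` and at
#'   least one of `period`/`year` are mandatory.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param period_rule function mapping survey years to period labels;
#'   default [period_from_year()].
#' @param quiet suppress the record-count message.
#' @return a `data.frame` of checklist records with columns `species`,
#'   `area`, `period` and (if present in the input) `source`.
#' @export
read_checklist <- function(file,
                           schema = list(species = "species", area = "area",
                                         period = "period", year = "year",
                                         source = "source"),
                           sep = NULL, period_rule = period_from_year,
                           quiet = FALSE) {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           fileEncoding = "UTF-8")
  for (role in c("species", "area")) {
    if (!(schema[[role]] %in% names(raw)))
      stop_fb("checklist is missing mandatory column '", schema[[role]],
              "' (role: ", role, ")")
  }
  has_period <- !is.null(schema$period) && schema$period %in% names(raw)
  has_year   <- !is.null(schema$year)   && schema$year   %in% names(raw)
  if (!has_period && !has_year)
    stop_fb("checklist needs a '", schema$period %||% "period",
            "' or '", schema$year %||% "year", "' column")
  if (nrow(raw) == 0L) {
    warn_fb("checklist '", file, "' contains a header but no records")
    return(data.frame(species = character(), area = character(),
                      period = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  period <- rep(NA_character_, nrow(raw))
  if (has_period) period <- parse_period(raw[[schema$period]], period_rule)
  if (has_year) {
    yr <- suppressWarnings(as.integer(squish(raw[[schema$year]])))
    period[is.na(period) & !is.na(yr)] <- period_rule(yr[is.na(period) & !is.na(yr)])
  }
  if (anyNA(period))
    stop_fb("unparseable period value(s) in row(s): ",
            paste(which(is.na(period)), collapse = ", "))
  rec <- data.frame(
    species = squish(raw[[schema$species]]),
    area    = squish(raw[[schema$area]]),
    period  = period,
    stringsAsFactors = FALSE
  )
  if (!is.null(schema$source) && schema$source %in% names(raw))
    rec$source <- squish(raw[[schema$source]])
  if (any(!nzchar(rec$species)))
    stop_fb("empty species name in row(s): ",
            paste(which(!nzchar(rec$species)), collapse = ", "))
  if (!quiet) message(nrow(rec), " checklist records read from '", file, "'")
  rec
}

#' Apply a synonym table to checklist species names
#'
#' Replaces every species name that appears as a key of `synonym_map` by its
#' canonical value. The map must be flat: a value may not itself be a key
#' that maps elsewhere (chained or cyclic maps are rejected), which makes the
#' operation idempotent.
#'
#' @param records checklist `data.frame` as returned by [read_checklist()],
#'   or any data frame with a `species` column.
#' @param synonym_map named character vector, `names()` = synonyms,
#'   values = canonical names; `NULL` or empty leaves the input unchanged.
#' @return the records with canonical species names.
#' @export
normalize_names <- function(records, synonym_map = NULL) {
  if (is.null(synonym_map) || length(synonym_map) == 0L) return(records)
  synonym_map <- setNames(squish(synonym_map), squish(names(synonym_map)))
  if (any(!nzchar(synonym_map)) || any(!nzchar(names(synonym_map))))
    stop_fb("synonym map keys and values must be non-empty names")
  chained <- intersect(unname(synonym_map), names(synonym_map))
  chained <- chained[synonym_map[chained] != chained]
  if (length(chained))
    stop_fb("synonym map is chained/cyclic through: ",
            paste(chained, collapse = ", "),
            " (map synonyms directly to their final canonical name)")
  hit <- records$species %in% names(synonym_map)
  records$species[hit] <- unname(synonym_map[records$species[hit]])
  records
}

#' Build a binary incidence matrix for one period
#'
#' Collapses checklist records of one period into a binary area x species
#' matrix: a cell is 1 if the species was recorded at least once in that
#' area during the period (union over sources; duplicates collapse). The
#' species axis is the union of species seen in the period, ordered
#' lexicographically so the result is invariant to record order; the area
#' axis follows `areas`.
#'
#' @param records checklist `data.frame` (`species`, `area`, `period`).
#' @param period `"historical"` or `"current"`.
#' @param areas ordered character vector of area labels; every record area
#'   must be one of these.
#' @return an `incidence` object: a binary integer matrix (areas x species)
#'   with a `period` attribute.
#' @export
build_incidence <- function(records, period, areas) {
  period <- match.arg(period, PERIODS)
  if (anyDuplicated(areas)) stop_fb("duplicate area labels in 'areas'")
  unknown <- setdiff(unique(records$area), areas)
  if (length(unknown))
    stop_fb("records reference unknown area(s): ", paste(unknown, collapse = ", "))
  rec <- records[records$period == period, , drop = FALSE]
  species <- sort(unique(rec$species))
  if (length(species) == 0L)
    warn_fb("no records for period '", period, "': incidence matrix has 0 species")
  m <- matrix(0L, nrow = length(areas), ncol = length(species),
              dimnames = list(areas, species))
  if (nrow(rec)) m[cbind(rec$area, rec$species)] <- 1L
  new_incidence(m, period)
}

#' @rdname build_incidence
#' @param m binary matrix, rows = areas, columns = species.
#' @export
new_incidence <- function(m, period) {
  period <- match.arg(period, PERIODS)
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop_fb("incidence cells must be 0 or 1")
  if (anyDuplicated(rownames(m))) stop_fb("duplicate area labels")
  if (anyDuplicated(colnames(m))) stop_fb("duplicate species names")
  structure(m, period = period, class = c("incidence", "matrix", "array"))
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("Incidence matrix (%s period): %d areas x %d species, %d presences\n",
              attr(x, "period"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Convert an incidence matrix back to long checklist records
#'
#' @param inc an `incidence` object.
#' @return `data.frame` with columns `species`, `area`, `period`, one row per
#'   presence, ordered by area then species.
#' @export
as_checklist <- function(inc) {
  # column-major order of t(inc) yields rows sorted by area, then species
  idx <- which(t(unclass(inc)) == 1L, arr.ind = TRUE)
  out <- data.frame(
    species = colnames(inc)[idx[, 1L]],
    area    = rownames(inc)[idx[, 2L]],
    period  = rep(attr(inc, "period"), nrow(idx)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Export an incidence matrix as wide CSV plus JSON sidecar
#'
#' Writes rows = areas, columns = species, cells 0/1, and (optionally) a
#' `<file>.json` sidecar recording the period and the row/column order.
#'
#' @param inc an `incidence` object.
#' @param file output CSV path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `file`, invisibly.
#' @export
write_incidence <- function(inc, file, sidecar = TRUE) {
  df <- as.data.frame(unclass(inc), check.names = FALSE)
  df <- cbind(area = rownames(inc), df)
  utils::write.csv(df, file, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(period = attr(inc, "period"),
           areas = rownames(inc), species = colnames(inc)),
      paste0(file, ".json"), auto_unbox = TRUE)
  }
  invisible(file)
}

#' Read a species attribute table
#'
#' Attributes drive the native/introduced accounting and the ecotype-loss
#' summaries. Enum spellings are case-insensitive; `mountain stream`,
#' `mountain-stream` and `mountain_stream` are equivalent. Empty cells in
#' the three ecotype columns become `NA` (unknown; such species are excluded
#' from ecotype summaries, with a warning there).
#'
#' @param file CSV path with columns `species` plus any of `order`, `family`,
#'   `origin`, `life_habit`, `feeding`, `water_layer`, `red_list`.
#' @param sep field delimiter (`NULL` = auto-detect).
#' @return validated attribute `data.frame`, one row per species.
#' @export
read_attributes <- function(file, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  at <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  if (!("species" %in% names(at))) stop_fb("attribute table needs a 'species' column")
  at$species <- squish(at$species)
  validate_attributes(at)
}

# canonicalize + validate attribute enums; shared by read_attributes and the
# synthetic generator
validate_attributes <- function(at) {
  if (anyDuplicated(at$species))
    stop_fb("duplicate species in attribute table: ",
            paste(unique(at$species[duplicated(at$species)]), collapse = ", "))
  for (col in names(ATTR_LEVELS)) {
    if (!(col %in% names(at))) next
    v <- squish(as.character(at[[col]]))
    v[!nzchar(v)] <- NA_character_
    canon <- gsub("[ -]", "_", tolower(v))
    levs <- ATTR_LEVELS[[col]]
    match_idx <- match(canon, gsub("[ -]", "_", tolower(levs)))
    bad <- !is.na(v) & is.na(match_idx)
    if (any(bad))
      stop_fb("invalid ", col, " value(s): ",
              paste(unique(v[bad]), collapse = ", "),
              " (allowed: ", paste(levs, collapse = ", "), ")")
    at[[col]] <- levs[match_idx]
  }
  at
}

# align an attribute table to a species vector; unlisted species default to
# origin = native with unknown ecotypes (they are excluded from ecotype
# summaries downstream)
match_attributes <- function(species, attrs, warn = TRUE) {
  if (is.null(attrs)) {
    attrs <- data.frame(species = character(), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("origin", "life_habit", "feeding", "water_layer",
                            "red_list", "order", "family"), names(attrs))
  for (col in missing_cols) attrs[[col]] <- rep(NA_character_, nrow(attrs))
  idx <- match(species, attrs$species)
  if (warn && anyNA(idx) && nrow(attrs))
    warn_fb(sum(is.na(idx)), " checklist species missing from the attribute ",
            "table; treated as native with unknown ecotypes")
  out <- attrs[idx, , drop = FALSE]
  out$species <- species
  out$origin[is.na(out$origin)] <- "native"
  rownames(out) <- NULL
  out
}
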