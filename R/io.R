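#' Read a table of body-size observation records
#'
#' Parses a delimited text file of individual specimen/capture records into
#' the package's canonical observation table. Unparseable size or date
#' fields become `NA` but never drop a row: the row count of the output
#' equals the row count of the file.
#'
#' @param path CSV file (comma-separated, UTF-8, header row).
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names. Canonical names: `species`, `lat`, `lon`, and
#'   either `date` (ISO `yyyy-mm-dd` or `yyyy-mm`) or `year`/`month`/`day`;
#'   optional: `mass` (g), `length` (mm), `life_stage`, `sex`, `source`,
#'   `exclude`. At least one of `mass`/`length` must be mapped.
#'
#' @return A tibble with columns `species_id`, `year`, `month`, `day`,
#'   `lat`, `lon`, `mass`, `length`, `life_stage`, `sex`, `source`,
#'   `exclude`. Vocabulary columns are raw strings until
#'   [reclassify_vocab()] is applied.
#' @export
read_observations <- function(path, column_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (is.null(column_map)) {
    column_map <- stats::setNames(intersect(obs_canonical_cols(), names(raw)),
                                  intersect(obs_canonical_cols(), names(raw)))
  }
  column_map <- unlist(column_map)

  mapped_missing <- setdiff(unname(column_map), names(raw))
  if (length(mapped_missing) > 0) {
    stop("read_observations: mapped column(s) absent from file: ",
         paste(mapped_missing, collapse = ", "), call. = FALSE)
  }
  need <- c("species", "lat", "lon")
  miss <- setdiff(need, names(column_map))
  has_date <- "date" %in% names(column_map) ||
    all(c("year", "month") %in% names(column_map))
  if (!has_date) miss <- c(miss, "date (or year+month)")
  if (!any(c("mass", "length") %in% names(column_map))) miss <- c(miss, "mass or length")
  if (length(miss) > 0) {
    stop("read_observations: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  pick <- function(key) {
    if (key %in% names(column_map)) raw[[column_map[[key]]]] else rep(NA_character_, nrow(raw))
  }
  if ("date" %in% names(column_map)) {
    d <- parse_date_parts(pick("date"))
    year <- d$year; month <- d$month; day <- d$day
  } else {
    year <- quiet_int(pick("year"))
    month <- quiet_int(pick("month"))
    day <- quiet_int(pick("day"))
  }
  month[!is.na(month) & (month < 1 | month > 12)] <- NA_integer_

  tibble::tibble(
    species_id = pick("species"),
    year = year, month = month, day = day,
    lat = quiet_num(pick("lat")),
    lon = quiet_num(pick("lon")),
    mass = positive_or_na(quiet_num(pick("mass"))),
    length = positive_or_na(quiet_num(pick("length"))),
    life_stage = pick("life_stage"),
    sex = pick("sex"),
    source = pick("source"),
    exclude = tolower(trimws(pick("exclude"))) %in% c("true", "t", "1", "yes")
  )
}

obs_canonical_cols <- function() {
  c("species", "date", "year", "month", "day", "lat", "lon",
    "mass", "length", "life_stage", "sex", "source", "exclude")
}

quiet_num <- function(x) suppressWarnings(as.numeric(x))
quiet_int <- function(x) suppressWarnings(as.integer(x))
positive_or_na <- function(x) ifelse(!is.na(x) & x <= 0, NA_real_, x)

parse_date_parts <- function(x) {
  m <- regmatches(x, regexec("^(\\d{4})-(\\d{1,2})(?:-(\\d{1,2}))?", x))
  get <- function(i) vapply(m, function(p) if (length(p) >= i && nzchar(p[i])) as.integer(p[i]) else NA_integer_, 1L)
  list(year = get(2), month = get(3), day = get(4))
}

#' Read / write species range masks as CSV cell lists
#'
#' A range mask lists the grid cells (cell centers, on a stated companion
#' grid) where a species is present.
#'
#' @param path CSV with columns `species_id`, `lat`, `lon`.
#' @param masks A tibble with those columns (one row per species-cell).
#' @return A tibble with columns `species_id`, `lat`, `lon`.
#' @export
read_range_masks <- function(path) {
  out <- readr::read_csv(path, col_types = "cdd", progress = FALSE)
  stopifnot(all(c("species_id", "lat", "lon") %in% names(out)))
  if (nrow(out) == 0) stop("read_range_masks: empty mask file", call. = FALSE)
  out
}

#' @rdname read_range_masks
#' @export
write_range_masks <- function(masks, path) {
  readr::write_csv(masks[c("species_id", "lat", "lon")], path)
  invisible(path)
}

#' Read a synonym table mapping raw names to canonical binomials
#'
#' Canonical names are fixed points: any canonical name that also appears as
#' a raw name must map to itself, and every canonical name is added as its
#' own key so harmonization is idempotent.
#'
#' @param path CSV with columns `raw`, `canonical`.
#' @return A tibble with columns `raw`, `canonical`.
#' @export
read_synonyms <- function(path) {
  syn <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  stopifnot(all(c("raw", "canonical") %in% names(syn)))
  as_synonym_table(syn)
}

#' @rdname read_synonyms
#' @param syn A data frame with columns `raw`, `canonical`.
#' @export
as_synonym_table <- function(syn) {
  syn <- tibble::as_tibble(syn)[c("raw", "canonical")]
  bad <- syn$raw %in% syn$canonical & syn$raw != syn$canonical
  if (any(bad)) {
    stop("synonym table: canonical name(s) remapped elsewhere: ",
         paste(unique(syn$raw[bad]), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(syn$canonical, syn$raw)
  dplyr::distinct(dplyr::bind_rows(syn, tibble::tibble(raw = extra, canonical = extra)))
}

#' Read a phylogenetic tree from Newick
#'
#' Thin wrapper over [ape::read.tree()] that validates branch lengths and
#' tip uniqueness and, given a species set, reports tips without a match.
#'
#' @param path Newick file.
#' @param species Optional character vector of expected species ids; tips
#'   absent from it are reported with a warning.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, species = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    stop("read_tree: malformed Newick in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("read_tree: duplicated tip labels", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("read_tree: negative branch lengths", call. = FALSE)
  }
  if (!is.null(species)) {
    unmatched <- setdiff(tree$tip.label, species)
    if (length(unmatched) > 0) {
      warning("read_tree: tips not in species set: ",
              paste(unmatched, collapse = ", "), call. = FALSE)
    }
  }
  tree
}
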