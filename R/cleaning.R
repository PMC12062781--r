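#' Remove structurally invalid records
#'
#' Drops records with impossible coordinates (|lat| > 90 or |lon| > 180),
#' coordinates where latitude exactly equals longitude (a classic
#' data-entry artifact), missing coordinates, missing year or month,
#' missing species id, or with neither size measurement. Records carrying a
#' pre-set `exclude` flag (provider-side exclusions such as recaptures) are
#' honoured before all other rules.
#'
#' @param table Observation tibble from [read_observations()].
#' @return List with `table` (retained rows) and `report` (named integer
#'   removal counts; see [cleaning_report()]).
#' @export
filter_invalid_records <- function(table) {
  n0 <- nrow(table)
  counts <- integer(0)
  drop_rule <- function(tab, flag, name) {
    counts[[name]] <<- sum(flag)
    tab[!flag, , drop = FALSE]
  }
  t <- table
  t <- drop_rule(t, isTRUE_vec(t$exclude), "provider_excluded")
  t <- drop_rule(t, is.na(t$lat) | is.na(t$lon), "missing_coordinates")
  t <- drop_rule(t, abs(t$lat) > 90 | abs(t$lon) > 180, "impossible_coordinates")
  t <- drop_rule(t, t$lat == t$lon, "lat_equals_lon")
  t <- drop_rule(t, is.na(t$year) | is.na(t$month), "missing_date")
  t <- drop_rule(t, is.na(t$species_id) | !nzchar(t$species_id), "missing_species")
  t <- drop_rule(t, is.na(t$mass) & is.na(t$length), "missing_size")
  if (nrow(t) == 0) warning("filter_invalid_records: no records retained", call. = FALSE)
  stopifnot(n0 - nrow(t) == sum(counts))
  list(table = t, report = counts)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Reclassify life stage and sex to controlled vocabularies
#'
#' Raw strings are matched case-insensitively against the supplied maps;
#' anything unmapped (including `NA`) becomes `"unknown"`. The operation is
#' idempotent because the canonical values map to themselves.
#'
#' @param table Observation tibble.
#' @param stage_map,sex_map Named character vectors, raw (lower-case) to
#'   canonical. Defaults cover common museum/survey abbreviations.
#' @return The table with `life_stage` in `{adult, juvenile, unknown}` and
#'   `sex` in `{male, female, unknown}`.
#' @export
reclassify_vocab <- function(table, stage_map = default_stage_map(),
                             sex_map = default_sex_map()) {
  map_to <- function(x, map, allowed) {
    key <- tolower(trimws(ifelse(is.na(x), "", x)))
    out <- unname(map[key])
    out[is.na(out) | !out %in% allowed] <- "unknown"
    out
  }
  table$life_stage <- map_to(table$life_stage, stage_map,
                             c("adult", "juvenile", "unknown"))
  table$sex <- map_to(table$sex, sex_map, c("male", "female", "unknown"))
  table
}

#' @rdname reclassify_vocab
#' @export
default_stage_map <- function() {
  c(adult = "adult", ad = "adult", "ad." = "adult", a = "adult", mature = "adult",
    juvenile = "juvenile", juv = "juvenile", "juv." = "juvenile", j = "juvenile",
    immature = "juvenile", subadult = "juvenile", chick = "juvenile",
    nestling = "juvenile", pup = "juvenile", unknown = "unknown", u = "unknown")
}

#' @rdname reclassify_vocab
#' @export
default_sex_map <- function() {
  c(male = "male", m = "male", female = "female", f = "female",
    unknown = "unknown", u = "unknown")
}

#' Harmonize species names against a synonym table
#'
#' Every raw name found in the table is replaced by its canonical binomial.
#' Names absent from the synonym table are flagged (`name_unresolved`
#' column) and excluded from modelling downstream, never silently dropped
#' here.
#'
#' @param table Observation tibble.
#' @param synonyms Synonym table from [read_synonyms()]/[as_synonym_table()].
#' @return The table with harmonized `species_id` and logical
#'   `name_unresolved`.
#' @export
harmonize_names <- function(table, synonyms) {
  idx <- match(table$species_id, synonyms$raw)
  table$name_unresolved <- is.na(idx)
  table$species_id <- ifelse(is.na(idx), table$species_id, synonyms$canonical[idx])
  table
}

#' Assign site ids by coincident geographic location
#'
#' Two records share a site iff their coordinates agree after rounding to
#' `precision_decimals` decimal places (default 4, roughly 11 m at the
#' equator — coincident sampling points, robust to float formatting noise
#' across sources).
#'
#' @param table Observation tibble with valid coordinates.
#' @param precision_decimals Rounding precision.
#' @return The table with an integer `site` column.
#' @export
assign_sites <- function(table, precision_decimals = 4) {
  key <- paste(sprintf("%.*f", precision_decimals, table$lat),
               sprintf("%.*f", precision_decimals, table$lon))
  table$site <- as.integer(factor(key, levels = unique(key)))
  table
}

#' Robust MAD filter for likely juveniles and outliers
#'
#' Per species, the median `M` and the (unscaled) median absolute deviation
#' `MAD = median(|x - M|)` of the metric are computed on adult records
#' only; adult and unknown-stage records are then retained iff their value
#' lies within `M - k MAD` to `M + k MAD` inclusive. Removals below the
#' band are counted as likely juveniles, above as outliers (plausible
#' digitization errors). Species whose adult MAD is zero are retained in
#' full with a warning; species with no adult record lose all their
#' unknown-stage records (no reference to filter against). Juvenile-stage
#' records must already have been removed.
#'
#' @param table Observation tibble (no `life_stage == "juvenile"` rows).
#' @param metric `"mass"` or `"length"`.
#' @param k Band half-width in MADs (default 5).
#' @return List with `table`, and `report` counting `mad_below` (likely
#'   juvenile), `mad_above` (outlier) and `no_adult_reference` removals.
#'   Records with a missing metric are passed through untouched.
#' @export
mad_filter <- function(table, metric = "mass", k = 5) {
  stopifnot(metric %in% c("mass", "length"))
  if (any(table$life_stage == "juvenile", na.rm = TRUE)) {
    stop("mad_filter: juvenile records must be removed first", call. = FALSE)
  }
  x <- table[[metric]]
  sp <- table$species_id
  keep <- rep(TRUE, nrow(table))
  below <- above <- no_ref <- 0L
  zero_mad_species <- character(0)

  for (s in unique(sp)) {
    rows <- which(sp == s & !is.na(x))
    if (length(rows) == 0) next
    adults <- rows[table$life_stage[rows] == "adult"]
    if (length(adults) == 0) {
      keep[rows] <- FALSE
      no_ref <- no_ref + length(rows)
      next
    }
    m <- stats::median(x[adults])
    mad <- stats::median(abs(x[adults] - m))
    if (mad == 0) {
      zero_mad_species <- c(zero_mad_species, s)
      next
    }
    lo <- x[rows] < m - k * mad
    hi <- x[rows] > m + k * mad
    keep[rows[lo | hi]] <- FALSE
    below <- below + sum(lo)
    above <- above + sum(hi)
  }
  if (length(zero_mad_species) > 0) {
    warning("mad_filter: zero adult MAD for ",
            paste(zero_mad_species, collapse = ", "),
            "; all records retained for these species", call. = FALSE)
  }
  list(table = table[keep, , drop = FALSE],
       report = c(mad_below = below, mad_above = above,
                  no_adult_reference = no_ref))
}

#' Drop species with too few unique measurements
#'
#' A measurement is "unique" if its (value, year, month, day, lat, lon)
#' tuple is distinct — exact duplicate ingestions count once. Applied
#' independently per metric, so the mass and length datasets retain
#' different species sets.
#'
#' @param table Observation tibble.
#' @param metric `"mass"` or `"length"`.
#' @param n_min Minimum unique count (default 100).
#' @return List with `table` (records of retained species that carry the
#'   metric), and `report` with the rows removed and species counts.
#' @export
min_count_filter <- function(table, metric = "mass", n_min = 100) {
  stopifnot(metric %in% c("mass", "length"))
  has <- !is.na(table[[metric]])
  tab <- table[has, , drop = FALSE]
  uniq <- tab |>
    dplyr::distinct(.data$species_id, .data[[metric]], .data$year, .data$month,
                    .data$day, .data$lat, .data$lon) |>
    dplyr::count(.data$species_id)
  keep_species <- uniq$species_id[uniq$n >= n_min]
  out <- tab[tab$species_id %in% keep_species, , drop = FALSE]
  list(table = out,
       report = c(below_min_count = nrow(tab) - nrow(out),
                  metric_missing = sum(!has)),
       species_retained = keep_species)
}

#' Derive log and ratio size metrics
#'
#' Adds `log10_mass`, `log10_length` and the volume-to-surface-area proxy
#' `mass_length_ratio = mass^(1/3) / length`, each only where the inputs
#' are present. Non-positive sizes are flagged invalid (they should have
#' been caught at parse time).
#'
#' @param table Observation tibble.
#' @return The table with the derived columns.
#' @export
derive_size_metrics <- function(table) {
  bad <- (isTRUE_vec(table$mass <= 0)) | (isTRUE_vec(table$length <= 0))
  if (any(bad)) {
    warning("derive_size_metrics: ", sum(bad), " record(s) with non-positive size flagged",
            call. = FALSE)
  }
  table$size_invalid <- bad
  table$log10_mass <- ifelse(!is.na(table$mass) & table$mass > 0,
                             log10(table$mass), NA_real_)
  table$log10_length <- ifelse(!is.na(table$length) & table$length > 0,
                               log10(table$length), NA_real_)
  both <- !is.na(table$mass) & !is.na(table$length) & !bad
  table$mass_length_ratio <- ifelse(both, table$mass^(1 / 3) / table$length, NA_real_)
  table
}

#' Run the full record-cleaning pipeline for one size metric
#'
#' Fixed, logged order: invalid-record filter, vocabulary reclassification,
#' name harmonization, site assignment, juvenile removal, MAD filter,
#' minimum-count filter, derived metrics. Covariate attachment happens
#' between harmonization and juvenile removal when cubes are supplied via
#' `attach` (a function taking and returning the table), mirroring the
#' extract-then-filter order of the source pipeline. The cleaner is
#' idempotent: rerunning it on its own output changes nothing.
#'
#' @param table Raw observation tibble.
#' @param metric `"mass"` or `"length"`.
#' @param synonyms Optional synonym table.
#' @param attach Optional function attaching covariates, applied after
#'   harmonization.
#' @param mad_k MAD band half-width (default 5).
#' @param n_min Minimum unique measurements per species (default 100).
#' @param site_decimals Site rounding precision (default 4).
#' @return List with `table` (clean records), `report` (a
#'   `cleaning_report`), and `species_retained`.
#' @export
clean_observations <- function(table, metric = "mass", synonyms = NULL,
                               attach = NULL, mad_k = 5, n_min = 100,
                               site_decimals = 4) {
  n_input <- nrow(table)
  f1 <- filter_invalid_records(table)
  t <- reclassify_vocab(f1$table)
  unresolved <- 0L
  if (!is.null(synonyms)) {
    t <- harmonize_names(t, synonyms)
    unresolved <- sum(t$name_unresolved)
    t <- t[!t$name_unresolved, , drop = FALSE]
  }
  t <- assign_sites(t, site_decimals)
  if (!is.null(attach)) t <- attach(t)

  juv <- t$life_stage == "juvenile"
  n_juv <- sum(juv)
  t <- t[!juv, , drop = FALSE]

  f2 <- mad_filter(t, metric = metric, k = mad_k)
  f3 <- min_count_filter(f2$table, metric = metric, n_min = n_min)
  out <- derive_size_metrics(f3$table)

  report <- cleaning_report(
    c(f1$report, name_unresolved = unresolved, juvenile_stage = n_juv,
      f2$report, f3$report),
    n_input = n_input, n_output = nrow(out))
  list(table = out, report = report, species_retained = f3$species_retained)
}

#' Cleaning report
#'
#' Named removal counts per rule plus input/output row counts. The class
#' checks the ledger property that removals reconcile exactly with the row
#' delta.
#'
#' @param counts Named integer vector of removals per rule.
#' @param n_input,n_output Row counts before/after.
#' @return A `cleaning_report` object (list).
#' @export
cleaning_report <- function(counts, n_input, n_output) {
  if (sum(counts) != n_input - n_output) {
    stop("cleaning_report: removal counts (", sum(counts),
         ") do not reconcile with row delta (", n_input - n_output, ")",
         call. = FALSE)
  }
  structure(list(counts = counts, n_input = n_input, n_output = n_output),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d -> %d rows (%d removed)\n",
              x$n_input, x$n_output, x$n_input - x$n_output))
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
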