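#' Niche position index
#'
#' The scaled position of an observed climate value within a species'
#' derived niche: `(n_m - n_min) / (n_max - n_min)`. Applied to monthly
#' maximum temperature this is the thermal position index (TPI); applied to
#' the aridity index it is the aridity position index (API). 0 and 1 mark
#' the derived lower and upper limits; values outside `[0, 1]` are
#' meaningful (conditions beyond the derived tolerance limits) and are
#' never truncated.
#'
#' @param n_m Observed value(s).
#' @param n_min,n_max Lower and upper niche limits; `n_max > n_min`.
#' @return Numeric vector of position indices.
#' @export
position_index <- function(n_m, n_min, n_max) {
  if (any(!is.na(n_min) & !is.na(n_max) & n_max <= n_min)) {
    stop("position_index: degenerate limits (n_max <= n_min)", call. = FALSE)
  }
  (n_m - n_min) / (n_max - n_min)
}

#' Mean position index over several time units
#'
#' Arithmetic mean of unit-wise position indices, each computed against the
#' limits matching its own time unit.
#'
#' @param n_m Observed values, one per time unit.
#' @param n_min,n_max Matching unit-wise limits (recycled if scalar).
#' @return A single mean position index.
#' @export
position_index_mean <- function(n_m, n_min, n_max) {
  stopifnot(length(n_m) >= 1)
  mean(position_index(n_m, n_min, n_max))
}

#' Attach thermal and aridity position indices to observations
#'
#' Looks up the monthly climate value at each record's grid cell, year and
#' month, matches the record's species and month to its niche limits, and
#' computes the position index. Audit columns (the observed value and the
#' limits used) are kept alongside each index. Records whose cell-month
#' climate value is missing (e.g. aridity over snow) get a missing index;
#' they are counted but never dropped here.
#'
#' @param table Observation tibble with `species_id`, `year`, `month`,
#'   `lat`, `lon`.
#' @param tmax_cube,ai_cube Monthly `climate_cube`s (either may be `NULL`
#'   to skip that index).
#' @param limits Niche-limit table from [derive_limits()] covering every
#'   (species, month, variable) needed.
#' @return The table with new columns `tpi`, `tpi_nm`, `tpi_nmin`,
#'   `tpi_nmax` and/or `api`, `api_nm`, `api_nmin`, `api_nmax`, plus an
#'   attribute `n_missing_index` counting records with a missing index.
#' @export
attach_climate_indices <- function(table, tmax_cube = NULL, ai_cube = NULL, limits) {
  out <- table
  n_missing <- 0L
  for (spec in list(list(cube = tmax_cube, var = "tmax", prefix = "tpi"),
                    list(cube = ai_cube, var = "ai", prefix = "api"))) {
    if (is.null(spec$cube)) next
    out <- attach_one_index(out, spec$cube, limits, spec$var, spec$prefix)
    n_missing <- n_missing + sum(is.na(out[[spec$prefix]]))
  }
  attr(out, "n_missing_index") <- n_missing
  out
}

attach_one_index <- function(table, cube, limits, var, prefix) {
  lim <- limits[limits$variable == var,
                c("species_id", "month", "n_min", "n_max")]
  needed <- dplyr::distinct(table[c("species_id", "month")])
  uncovered <- dplyr::anti_join(needed, lim, by = c("species_id", "month"))
  if (nrow(uncovered) > 0) {
    stop("attach_climate_indices: no ", var, " limits for ",
         paste(utils::head(paste0(uncovered$species_id, "/m", uncovered$month), 5),
               collapse = ", "), call. = FALSE)
  }
  cells <- snap_to_grid(cube, table$lat, table$lon)
  vals <- tibble::as_tibble(cube)
  names(vals)[names(vals) == "value"] <- ".obs_value"
  joined <- dplyr::bind_cols(table, cells) |>
    dplyr::left_join(vals,
                     by = c(cell_lat = "lat", cell_lon = "lon",
                            year = "year", month = "month")) |>
    dplyr::left_join(lim, by = c("species_id", "month"))
  degenerate <- !is.na(joined$n_min) & !is.na(joined$n_max) &
    joined$n_max <= joined$n_min
  n_m <- joined$.obs_value
  idx <- ifelse(is.na(n_m) | is.na(joined$n_min) | is.na(joined$n_max) | degenerate,
                NA_real_,
                (n_m - joined$n_min) / (joined$n_max - joined$n_min))
  table[[prefix]] <- idx
  table[[paste0(prefix, "_nm")]] <- n_m
  table[[paste0(prefix, "_nmin")]] <- joined$n_min
  table[[paste0(prefix, "_nmax")]] <- joined$n_max
  table
}

#' Attach agricultural and urban land-use fractions
#'
#' ALU is the summed cropland and pasture fraction of the observation's
#' quadrat in the observation year; ULU is the urban fraction. Sums above 1
#' are clamped to 1 with a warning. Years outside the land-use coverage use
#' the nearest covered year, with a warning.
#'
#' @param table Observation tibble.
#' @param cropland_cube,pasture_cube,urban_cube Yearly fraction
#'   `climate_cube`s on a common grid.
#' @return The table with `alu` and `ulu` columns.
#' @export
attach_landuse <- function(table, cropland_cube, pasture_cube, urban_cube) {
  years_avail <- sort(unique(cropland_cube$year))
  yr <- table$year
  matched <- years_avail[pmax(1L, findInterval(yr, years_avail))]
  # findInterval is a floor; snap to the nearer neighbour above when closer
  upper <- years_avail[pmin(length(years_avail), findInterval(yr, years_avail) + 1L)]
  matched <- ifelse(abs(upper - yr) < abs(matched - yr), upper, matched)
  if (any(!yr %in% years_avail, na.rm = TRUE)) {
    warning("attach_landuse: observation year(s) outside land-use coverage; ",
            "nearest covered year used", call. = FALSE)
  }

  lookup <- function(cube) {
    cells <- snap_to_grid(cube, table$lat, table$lon)
    key <- dplyr::bind_cols(cells, tibble::tibble(year = matched))
    vals <- tibble::as_tibble(cube)[c("lat", "lon", "year", "value")]
    dplyr::left_join(key, vals,
                     by = c(cell_lat = "lat", cell_lon = "lon", "year"))$value
  }
  crop <- lookup(cropland_cube)
  past <- lookup(pasture_cube)
  alu <- crop + past
  if (any(alu > 1, na.rm = TRUE)) {
    warning("attach_landuse: cropland + pasture exceeds 1 for ",
            sum(alu > 1, na.rm = TRUE), " record(s); clamped to 1", call. = FALSE)
    alu <- pmin(alu, 1)
  }
  table$alu <- alu
  table$ulu <- lookup(urban_cube)
  table
}

#' Attach the biogeographic realm label
#'
#' @param table Observation tibble.
#' @param realm_cube Static categorical `climate_cube` of realm labels.
#' @return The table with a `realm` column; records over a missing realm
#'   cell get `NA` and are counted in attribute `n_missing_realm`.
#' @export
attach_realm <- function(table, realm_cube) {
  cells <- snap_to_grid(realm_cube, table$lat, table$lon)
  vals <- tibble::as_tibble(realm_cube)[c("lat", "lon", "value")]
  table$realm <- dplyr::left_join(cells, vals,
                                  by = c(cell_lat = "lat", cell_lon = "lon"))$value
  attr(table, "n_missing_realm") <- sum(is.na(table$realm))
  table
}

#' Z-score columns of a table
#'
#' Centers and scales each named column by its own mean and standard
#' deviation over the rows of `table`, returning the transform parameters
#' for back-transformation. Interaction terms must be formed from z-scored
#' main effects, i.e. after this step.
#'
#' @param table A data frame.
#' @param columns Character vector of numeric column names.
#' @return List with `table` (transformed), `means`, `sds`.
#' @export
zscore_columns <- function(table, columns) {
  means <- vapply(columns, function(cl) mean(table[[cl]], na.rm = TRUE), 0)
  sds <- vapply(columns, function(cl) stats::sd(table[[cl]], na.rm = TRUE), 0)
  zero <- columns[!is.na(sds) & sds == 0]
  if (length(zero) > 0) {
    stop("zscore_columns: zero standard deviation in column(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  for (cl in columns) table[[cl]] <- (table[[cl]] - means[[cl]]) / sds[[cl]]
  list(table = table, means = means, sds = sds)
}
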