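#' Construct a climate cube
#'
#' A climate cube is a long-format tibble of values on a regular lat/lon
#' lattice of cell centers, optionally indexed by `(year, month)`. It is the
#' package's container for gridded monthly climate (`tmax`, `ppt`, `pet`,
#' `ai`), yearly land-use fractions (`cropland`, `pasture`, `urban`) and the
#' static biogeographic-realm layer (`realm`).
#'
#' @param data A data frame with columns `lat`, `lon`, `value`, and
#'   optionally `year` and `month`. `value` may be numeric or, for the realm
#'   layer, character. Missing values are allowed and preserved.
#' @param variable Variable name, one of
#'   `"tmax"`, `"ppt"`, `"pet"`, `"ai"`, `"cropland"`, `"pasture"`,
#'   `"urban"`, `"realm"`.
#' @param res Grid resolution in decimal degrees (> 0).
#' @param units Free-text units label (e.g. `"degC"`, `"mm/month"`).
#'
#' @return A tibble of class `climate_cube` with attributes `variable`,
#'   `res` and `units`. Rows are ordered by time then latitude then
#'   longitude.
#' @export
climate_cube <- function(data, variable, res, units = "") {
  variable <- match.arg(variable, cube_variables())
  stopifnot(is.numeric(res), length(res) == 1L, res > 0)
  data <- tibble::as_tibble(data)
  need <- c("lat", "lon", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("climate_cube: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"year" %in% names(data)) data$year <- NA_integer_
  if (!"month" %in% names(data)) data$month <- NA_integer_
  data <- data[c("lat", "lon", "year", "month", "value")]

  ok_lat <- all(data$lat >= -90 & data$lat <= 90)
  ok_lon <- all(data$lon >= -180 & data$lon <= 180)
  if (!ok_lat || !ok_lon) {
    stop("climate_cube: cell centers outside [-90, 90] x [-180, 180]", call. = FALSE)
  }
  check_lattice(data$lat, res, "lat")
  check_lattice(data$lon, res, "lon")
  if (variable %in% c("cropland", "pasture", "urban")) {
    v <- data$value
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("climate_cube: fraction-valued variable '", variable,
           "' outside [0, 1]", call. = FALSE)
    }
  }
  data <- dplyr::arrange(data, .data$year, .data$month, .data$lat, .data$lon)
  structure(data,
            class = c("climate_cube", class(tibble::tibble())),
            variable = variable, res = res, units = units)
}

cube_variables <- function() {
  c("tmax", "ppt", "pet", "ai", "cropland", "pasture", "urban", "realm")
}

# all coordinates must sit on one lattice with spacing `res`
check_lattice <- function(x, res, what) {
  u <- sort(unique(x))
  if (length(u) > 1) {
    k <- (u - u[1]) / res
    if (any(abs(k - round(k)) > 1e-6)) {
      stop("climate_cube: ", what, " centers are not on a regular grid of ",
           res, " degrees", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.climate_cube <- function(x, ...) {
  cat(sprintf("<climate_cube> variable=%s res=%g%s cells=%d\n",
              cube_variable(x), cube_res(x),
              if (nzchar(cube_units(x))) paste0(" units=", cube_units(x)) else "",
              nrow(dplyr::distinct(tibble::as_tibble(x)[c("lat", "lon")]))))
  NextMethod()
}

#' Cube metadata accessors
#'
#' @param x A `climate_cube`.
#' @return The variable name, grid resolution (degrees) or units string.
#' @export
cube_variable <- function(x) attr(x, "variable")

#' @rdname cube_variable
#' @export
cube_res <- function(x) attr(x, "res")

#' @rdname cube_variable
#' @export
cube_units <- function(x) attr(x, "units")

#' Snap points to the cube's grid cells
#'
#' A point belongs to the cell whose half-open square
#' `[center - res/2, center + res/2)` contains it. Points falling outside
#' the lattice spanned by the cube's cells get `NA` centers.
#'
#' @param cube A `climate_cube` (only its lattice is used).
#' @param lat,lon Numeric vectors of point coordinates (decimal degrees).
#' @return A tibble with columns `cell_lat` and `cell_lon` (cell centers).
#' @export
snap_to_grid <- function(cube, lat, lon) {
  res <- cube_res(cube)
  tibble::tibble(
    cell_lat = snap_axis(lat, sort(unique(cube$lat)), res),
    cell_lon = snap_axis(lon, sort(unique(cube$lon)), res)
  )
}

snap_axis <- function(x, centers, res) {
  lo <- centers[1] - res / 2
  idx <- floor((x - lo) / res + 1e-9)
  ctr <- centers[1] + idx * res
  # only centers actually present count as inside the grid
  ctr[!round(ctr, 9) %in% round(centers, 9)] <- NA_real_
  ctr
}

#' Write / read a climate cube as long-format CSV
#'
#' The on-disk format is a plain CSV with columns
#' `lat, lon, year, month, value`, preceded by a single comment line holding
#' the cube metadata (`variable`, `res`, `units`). Values round-trip
#' bit-exactly for finite numbers; missing cells are written as empty fields
#' and read back as `NA`, never zero-filled.
#'
#' @param cube A `climate_cube`.
#' @param path File path.
#' @return `write_climate_cube` returns `path` invisibly;
#'   `read_climate_cube` returns a `climate_cube`.
#' @export
write_climate_cube <- function(cube, path) {
  stopifnot(inherits(cube, "climate_cube"))
  meta <- sprintf("# climate_cube variable=%s res=%.17g units=%s",
                  cube_variable(cube), cube_res(cube), cube_units(cube))
  out <- tibble::as_tibble(cube)
  # print doubles at 17 significant digits so reading back is bit-exact
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out$lat <- fmt(out$lat)
  out$lon <- fmt(out$lon)
  if (is.numeric(out$value)) out$value <- fmt(out$value)
  readr::write_lines(meta, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_climate_cube
#' @export
read_climate_cube <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  m <- regmatches(first,
                  regexec("^# climate_cube variable=(\\S+) res=(\\S+) units=(.*)$", first))[[1]]
  if (length(m) != 4L) {
    stop("read_climate_cube: '", path, "' lacks the climate_cube metadata line",
         call. = FALSE)
  }
  variable <- m[2]
  res <- as.numeric(m[3])
  units <- m[4]
  classes <- c(lat = "numeric", lon = "numeric", year = "integer",
               month = "integer",
               value = if (identical(variable, "realm")) "character" else "numeric")
  # base strtod parsing: bit-exact for the 17-digit representation we write
  data <- tibble::as_tibble(utils::read.csv(path, skip = 1L, colClasses = classes,
                                            na.strings = c("", "NA")))
  climate_cube(data, variable = variable, res = res, units = units)
}
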