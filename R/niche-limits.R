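#' Aridity index from precipitation and potential evapotranspiration
#'
#' AI = PPT / PET per cell-month; larger values are wetter. Cells where PET
#' is missing or non-positive (e.g. snow-covered areas, which carry no PET)
#' get a missing AI rather than an infinite or negative ratio.
#'
#' @param ppt_cube,pet_cube `climate_cube`s of monthly precipitation and
#'   potential evapotranspiration on identical grids and time indices.
#' @return A `climate_cube` of variable `"ai"` (dimensionless).
#' @export
compute_ai <- function(ppt_cube, pet_cube) {
  stopifnot(inherits(ppt_cube, "climate_cube"), inherits(pet_cube, "climate_cube"))
  if (!isTRUE(all.equal(cube_res(ppt_cube), cube_res(pet_cube)))) {
    stop("compute_ai: grid resolutions differ", call. = FALSE)
  }
  a <- tibble::as_tibble(ppt_cube)
  b <- tibble::as_tibble(pet_cube)
  same_index <- nrow(a) == nrow(b) &&
    all(vapply(c("lat", "lon", "year", "month"),
               function(cl) identical(unname(unclass(a[[cl]])),
                                      unname(unclass(b[[cl]]))), TRUE))
  if (!same_index) {
    stop("compute_ai: ppt and pet cubes are not on the same grid/time index",
         call. = FALSE)
  }
  ai <- ifelse(is.na(b$value) | b$value <= 0, NA_real_, a$value / b$value)
  climate_cube(dplyr::mutate(a, value = ai), variable = "ai",
               res = cube_res(ppt_cube), units = "")
}

#' Tukey fences from the interquartile range
#'
#' Quartiles follow the type-7 (linear interpolation) convention; the fences
#' are `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#'
#' @param values Numeric vector with at least two finite values.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
iqr_fences <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    stop("iqr_fences: need at least 2 finite values", call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Replace out-of-fence values by the fence values
#'
#' Single pass: values above the upper fence are set to the upper fence,
#' values below the lower fence to the lower fence. Missing values pass
#' through untouched.
#'
#' @param values Numeric vector.
#' @param fences Output of [iqr_fences()] on these values.
#' @return List with `values`, `n_replaced_upper`, `n_replaced_lower`.
#' @export
clamp_to_fences <- function(values, fences) {
  hi <- !is.na(values) & values > fences[["upper"]]
  lo <- !is.na(values) & values < fences[["lower"]]
  values[hi] <- fences[["upper"]]
  values[lo] <- fences[["lower"]]
  list(values = values,
       n_replaced_upper = sum(hi),
       n_replaced_lower = sum(lo))
}

#' Derive per-species monthly niche limits over a baseline period
#'
#' For each species and calendar month, the range-wide minimum and maximum
#' of the climate variable are taken within each baseline year, then
#' averaged across the baseline years to give the lower (`n_min`) and upper
#' (`n_max`) niche limits. For the aridity index, extreme cell values are
#' first replaced by their Tukey-fence cutoffs ([clamp_to_fences()]) within
#' each species x month x year extraction, and the number of replacements is
#' reported.
#'
#' @param cube A `climate_cube` (`tmax` or `ai`).
#' @param range_masks Tibble of species range cells
#'   (`species_id`, `lat`, `lon`) on the cube's grid.
#' @param baseline_years Integer vector of years, default `1961:1975` — a
#'   baseline prior to the onset of rapid recent warming.
#' @param fence_ai Apply IQR fencing before taking extremes (default: only
#'   for the `ai` variable).
#' @param pooled Use the alternative order of operations — extremes of the
#'   values pooled across all baseline years — instead of the default mean
#'   of yearly extremes.
#' @return A tibble (`species_id`, `variable`, `month`, `n_min`, `n_max`,
#'   `n_adjusted_lower`, `n_adjusted_upper`, `n_cells`): 12 rows per
#'   species; months with no valid cells in any year have `NA` limits.
#' @export
derive_limits <- function(cube, range_masks, baseline_years = 1961:1975,
                          fence_ai = cube_variable(cube) == "ai",
                          pooled = FALSE) {
  stopifnot(inherits(cube, "climate_cube"))
  variable <- cube_variable(cube)
  cells <- tibble::as_tibble(cube) |>
    dplyr::filter(.data$year %in% baseline_years)
  species <- unique(range_masks$species_id)

  per_species <- function(sp) {
    mask <- range_masks[range_masks$species_id == sp, c("lat", "lon")]
    vals <- dplyr::inner_join(cells, mask, by = c("lat", "lon"))
    if (nrow(vals) == 0) {
      stop("derive_limits: range of '", sp, "' does not intersect the cube grid",
           call. = FALSE)
    }
    purrr::map_dfr(1:12, function(m) {
      vm <- vals[vals$month == m, ]
      limit_one_month(vm, sp, variable, m, fence_ai, pooled)
    })
  }
  purrr::map_dfr(species, per_species)
}

limit_one_month <- function(vm, sp, variable, m, fence_ai, pooled) {
  empty <- tibble::tibble(species_id = sp, variable = variable, month = m,
                          n_min = NA_real_, n_max = NA_real_,
                          n_adjusted_lower = 0L, n_adjusted_upper = 0L,
                          n_cells = 0L)
  vm <- vm[!is.na(vm$value), ]
  if (nrow(vm) == 0) return(empty)

  extract <- function(v) {
    adj_lo <- 0L; adj_hi <- 0L
    if (fence_ai && sum(is.finite(v)) >= 2) {
      cl <- clamp_to_fences(v, iqr_fences(v))
      v <- cl$values
      adj_lo <- cl$n_replaced_lower; adj_hi <- cl$n_replaced_upper
    }
    list(min = min(v), max = max(v), adj_lo = adj_lo, adj_hi = adj_hi)
  }

  if (pooled) {
    e <- extract(vm$value)
    lo <- e$min; hi <- e$max; adj_lo <- e$adj_lo; adj_hi <- e$adj_hi
  } else {
    per_year <- lapply(split(vm$value, vm$year), extract)
    lo <- mean(vapply(per_year, `[[`, 0, "min"))
    hi <- mean(vapply(per_year, `[[`, 0, "max"))
    adj_lo <- sum(vapply(per_year, `[[`, 0L, "adj_lo"))
    adj_hi <- sum(vapply(per_year, `[[`, 0L, "adj_hi"))
  }
  tibble::tibble(species_id = sp, variable = variable, month = m,
                 n_min = lo, n_max = hi,
                 n_adjusted_lower = as.integer(adj_lo),
                 n_adjusted_upper = as.integer(adj_hi),
                 n_cells = nrow(vm))
}

#' Fraction of species-month upper limits altered by AI fencing
#'
#' @param limits Output of [derive_limits()] for the `ai` variable.
#' @return Proportion of species x month rows with at least one upper
#'   replacement.
#' @export
fencing_adjustment_rate <- function(limits) {
  lim <- limits[limits$variable == "ai" & !is.na(limits$n_max), ]
  if (nrow(lim) == 0) return(NA_real_)
  mean(lim$n_adjusted_upper > 0)
}
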