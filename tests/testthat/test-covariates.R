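test_that("the position index maps limits to 0/1 and extrapolates linearly", {
  expect_equal(position_index(20, 5, 35), 0.5)
  expect_equal(position_index(5, 5, 35), 0)
  expect_equal(position_index(35, 5, 35), 1)
  expect_equal(position_index(40, 5, 35), 7 / 6)
  expect_error(position_index(10, 20, 20), "degenerate")
})

test_that("the position index is invariant to affine rescaling of the units", {
  set.seed(3)
  for (i in 1:25) {
    nm <- runif(1, -10, 50); lo <- runif(1, -20, 0); hi <- lo + runif(1, 1, 40)
    a <- runif(1, 0.1, 9); b <- runif(1, -30, 30)
    expect_equal(position_index(a * nm + b, a * lo + b, a * hi + b),
                 position_index(nm, lo, hi), tolerance = 1e-12)
  }
})

test_that("the mean position index averages unit-wise indices", {
  expect_equal(position_index_mean(10, 0, 40), position_index(10, 0, 40))
  expect_equal(position_index_mean(c(10, 20), c(0, 0), c(40, 40)), 0.375)
  expect_error(position_index_mean(c(10, 20), c(0, 5), c(40, 5)), "degenerate")
})

covariate_fixture <- function() {
  grid <- tidyr::expand_grid(lat = c(0, 2), lon = c(0, 2),
                             year = 1961:1970, month = 1:12)
  grid$value <- 10 + 10 * (grid$month %in% 4:9) + (grid$year - 1961) * 0.5 + grid$lat
  tmax <- climate_cube(grid, "tmax", 2)
  mask <- tibble::tibble(species_id = "A", lat = c(0, 2), lon = c(0, 2))
  limits <- derive_limits(tmax, mask, baseline_years = 1961:1965)
  list(tmax = tmax, mask = mask, limits = limits)
}

test_that("climate indices look up cell, year, month and the species limits", {
  fx <- covariate_fixture()
  obs <- tibble::tibble(species_id = "A", year = c(1961L, 1961L, 1965L),
                        month = 1L, lat = 0.4, lon = 0.4)
  out <- attach_climate_indices(obs, tmax_cube = fx$tmax, limits = fx$limits)
  lim1 <- fx$limits[fx$limits$month == 1, ]
  expect_equal(out$tpi_nmin, rep(lim1$n_min, 3))
  expect_equal(out$tpi,
               (out$tpi_nm - out$tpi_nmin) / (out$tpi_nmax - out$tpi_nmin))
  expect_false(out$tpi[1] == out$tpi[3])   # different years, different tmax

  # an observation in the coolest cell of a mid-baseline year sits exactly
  # at the species-month lower limit and scores 0
  cool <- tibble::tibble(species_id = "A", year = 1963L, month = 1L,
                         lat = 0.4, lon = 0.4)
  cool_out <- attach_climate_indices(cool, tmax_cube = fx$tmax, limits = fx$limits)
  expect_equal(cool_out$tpi_nm, 10 + (1963 - 1961) * 0.5)
  expect_equal(cool_out$tpi, position_index(cool_out$tpi_nm, cool_out$tpi_nmin,
                                            cool_out$tpi_nmax))
})

test_that("missing cell-month climate yields a missing index, counted not dropped", {
  fx <- covariate_fixture()
  grid <- tibble::as_tibble(fx$tmax)
  grid$value[grid$year == 1966 & grid$month == 1] <- NA
  cube <- climate_cube(grid, "tmax", 2)
  obs <- tibble::tibble(species_id = "A", year = c(1966L, 1967L), month = 1L,
                        lat = 0.4, lon = 0.4)
  out <- attach_climate_indices(obs, tmax_cube = cube, limits = fx$limits)
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$tpi[1]) && !is.na(out$tpi[2]))
  expect_equal(attr(out, "n_missing_index"), 1L)
})

test_that("an observation month without a limit row is an error", {
  fx <- covariate_fixture()
  lim_partial <- fx$limits[fx$limits$month != 3, ]
  obs <- tibble::tibble(species_id = "A", year = 1961L, month = 3L,
                        lat = 0.4, lon = 0.4)
  expect_error(attach_climate_indices(obs, tmax_cube = fx$tmax,
                                      limits = lim_partial), "no tmax limits")
})

landuse_fixture <- function(crop, past, urb) {
  grid <- tidyr::expand_grid(lat = c(0, 2), lon = c(0, 2), year = 2000:2001)
  mk <- function(v, var) climate_cube(dplyr::mutate(grid, value = v), var, 2)
  list(crop = mk(crop, "cropland"), past = mk(past, "pasture"),
       urb = mk(urb, "urban"))
}

test_that("ALU sums cropland and pasture; ULU is the urban fraction", {
  lu <- landuse_fixture(0.2, 0.3, 0.05)
  obs <- tibble::tibble(species_id = "A", year = 2000L, month = 1L,
                        lat = 0.1, lon = 0.1)
  out <- attach_landuse(obs, lu$crop, lu$past, lu$urb)
  expect_equal(out$alu, 0.5)
  expect_equal(out$ulu, 0.05)

  natural <- landuse_fixture(0, 0, 0)
  out0 <- attach_landuse(obs, natural$crop, natural$past, natural$urb)
  expect_equal(out0$alu, 0)
  expect_equal(out0$ulu, 0)
})

test_that("ALU sums above 1 clamp with a warning; years snap to nearest coverage", {
  lu <- landuse_fixture(0.7, 0.5, 0.1)
  obs <- tibble::tibble(species_id = "A", year = 2000L, month = 1L,
                        lat = 0.1, lon = 0.1)
  expect_warning(out <- attach_landuse(obs, lu$crop, lu$past, lu$urb), "clamped")
  expect_equal(out$alu, 1)

  late <- dplyr::mutate(obs, year = 2010L)
  warns <- testthat::capture_warnings(
    out2 <- attach_landuse(late, lu$crop, lu$past, lu$urb))
  expect_true(any(grepl("nearest covered year", warns)))
  expect_true(any(grepl("clamped", warns)))
  expect_equal(out2$alu, 1)
})

test_that("realm labels come from cell containment; missing cells are flagged", {
  grid <- tidyr::expand_grid(lat = c(0, 2), lon = c(0, 2))
  realm <- climate_cube(dplyr::mutate(grid, value = c("A", "A", "B", "B")),
                        "realm", 2)
  obs <- tibble::tibble(species_id = "x", year = 2000L, month = 1L,
                        lat = c(0.2, 1.0, 30), lon = c(0.2, 2.3, 0))
  out <- attach_realm(obs, realm)
  expect_equal(out$realm[1], "A")
  expect_equal(out$realm[2], "B")   # lat 1.0 rounds up into the lat-2 row
  expect_true(is.na(out$realm[3]))
  expect_equal(attr(out, "n_missing_realm"), 1L)
})

test_that("attach operations preserve row order and count", {
  set.seed(99)
  fx <- covariate_fixture()
  obs <- tibble::tibble(species_id = "A",
                        year = sample(1961:1970, 20, TRUE),
                        month = sample(1:12, 20, TRUE),
                        lat = runif(20, -0.9, 2.9), lon = runif(20, -0.9, 2.9),
                        tag = seq_len(20))
  out <- attach_climate_indices(obs, tmax_cube = fx$tmax, limits = fx$limits)
  expect_equal(out$tag, obs$tag)
  expect_equal(nrow(out), 20)
})

test_that("z-scoring standardizes, returns parameters, and rejects constants", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_columns(tab, "a")
  expect_equal(mean(z$table$a), 0)
  expect_equal(stats::sd(z$table$a), 1)
  expect_equal(z$table$a[2], 0)              # the mean maps to zero
  expect_equal(unname(z$means[["a"]]), 2)
  expect_error(zscore_columns(tab, c("a", "b")), "b")
})
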