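#' Configuration for the synthetic world
#'
#' Bundles every knob of the seeded synthetic dataset: the grid, the year
#' span, the species pool, the true fixed effects and variance components
#' of the generative mixed model (all on the z-scale of the response), the
#' contamination rates, and the climate structure. The defaults define the
#' package's reference study conditions; see the methods vignette for the
#' reasoning behind each value.
#'
#' @param seed Integer seed; every generator derives its own stream from it.
#' @param n_lat,n_lon,res Grid dimensions (cells) and resolution (degrees).
#' @param years Inclusive year range covered by the climate and the records.
#' @param baseline_years Years used for niche-limit derivation.
#' @param n_species Number of species.
#' @param obs_per_species Clean observation records per species.
#' @param beta Named true fixed effects on the z-scale:
#'   `tpi`, `api`, `alu`, `ulu`, `year_z`, `tpi:api`, `tpi:alu`, `tpi:ulu`.
#' @param sigma2 Named true variance components (z-scale):
#'   `realm`, `site`, `species_iid`, `species_phylo`, `slope_tpi_iid`,
#'   `slope_tpi_phylo`, `resid`.
#' @param juvenile_frac,outlier_frac Contamination fractions; contaminants
#'   are planted 6-10 adult MADs outside the retention band with life stage
#'   `"unknown"` so the ideal filter behaviour is knowable.
#' @param response_scale Standard-deviation of the latent z-response in
#'   log10 units (`log10_mass = mu0 + response_scale * z`).
#' @param mu0 Baseline log10 body mass (grams).
#' @param seasonal_amplitude Seasonal tmax half-range (deg C).
#' @param meridional_gradient Tmax drop per degree of absolute latitude.
#' @param warming_trend Warming trend in deg C per decade.
#' @param climate_noise_sd Cell-month tmax noise sd (deg C).
#' @param snow_tmax Monthly tmax (deg C) below which PET is missing
#'   ("snow" cells).
#' @param n_realms Number of longitudinal realm blocks (2-4).
#' @param sites_range Min/max count of reused sampling points per species.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_lat = 10L, n_lon = 16L, res = 2,
                         years = c(1961L, 2010L),
                         baseline_years = 1961:1975,
                         n_species = 30L,
                         obs_per_species = 200L,
                         beta = c(tpi = -0.3, api = 0.3, alu = 0.1, ulu = 0,
                                  year_z = 0.05, `tpi:api` = 0.15,
                                  `tpi:alu` = 0, `tpi:ulu` = 0),
                         sigma2 = c(realm = 0.02, site = 0.05,
                                    species_iid = 0.08, species_phylo = 0.08,
                                    slope_tpi_iid = 0.01, slope_tpi_phylo = 0.01,
                                    resid = 0.55),
                         juvenile_frac = 0.025, outlier_frac = 0.025,
                         response_scale = 0.1, mu0 = 1.5,
                         seasonal_amplitude = 8,
                         meridional_gradient = 0.6,
                         warming_trend = 0.3,
                         climate_noise_sd = 1,
                         snow_tmax = -2,
                         n_realms = 3L,
                         sites_range = c(5L, 50L)) {
  stopifnot(all(sigma2 >= 0), juvenile_frac >= 0, juvenile_frac <= 1,
            outlier_frac >= 0, outlier_frac <= 1,
            years[2] >= years[1], n_species >= 2, res > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "world_config")
}

# independent, reproducible sub-streams per generator stage
with_world_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(config$seed) + offset) %% .Machine$integer.max)
  force(code)
}

world_grid <- function(config) {
  lat0 <- -(config$n_lat - 1) / 2 * config$res
  lon0 <- -(config$n_lon - 1) / 2 * config$res
  tidyr::expand_grid(lat = lat0 + (seq_len(config$n_lat) - 1) * config$res,
                     lon = lon0 + (seq_len(config$n_lon) - 1) * config$res)
}

#' Generate synthetic monthly climate cubes
#'
#' Monthly maximum temperature is a meridional gradient plus a sinusoidal
#' season (peaking in July north of the equator, January south), a linear
#' warming trend and Gaussian cell-month noise. Precipitation and potential
#' evapotranspiration are positive seasonal fields; PET is missing where
#' the cell-month is below the snow threshold, mimicking missing PET over
#' snow.
#'
#' @param config A [world_config()].
#' @return A list of `climate_cube`s: `tmax`, `ppt`, `pet`.
#' @export
gen_climate <- function(config) {
  grid <- world_grid(config)
  years <- config$years[1]:config$years[2]
  full <- tidyr::expand_grid(grid, year = years, month = 1:12)
  with_world_seed(config, 1L, {
    phase <- ifelse(full$lat >= 0, 7, 1)
    season <- cos(2 * pi * (full$month - phase) / 12)
    base <- 30 - config$meridional_gradient * abs(full$lat)
    trend <- config$warming_trend * (full$year - years[1]) / 10
    noise <- if (config$climate_noise_sd > 0)
      stats::rnorm(nrow(full), 0, config$climate_noise_sd) else 0
    tmax_v <- base + config$seasonal_amplitude * season + trend + noise

    ppt_v <- pmax(2, 70 + 0.8 * full$lat + 30 * cos(2 * pi * (full$month - phase + 3) / 12) +
                    stats::rnorm(nrow(full), 0, 10))
    pet_v <- pmax(5, 60 + 0.9 * (tmax_v - 10) + stats::rnorm(nrow(full), 0, 5))
    pet_v[tmax_v < config$snow_tmax] <- NA_real_

    list(
      tmax = climate_cube(dplyr::mutate(full, value = tmax_v), "tmax", config$res, "degC"),
      ppt = climate_cube(dplyr::mutate(full, value = ppt_v), "ppt", config$res, "mm/month"),
      pet = climate_cube(dplyr::mutate(full, value = pet_v), "pet", config$res, "mm/month")
    )
  })
}

#' Generate yearly land-use fraction cubes
#'
#' Per-cell base fractions with a slow linear intensification over years,
#' clamped to `[0, 1]`.
#'
#' @param config A [world_config()].
#' @return A list of `climate_cube`s: `cropland`, `pasture`, `urban`.
#' @export
gen_landuse <- function(config) {
  grid <- world_grid(config)
  years <- config$years[1]:config$years[2]
  with_world_seed(config, 2L, {
    base <- dplyr::mutate(grid,
                          crop0 = stats::runif(dplyr::n(), 0, 0.35),
                          past0 = stats::runif(dplyr::n(), 0, 0.3),
                          urb0 = stats::runif(dplyr::n(), 0, 0.08))
    full <- tidyr::expand_grid(base, year = years)
    tr <- (full$year - years[1]) / (max(1L, years[length(years)] - years[1]))
    mk <- function(v0, slope, variable) {
      climate_cube(tibble::tibble(lat = full$lat, lon = full$lon, year = full$year,
                                  value = pmin(1, pmax(0, v0 + slope * tr))),
                   variable, config$res, "fraction")
    }
    list(cropland = mk(full$crop0, 0.1, "cropland"),
         pasture = mk(full$past0, 0.05, "pasture"),
         urban = mk(full$urb0, 0.06, "urban"))
  })
}

#' Generate the static biogeographic-realm layer
#'
#' A fixed partition of the grid into `n_realms` longitudinal blocks,
#' giving the realm random intercept something to estimate.
#'
#' @param config A [world_config()].
#' @return A categorical `climate_cube` of variable `"realm"`.
#' @export
gen_realm <- function(config) {
  grid <- world_grid(config)
  lons <- sort(unique(grid$lon))
  block <- ceiling(match(grid$lon, lons) / (length(lons) / config$n_realms))
  climate_cube(dplyr::mutate(grid, value = LETTERS[block]), "realm", config$res)
}

#' Generate species ranges and an ultrametric tree
#'
#' Ranges are contiguous rectangular blocks of grid cells with randomized
#' centers and extents; the tree is a pure-birth (Yule) simulation over the
#' same species ids, hence ultrametric.
#'
#' @param config A [world_config()].
#' @return A list with `ranges` (tibble `species_id`, `lat`, `lon`) and
#'   `tree` (a `phylo`).
#' @export
gen_ranges_and_tree <- function(config) {
  grid <- world_grid(config)
  lats <- sort(unique(grid$lat))
  lons <- sort(unique(grid$lon))
  sp_ids <- sprintf("Synthus_sp%03d", seq_len(config$n_species))
  with_world_seed(config, 3L, {
    ranges <- purrr::map_dfr(sp_ids, function(sp) {
      ci <- sample.int(length(lats), 1)
      cj <- sample.int(length(lons), 1)
      hi <- sample(1:max(2L, config$n_lat %/% 2), 1)
      hj <- sample(1:max(2L, config$n_lon %/% 2), 1)
      sel_lat <- lats[abs(seq_along(lats) - ci) <= hi]
      sel_lon <- lons[abs(seq_along(lons) - cj) <= hj]
      tidyr::expand_grid(species_id = sp, lat = sel_lat, lon = sel_lon)
    })
    tree <- ape::rphylo(config$n_species, birth = 1, death = 0)
    tree$tip.label <- sp_ids
    list(ranges = ranges, tree = tree)
  })
}

#' Generate observation records from the model's own generative structure
#'
#' Places records at reused sampling sites within each species range,
#' uniformly over years and months; computes TPI/API/ALU/ULU/realm through
#' the package's own covariate machinery; draws the z-scale response from
#' the exact mixed-model structure (true fixed effects, random intercepts
#' for realm/site/species, a phylogenetically correlated species intercept,
#' dual TPI random slopes, Gaussian residual); converts it to raw body mass
#' and an allometrically linked body length; and finally appends planted
#' contamination with ground-truth flags.
#'
#' @param config A [world_config()].
#' @param climate Output of [gen_climate()].
#' @param landuse Output of [gen_landuse()].
#' @param realm_cube Output of [gen_realm()].
#' @param ranges,tree Output of [gen_ranges_and_tree()].
#' @param limits Optional precomputed niche-limit table (else derived here).
#' @return An observation tibble with ground-truth columns
#'   `true_log10_mass`, `contaminant` (`"none"`, `"juvenile"`,
#'   `"outlier"`), plus the generating covariates; attribute `truth` holds
#'   the true parameters.
#' @export
gen_observations <- function(config, climate, landuse, realm_cube, ranges, tree,
                             limits = NULL) {
  sp_ids <- unique(ranges$species_id)
  missing_tips <- setdiff(sp_ids, tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("gen_observations: species absent from tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  ai_cube <- compute_ai(climate$ppt, climate$pet)
  if (is.null(limits)) {
    limits <- dplyr::bind_rows(
      derive_limits(climate$tmax, ranges, config$baseline_years),
      derive_limits(ai_cube, ranges, config$baseline_years))
  }
  years <- config$years[1]:config$years[2]

  with_world_seed(config, 4L, {
    # reused sampling sites inside each range, jittered within the cell
    obs <- purrr::map_dfr(sp_ids, function(sp) {
      cells <- ranges[ranges$species_id == sp, ]
      n_sites <- sample(config$sites_range[1]:config$sites_range[2], 1)
      pick <- cells[sample.int(nrow(cells), n_sites, replace = TRUE), ]
      pts <- dplyr::mutate(pick,
                           lat = .data$lat + stats::runif(n_sites, -0.49, 0.49) * config$res,
                           lon = .data$lon + stats::runif(n_sites, -0.49, 0.49) * config$res)
      idx <- sample.int(n_sites, config$obs_per_species, replace = TRUE)
      tibble::tibble(species_id = sp,
                     lat = round(pts$lat[idx], 6), lon = round(pts$lon[idx], 6),
                     year = sample(years, config$obs_per_species, replace = TRUE),
                     month = sample(1:12, config$obs_per_species, replace = TRUE),
                     day = sample(1:28, config$obs_per_species, replace = TRUE))
    })

    obs <- attach_climate_indices(obs, tmax_cube = climate$tmax, ai_cube = ai_cube,
                                  limits = limits)
    obs <- attach_landuse(obs, landuse$cropland, landuse$pasture, landuse$urban)
    obs <- attach_realm(obs, realm_cube)
    obs <- assign_sites(obs)

    # z-scale covariates over the clean sample, as the analysis will
    usable <- stats::complete.cases(obs[c("tpi", "api", "alu", "ulu", "realm")])
    obs <- obs[usable, , drop = FALSE]
    obs$year_z <- as.numeric(obs$year)
    z <- zscore_columns(obs, c("tpi", "api", "alu", "ulu", "year_z"))$table

    beta <- config$beta
    eta <- beta[["tpi"]] * z$tpi + beta[["api"]] * z$api +
      beta[["alu"]] * z$alu + beta[["ulu"]] * z$ulu +
      beta[["year_z"]] * z$year_z +
      beta[["tpi:api"]] * z$tpi * z$api +
      beta[["tpi:alu"]] * z$tpi * z$alu +
      beta[["tpi:ulu"]] * z$tpi * z$ulu

    s2 <- config$sigma2
    C <- phylo_correlation(tree, sp_ids)
    Lc <- t(chol(C))
    realms <- sort(unique(obs$realm))
    sites <- sort(unique(obs$site))
    u_realm <- stats::rnorm(length(realms), 0, sqrt(s2[["realm"]]))
    u_site <- stats::rnorm(length(sites), 0, sqrt(s2[["site"]]))
    u_sp <- stats::rnorm(length(sp_ids), 0, sqrt(s2[["species_iid"]]))
    u_phy <- drop(Lc %*% stats::rnorm(length(sp_ids), 0, sqrt(s2[["species_phylo"]])))
    b_sp <- stats::rnorm(length(sp_ids), 0, sqrt(s2[["slope_tpi_iid"]]))
    b_phy <- drop(Lc %*% stats::rnorm(length(sp_ids), 0, sqrt(s2[["slope_tpi_phylo"]])))
    names(u_sp) <- names(u_phy) <- names(b_sp) <- names(b_phy) <- sp_ids
    names(u_realm) <- realms

    i_sp <- match(obs$species_id, sp_ids)
    y_z <- eta + u_realm[obs$realm] + u_site[match(obs$site, sites)] +
      u_sp[i_sp] + u_phy[i_sp] + (b_sp[i_sp] + b_phy[i_sp]) * z$tpi +
      stats::rnorm(nrow(obs), 0, sqrt(s2[["resid"]]))

    obs$true_log10_mass <- config$mu0 + config$response_scale * unname(y_z)
    obs$mass <- round(10^obs$true_log10_mass, 4)
    # allometric length with a little independent noise, in mm
    obs$length <- round(obs$mass^(1 / 3) / 0.1 *
                          10^stats::rnorm(nrow(obs), 0, 0.01), 4)
    obs$life_stage <- sample(c("adult", "Ad", "unknown"), nrow(obs),
                             replace = TRUE, prob = c(0.6, 0.15, 0.25))
    obs$sex <- sample(c("male", "female", "M", "F", "U"), nrow(obs), replace = TRUE)
    obs$source <- "synthetic-world"
    obs$exclude <- FALSE
    obs$contaminant <- "none"

    derive_size_metrics(contaminate(obs, config))
  })
}

# plant likely-juvenile and outlier records strictly outside the 5-MAD
# retention band (6-10 adult MADs from the species median, life stage
# unknown so the adult reference statistics stay clean)
contaminate <- function(obs, config) {
  if (config$juvenile_frac == 0 && config$outlier_frac == 0) return(obs)
  out <- list(obs)
  for (sp in unique(obs$species_id)) {
    rows <- obs[obs$species_id == sp, ]
    m <- stats::median(rows$mass)
    mad <- stats::median(abs(rows$mass - m))
    n_juv <- round(config$juvenile_frac * nrow(rows))
    n_out <- round(config$outlier_frac * nrow(rows))
    # a low-side contaminant must sit >= 6 MADs below the median AND stay
    # positive; when the species' dispersion makes that impossible
    # (0.99 m / MAD < 6) it is planted on the high side as an outlier instead
    d_low_max <- 0.99 * m / mad
    mk <- function(n, type) {
      if (n == 0 || mad == 0) return(NULL)
      src <- rows[sample.int(nrow(rows), n, replace = TRUE), ]
      sign <- if (type == "juvenile") rep(-1, n) else sample(c(-1, 1), n, replace = TRUE)
      if (d_low_max < 6) sign[] <- 1
      d <- ifelse(sign < 0,
                  stats::runif(n, 6, min(8, d_low_max)),
                  stats::runif(n, 6, 10))
      src$mass <- round(m + sign * d * mad, 4)
      src$life_stage <- "unknown"
      src$true_log10_mass <- NA_real_
      src$contaminant <- ifelse(sign < 0 | type == "outlier", type, "outlier")
      src
    }
    out <- c(out, list(mk(n_juv, "juvenile"), mk(n_out, "outlier")))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$species_id, res$site, res$year, res$month), ]
}

#' Generate the complete synthetic world
#'
#' Convenience wrapper running every generator off one config, returning
#' all artifacts plus the niche-limit table used for the ground truth.
#'
#' @param config A [world_config()].
#' @return A list: `climate`, `ai`, `landuse`, `realm`, `ranges`, `tree`,
#'   `limits`, `observations`, `config`.
#' @export
gen_world <- function(config = world_config()) {
  climate <- gen_climate(config)
  landuse <- gen_landuse(config)
  realm_cube <- gen_realm(config)
  rt <- gen_ranges_and_tree(config)
  ai_cube <- compute_ai(climate$ppt, climate$pet)
  limits <- dplyr::bind_rows(
    derive_limits(climate$tmax, rt$ranges, config$baseline_years),
    derive_limits(ai_cube, rt$ranges, config$baseline_years))
  obs <- gen_observations(config, climate, landuse, realm_cube,
                          rt$ranges, rt$tree, limits = limits)
  list(climate = climate, ai = ai_cube, landuse = landuse, realm = realm_cube,
       ranges = rt$ranges, tree = rt$tree, limits = limits,
       observations = obs, config = config)
}
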