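# Small, fast synthetic-world configurations used across test files.

tiny_world <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_lat = 6L, n_lon = 8L, res = 2,
               years = c(1961L, 1990L), baseline_years = 1961:1970,
               n_species = 8L, obs_per_species = 60L,
               sites_range = c(4L, 12L))
  args[names(list(...))] <- list(...)
  do.call(world_config, args)
}

# a minimal observation tibble for cleaning/covariate unit tests
toy_obs <- function(n = 5) {
  tibble::tibble(
    species_id = rep("Aus bus", n),
    year = 1980L, month = 6L, day = 15L,
    lat = seq(10, 10 + (n - 1) * 0.1, by = 0.1),
    lon = seq(20, 20 + (n - 1) * 0.1, by = 0.1),
    mass = rep(10, n), length = rep(50, n),
    life_stage = "adult", sex = "unknown", source = "test",
    exclude = FALSE
  )
}

# small constant-valued monthly cube over a given grid
const_cube <- function(value = 20, variable = "tmax", years = 1961:1962,
                       lats = c(0, 2), lons = c(0, 2), res = 2) {
  grid <- tidyr::expand_grid(lat = lats, lon = lons, year = years, month = 1:12)
  climate_cube(dplyr::mutate(grid, value = value), variable, res)
}

# dense brute-force marginal Gaussian log-likelihood: builds the full n x n
# covariance from the UNfolded incidence structures and the phylogenetic
# correlation, independent of the fitter's sparse Woodbury path
dense_mixed_loglik <- function(design, beta, sigma2, varcomp) {
  dat <- design$data
  n <- nrow(dat)
  mk_Z <- function(f) {
    f <- factor(f)
    Z <- matrix(0, n, nlevels(f))
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Z
  }
  sp_f <- factor(dat$species_id, levels = design$species)
  Z_sp <- mk_Z(sp_f)
  C <- design$C
  Sigma <- diag(sigma2, n)
  add <- function(Sigma, Z, G, s2) Sigma + s2 * Z %*% G %*% t(Z)
  for (k in names(design$blocks)) {
    s2 <- varcomp[[k]]
    if (k == "realm") Sigma <- add(Sigma, mk_Z(dat$realm), diag(nlevels(factor(dat$realm))), s2)
    else if (k == "site") Sigma <- add(Sigma, mk_Z(dat$site), diag(nlevels(factor(dat$site))), s2)
    else if (k == "species_iid") Sigma <- add(Sigma, Z_sp, diag(ncol(Z_sp)), s2)
    else if (k == "species_phylo") Sigma <- add(Sigma, Z_sp, C, s2)
    else {
      xs <- dat[[sub("^slope_(.*)_(iid|phylo)$", "\\1", k)]]
      Zs <- Z_sp * xs
      G <- if (grepl("_phylo$", k)) C else diag(ncol(Z_sp))
      Sigma <- add(Sigma, Zs, G, s2)
    }
  }
  r <- design$y - drop(design$X %*% beta)
  ch <- chol(Sigma)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# independent type-7 quantile by explicit order-statistic interpolation
interp_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# shared fixture: a plain mixed-model dataset with iid structure
sim_model_data <- function(n = 400, n_sp = 6, n_site = 25, seed = 1,
                           beta = c(tpi = 0.5, api = -0.3),
                           sd_sp = 0.4, sd_site = 0.3, sd_e = 1) {
  set.seed(seed)
  sp <- sample(n_sp, n, TRUE); site <- sample(n_site, n, TRUE)
  u_sp <- rnorm(n_sp, 0, sd_sp); u_site <- rnorm(n_site, 0, sd_site)
  tpi <- rnorm(n); api <- rnorm(n)
  y <- beta[["tpi"]] * tpi + beta[["api"]] * api +
    u_sp[sp] + u_site[site] + rnorm(n, 0, sd_e)
  tibble::tibble(log10_mass = y, tpi = tpi, api = api, alu = rnorm(n),
                 ulu = rnorm(n), year = rnorm(n), realm = rep(c("R1", "R2"),
                 length.out = n), site = site,
                 species_id = sprintf("sp%02d", sp))
}

ident_C <- function(dat) {
  sp <- sort(unique(dat$species_id))
  C <- diag(length(sp)); dimnames(C) <- list(sp, sp)
  C
}

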