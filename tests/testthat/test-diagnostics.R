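test_that("VIF is 1 for orthogonal designs and infinite under duplication", {
  # orthogonal columns that are also orthogonal to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)

  Xd <- cbind(X, d = X[, 1])
  expect_true(is.infinite(vif(Xd)[["d"]]))
})

test_that("VIF matches the 1/(1 - R2) regression oracle", {
  set.seed(12)
  for (i in 1:5) {
    x1 <- rnorm(200); x2 <- rnorm(200)
    x3 <- x1 + x2 + rnorm(200, 0, 0.5)
    X <- cbind(x1 = x1, x2 = x2, x3 = x3)
    v <- vif(X)
    for (j in 1:3) {
      r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
      expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
    }
  }
})

test_that("the Durbin-Watson statistic follows its closed form", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)       # 12 / 4
  expect_equal(durbin_watson(c(1, 2, 3, 4)), 0.1)       # 3 / 30
  set.seed(2)
  expect_lt(abs(durbin_watson(rnorm(5000)) - 2), 0.1)   # iid concentrates at 2
  expect_error(durbin_watson(c(0, 0, 0)), "all-zero")
})

test_that("the DW permutation p-value is uniform under exchangeability", {
  set.seed(31)
  p <- replicate(500, dw_test(rnorm(25), n_perm = 99)$p_value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DW resampling is seeded, calibrated on iid noise, and detects AR(1)", {
  set.seed(41)
  n <- 3000
  years <- sample(1961:2010, n, TRUE)
  resid_iid <- rnorm(n)
  r1 <- dw_resample(resid_iid, years, n_iter = 400, seed = 9)
  r2 <- dw_resample(resid_iid, years, n_iter = 400, seed = 9)
  expect_identical(r1, r2)
  se <- sqrt(0.95 * 0.05 / 400)
  expect_lt(abs(r1$fraction_nonsignificant - 0.95), 3 * se + 1e-9)

  # strongly autocorrelated year means should be flagged far more often
  yr_effect <- as.numeric(stats::arima.sim(list(ar = 0.9), 50))
  resid_ar <- yr_effect[years - 1960] + rnorm(n, 0, 0.1)
  r3 <- dw_resample(resid_ar, years, n_iter = 200, seed = 9)
  expect_lt(r3$fraction_nonsignificant, 0.7)
})

test_that("years without residuals are skipped with a warning", {
  expect_warning(
    r <- dw_resample(rnorm(50), factor(rep(2000:2004, 10), levels = 2000:2005),
                     n_iter = 20, seed = 1),
    "skipped")
  expect_equal(r$n_iter, 20)
})

test_that("per-species DW averages flag autocorrelated species only", {
  set.seed(53)
  n <- 600
  years <- sample(1981:2010, n, TRUE)
  species <- rep(c("clean", "trendy"), each = n / 2)
  resid <- rnorm(n, 0, 0.2)
  trend <- (years - 1995) / 10
  resid[species == "trendy"] <- resid[species == "trendy"] + trend[species == "trendy"]
  out <- dw_by_species(resid, years, species, n_iter = 60, seed = 3)
  expect_false(out$flagged[out$species_id == "clean"])
  expect_true(out$flagged[out$species_id == "trendy"])
  expect_lt(out$mean_dw[out$species_id == "trendy"],
            out$mean_dw[out$species_id == "clean"])
})

test_that("the spline correlogram covers zero for iid residuals", {
  set.seed(61)
  n <- 150
  lat <- runif(n, -10, 10); lon <- runif(n, -10, 10)
  covers <- vapply(1:5, function(s) {
    cg <- spline_correlogram(rnorm(n), lat, lon, n_boot = 60, seed = s)
    mean(cg$lower <= 0 & cg$upper >= 0)
  }, 0)
  expect_gte(mean(covers >= 0.9), 0.8)   # most seeded runs cover 0 throughout
})

test_that("a distance-decaying field shows up at the shortest distances", {
  set.seed(62)
  n <- 160
  lat <- runif(n, -2, 2); lon <- runif(n, -2, 2)
  D <- geosphere::distm(cbind(lon, lat)) / 1000
  Sigma <- exp(-D / 100) + diag(1e-8, n)
  field <- drop(t(chol(Sigma)) %*% rnorm(n))
  cg <- spline_correlogram(field, lat, lon, n_boot = 40, seed = 1)
  expect_gt(cg$correlation[1], 0)
  expect_gt(cg$correlation[1], cg$correlation[nrow(cg)])
})

test_that("degenerate correlogram inputs are rejected", {
  expect_error(spline_correlogram(rnorm(10), rep(0, 10), rep(0, 10)), ">= 20")
  expect_error(spline_correlogram(rnorm(25), rep(0, 25), rep(0, 25)),
               "single location")
})

test_that("influence screening flags gross outliers and respects the threshold", {
  dat <- sim_model_data(n = 500, seed = 8)
  idx <- 17
  dat$log10_mass[idx] <- dat$log10_mass[idx] + 10 * sd(dat$log10_mass)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  scr <- influence_screen(fit, threshold = 4)
  flagged_rows <- fit$design$data$site[scr$flagged]
  expect_true(length(scr$flagged) >= 1)
  expect_true(any(abs(fit$residuals[scr$flagged]) ==
                    max(abs(fit$residuals))))
  expect_equal(influence_screen(fit, threshold = Inf)$flagged, integer(0))

  clean_fit <- fit_pglmm(assemble(sim_model_data(n = 2000, seed = 9),
                                  pglmm_spec("log10_mass"),
                                  ident_C(sim_model_data(n = 2000, seed = 9))),
                         vc_intervals = FALSE)
  expect_lt(influence_screen(clean_fit)$fraction, 0.01)
})

test_that("refitting without flagged rows reports coefficient shifts", {
  dat <- sim_model_data(n = 400, seed = 14)
  dat$log10_mass[3] <- dat$log10_mass[3] + 8 * sd(dat$log10_mass)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  scr <- influence_screen(fit, threshold = 4, refit = TRUE)
  expect_true(is.data.frame(scr$beta_shift))
  expect_true(all(c("estimate", "estimate_refit") %in% names(scr$beta_shift)))
})

test_that("posterior predictive checks are seeded and self-consistent", {
  dat <- sim_model_data(n = 600, seed = 21)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  a <- posterior_predictive_check(fit, n_sim = 200, seed = 5)
  b <- posterior_predictive_check(fit, n_sim = 200, seed = 5)
  expect_identical(a$observed, b$observed)
  expect_identical(a$lower, b$lower)
  # data generated from (close to) the fitted model: mean and sd inside
  expect_true(a$coverage[["mean"]])
  expect_true(a$coverage[["sd"]])
  expect_warning(posterior_predictive_check(fit, n_sim = 1, seed = 1),
                 "degenerate")
})

test_that("the assembled diagnostics report is reproducible under its seed", {
  dat <- sim_model_data(n = 400, seed = 33)
  dat$year <- sample(1990:2005, 400, TRUE)
  dat$lat <- runif(400, -5, 5); dat$lon <- runif(400, -5, 5)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  r1 <- diagnose(fit, seed = 2, dw_iter = 50, ppc_sim = 50, boot = 20)
  r2 <- diagnose(fit, seed = 2, dw_iter = 50, ppc_sim = 50, boot = 20)
  expect_identical(r1$dw_global, r2$dw_global)
  expect_identical(r1$correlogram$correlation, r2$correlogram$correlation)
  expect_true(all(r1$vif >= 1))
})
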