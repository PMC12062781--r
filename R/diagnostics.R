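#' Variance inflation factors of a fixed-effects design
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing column `j` on
#' the remaining columns (plus an intercept if absent). Exact collinearity
#' yields `Inf`.
#'
#' @param X Numeric design matrix (an intercept column is ignored).
#' @return Named numeric vector of VIFs (>= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(cl) stats::sd(cl) > 0)
  X <- X[, keep, drop = FALSE]
  terms <- colnames(X)
  out <- vapply(seq_along(terms), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(r^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(pmax(out, 1), terms)
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)`; about 2 under independence,
#' below 2 under positive first-order autocorrelation.
#'
#' @param series Numeric residual series ordered in time, length >= 2.
#' @return The statistic (scalar).
#' @export
durbin_watson <- function(series) {
  stopifnot(length(series) >= 2)
  if (all(series == 0)) stop("durbin_watson: all-zero series", call. = FALSE)
  sum(diff(series)^2) / sum(series^2)
}

#' Permutation p-value for the Durbin-Watson statistic
#'
#' The sampled one-per-year series are short and irregular, so tabulated
#' bounds do not apply; significance is assessed by shuffling the series.
#' One-sided for positive autocorrelation (small DW) by default.
#'
#' @param series Ordered residual series.
#' @param n_perm Number of shuffles (default 199).
#' @param alternative `"positive"` (default), `"negative"`, `"two.sided"`.
#' @return List with `statistic` and `p_value`.
#' @export
dw_test <- function(series, n_perm = 199, alternative = c("positive", "negative", "two.sided")) {
  alternative <- match.arg(alternative)
  dw <- durbin_watson(series)
  perm <- vapply(seq_len(n_perm), function(i) durbin_watson(sample(series)), 0)
  p <- switch(alternative,
    positive = (1 + sum(perm <= dw)) / (n_perm + 1),
    negative = (1 + sum(perm >= dw)) / (n_perm + 1),
    two.sided = min(1, 2 * min((1 + sum(perm <= dw)) / (n_perm + 1),
                               (1 + sum(perm >= dw)) / (n_perm + 1)))
  )
  list(statistic = dw, p_value = p)
}

#' Durbin-Watson resampling over years
#'
#' Per iteration, one residual is drawn uniformly from each year, the
#' series is ordered by year, and the Durbin-Watson statistic is tested by
#' permutation. Returns the fraction of iterations without a significant
#' signal of temporal autocorrelation.
#'
#' @param residuals Model residuals.
#' @param years Matching observation years (>= 2 distinct; years with no
#'   residuals are skipped with a warning).
#' @param n_iter Iterations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param n_perm Permutations per test (default 199).
#' @param alternative Passed to [dw_test()].
#' @return List with `fraction_nonsignificant`, `n_iter`, `mean_dw`,
#'   `mean_p`.
#' @export
dw_resample <- function(residuals, years, n_iter = 1000, alpha = 0.05,
                        seed = 1L, n_perm = 199,
                        alternative = "positive") {
  by_year <- split(residuals, years)
  empty <- vapply(by_year, function(v) length(v) == 0, TRUE)
  if (any(empty)) {
    warning("dw_resample: year(s) without residuals skipped: ",
            paste(names(by_year)[empty], collapse = ", "), call. = FALSE)
    by_year <- by_year[!empty]
  }
  if (length(by_year) < 2) stop("dw_resample: need >= 2 distinct years", call. = FALSE)
  ord <- order(as.numeric(names(by_year)))
  by_year <- by_year[ord]
  with_seed_local(seed, {
    res <- vapply(seq_len(n_iter), function(i) {
      s <- vapply(by_year, function(v) v[sample.int(length(v), 1)], 0)
      t <- dw_test(s, n_perm = n_perm, alternative = alternative)
      c(t$statistic, t$p_value)
    }, c(0, 0))
    list(fraction_nonsignificant = mean(res[2, ] >= alpha),
         n_iter = n_iter, mean_dw = mean(res[1, ]), mean_p = mean(res[2, ]))
  })
}

#' Per-species Durbin-Watson resampling
#'
#' Runs [dw_resample()] with 100 iterations within each species and
#' reports per-species mean statistics, flagging species whose mean
#' permutation p falls below `alpha`.
#'
#' @param residuals,years,species Parallel vectors.
#' @param n_iter Iterations per species (default 100).
#' @param alpha Flagging level (default 0.05).
#' @param seed Integer seed.
#' @return A tibble: `species_id`, `mean_dw`, `mean_p`, `flagged`.
#' @export
dw_by_species <- function(residuals, years, species, n_iter = 100, alpha = 0.05,
                          seed = 1L) {
  sp <- sort(unique(species))
  purrr::map_dfr(seq_along(sp), function(i) {
    idx <- species == sp[i]
    if (length(unique(years[idx])) < 2) {
      return(tibble::tibble(species_id = sp[i], mean_dw = NA_real_,
                            mean_p = NA_real_, flagged = FALSE))
    }
    r <- suppressWarnings(
      dw_resample(residuals[idx], years[idx], n_iter = n_iter, alpha = alpha,
                  seed = seed + i))
    tibble::tibble(species_id = sp[i], mean_dw = r$mean_dw, mean_p = r$mean_p,
                   flagged = r$mean_p < alpha)
  })
}

#' Spline correlogram of residual spatial autocorrelation
#'
#' A distance-binned Moran-type correlation of residual products against
#' great-circle distance (km), smoothed with a cubic spline, with a
#' bootstrap envelope from resampling observation locations. The contract
#' is a smooth correlation-versus-distance curve with an envelope, not any
#' particular published algorithm.
#'
#' @param residuals Model residuals (>= 20 points).
#' @param lat,lon Observation coordinates (decimal degrees).
#' @param n_boot Bootstrap replicates (default 99).
#' @param n_bins Distance bins (default 12).
#' @param max_dist Maximum pair distance in km (default: median pair
#'   distance, the informative short-range half).
#' @param seed Integer seed.
#' @param max_points Cap on points used (pairs grow quadratically); a
#'   random subset is taken above it.
#' @return A `spline_correlogram` tibble: `distance_km`, `correlation`,
#'   `lower`, `upper`.
#' @export
spline_correlogram <- function(residuals, lat, lon, n_boot = 99, n_bins = 12,
                               max_dist = NULL, seed = 1L, max_points = 600) {
  n <- length(residuals)
  if (n < 20) stop("spline_correlogram: need >= 20 points", call. = FALSE)
  if (length(unique(paste(lat, lon))) < 2) {
    stop("spline_correlogram: all points at a single location", call. = FALSE)
  }
  with_seed_local(seed, {
    if (n > max_points) {
      idx <- sample.int(n, max_points)
      residuals <- residuals[idx]; lat <- lat[idx]; lon <- lon[idx]
      n <- max_points
    }
    pts <- cbind(lon, lat)
    D <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
    z <- (residuals - mean(residuals)) / stats::sd(residuals)
    P <- tcrossprod(z)
    iu <- which(upper.tri(D))
    d <- D[iu]; prod <- P[iu]
    if (is.null(max_dist)) max_dist <- stats::median(d)
    keep <- d <= max_dist & d > 0
    d <- d[keep]; prod <- prod[keep]

    curve_on <- function(dd, pp) {
      brk <- seq(0, max_dist, length.out = n_bins + 1)
      mid <- (brk[-1] + brk[-length(brk)]) / 2
      bin <- cut(dd, brk, include.lowest = TRUE, labels = FALSE)
      est <- vapply(seq_len(n_bins), function(b) mean(pp[bin == b]), 0)
      ok <- is.finite(est)
      if (sum(ok) < 4) return(rep(NA_real_, n_bins))
      sp <- stats::smooth.spline(mid[ok], est[ok], df = min(5, sum(ok) - 1))
      stats::predict(sp, mid)$y
    }
    grid_mid <- (seq(0, max_dist, length.out = n_bins + 1)[-1] +
                   seq(0, max_dist, length.out = n_bins + 1)[-(n_bins + 1)]) / 2
    est <- curve_on(d, prod)
    boot <- replicate(n_boot, {
      bi <- sample.int(length(d), length(d), replace = TRUE)
      curve_on(d[bi], prod[bi])
    })
    lower <- apply(boot, 1, stats::quantile, 0.025, na.rm = TRUE)
    upper <- apply(boot, 1, stats::quantile, 0.975, na.rm = TRUE)
    structure(tibble::tibble(distance_km = grid_mid, correlation = est,
                             lower = lower, upper = upper),
              class = c("spline_correlogram", class(tibble::tibble())))
  })
}

#' Influence screening by standardized residuals
#'
#' Flags observations whose |residual / sd(residuals)| exceeds the
#' threshold (default 4). `refit` additionally refits the model without the
#' flagged rows and reports the shift in each fixed effect.
#'
#' @param fit A `pglmm_fit`.
#' @param threshold Standardized-residual cutoff.
#' @param refit Compare coefficients after dropping flagged rows.
#' @return List with `flagged` (row indices), `fraction`, and optionally
#'   `beta_shift` (tibble of original/refit estimates).
#' @export
influence_screen <- function(fit, threshold = 4, refit = FALSE) {
  stopifnot(inherits(fit, "pglmm_fit"))
  z <- fit$residuals / stats::sd(fit$residuals)
  flagged <- which(abs(z) > threshold)
  out <- list(flagged = flagged, fraction = length(flagged) / length(z))
  if (refit && length(flagged) > 0) {
    design <- fit$design
    dat <- design$data[-flagged, , drop = FALSE]
    # rebuild from the retained (already z-scored) rows
    refit_design <- assemble_rezscore(dat, design)
    refit_fit <- fit_pglmm(refit_design, reml = fit$reml, vc_intervals = FALSE)
    out$beta_shift <- dplyr::left_join(
      fit$coefficients[c("term", "estimate")],
      dplyr::rename(refit_fit$coefficients[c("term", "estimate")],
                    estimate_refit = "estimate"),
      by = "term")
  }
  out
}

# reassemble on a row subset without double z-scoring
assemble_rezscore <- function(dat, design) {
  spec <- design$spec
  for (cl in names(design$z_means)) {
    dat[[cl]] <- dat[[cl]] * design$z_sds[[cl]] + design$z_means[[cl]]
  }
  assemble(dat, spec, design$C)
}

#' Posterior predictive check by simulation from the fitted model
#'
#' Simulates `n_sim` response vectors from the fitted generative structure
#' (fixed effects, fitted variance components with their correlation, and
#' residual noise) and compares the observed response's mean, sd and
#' deciles against the simulated envelopes.
#'
#' @param fit A `pglmm_fit`.
#' @param n_sim Number of simulated response vectors (default 1000).
#' @param seed Integer seed.
#' @return A `ppc_summary` list: `observed` (named stats), `simulated`
#'   (matrix of the same stats per simulation), `coverage` (logical: is
#'   each observed stat inside its simulated 95% envelope), plus the
#'   simulations' 2.5/97.5% bounds.
#' @export
posterior_predictive_check <- function(fit, n_sim = 1000, seed = 1L) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (n_sim < 2) warning("posterior_predictive_check: envelope degenerate with n_sim < 2",
                         call. = FALSE)
  design <- fit$design
  Zt <- do.call(rbind, design$blocks)
  q <- nrow(Zt)
  d <- rep(fit$theta, times = design$block_sizes)
  mu <- drop(design$X %*% fit$coefficients$estimate)
  n <- length(mu)
  sstats <- function(y) c(mean = mean(y), sd = stats::sd(y),
                          stats::quantile(y, seq(0.1, 0.9, 0.1)))
  with_seed_local(seed, {
    sims <- vapply(seq_len(n_sim), function(i) {
      u <- stats::rnorm(q) * d
      y <- mu + as.numeric(Matrix::crossprod(Zt, u)) * sqrt(fit$sigma2) +
        stats::rnorm(n, 0, sqrt(fit$sigma2))
      sstats(y)
    }, sstats(mu))
    obs <- sstats(fit$y)
    lo <- apply(sims, 1, stats::quantile, 0.025)
    hi <- apply(sims, 1, stats::quantile, 0.975)
    structure(list(observed = obs, lower = lo, upper = hi,
                   coverage = obs >= lo & obs <= hi, n_sim = n_sim),
              class = "ppc_summary")
  })
}

#' Full diagnostics battery for a fitted model
#'
#' Bundles VIF, the global and per-species Durbin-Watson resampling, the
#' spatial spline correlogram, influence screening, and the posterior
#' predictive check into one report.
#'
#' @param fit A `pglmm_fit`.
#' @param seed Integer seed for every stochastic component.
#' @param dw_iter,ppc_sim,boot Iteration counts for the stochastic parts.
#' @return A `diagnostics_report` list.
#' @export
diagnose <- function(fit, seed = 1L, dw_iter = 1000, ppc_sim = 1000, boot = 99) {
  design <- fit$design
  dat <- design$data
  Xn <- design$X[, setdiff(colnames(design$X), "(Intercept)"), drop = FALSE]
  dw <- dw_resample(fit$residuals, dat$year, n_iter = dw_iter, seed = seed)
  report <- list(
    vif = vif(Xn),
    dw_global = dw,
    dw_species = dw_by_species(fit$residuals, dat$year, dat$species_id,
                               seed = seed + 1),
    correlogram = spline_correlogram(fit$residuals, dat$lat, dat$lon,
                                     n_boot = boot, seed = seed + 2),
    influence = influence_screen(fit),
    ppc = posterior_predictive_check(fit, n_sim = ppc_sim, seed = seed + 3)
  )
  structure(report, class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat("  max VIF:", round(max(x$vif), 2), "\n")
  cat(sprintf("  DW non-significant fraction: %.3f (n_iter=%d)\n",
              x$dw_global$fraction_nonsignificant, x$dw_global$n_iter))
  cat(sprintf("  influence: %d flagged (%.2f%%)\n",
              length(x$influence$flagged), 100 * x$influence$fraction))
  cat(sprintf("  PPC coverage: %d/%d observed stats inside the 95%% envelope\n",
              sum(x$ppc$coverage), length(x$ppc$coverage)))
  invisible(x)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
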