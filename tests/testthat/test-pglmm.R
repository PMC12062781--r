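# independent oracle: shared root-to-tip path length by explicit node-path
# enumeration, no vcv machinery
shared_path_corr <- function(tree, a, b) {
  root <- ape::Ntip(tree) + 1L
  depth <- function(tip) {
    p <- ape::nodepath(tree, root, which(tree$tip.label == tip))
    sum(tree$edge.length[match(paste(p[-length(p)], p[-1]),
                               paste(tree$edge[, 1], tree$edge[, 2]))])
  }
  pa <- ape::nodepath(tree, root, which(tree$tip.label == a))
  pb <- ape::nodepath(tree, root, which(tree$tip.label == b))
  common <- intersect(pa, pb)
  if (length(common) <= 1) return(0)
  deepest <- common[length(common)]
  pc <- pa[seq_len(match(deepest, pa))]
  shared <- sum(tree$edge.length[match(paste(pc[-length(pc)], pc[-1]),
                                       paste(tree$edge[, 1], tree$edge[, 2]))])
  shared / sqrt(depth(a) * depth(b))
}

test_that("phylogenetic correlation follows shared branch lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_correlation(tree, c("A", "B", "C"))
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(1, 3))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(phylo_correlation(star, LETTERS[1:4]), diag(4),
               ignore_attr = TRUE)
})

test_that("correlation matches the path-enumeration oracle on random trees", {
  set.seed(5)
  for (i in 1:10) {
    tree <- ape::rphylo(6, 1, 0)
    C <- phylo_correlation(tree, tree$tip.label)
    pairs <- utils::combn(tree$tip.label, 2)
    for (j in sample(ncol(pairs), 4)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      expect_equal(C[a, b], shared_path_corr(tree, a, b), tolerance = 1e-10)
    }
  }
})

test_that("the diagonal is exactly one for many random trees", {
  set.seed(8)
  for (i in 1:50) {
    tree <- ape::rtree(sample(3:20, 1))
    C <- phylo_correlation(tree, tree$tip.label)
    expect_equal(unname(diag(C)), rep(1, nrow(C)))
  }
})

test_that("missing tips raise an error listing the species", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(phylo_correlation(tree, c("A", "D")), "D")
})

test_that("design assembly builds the stated fixed and random structures", {
  dat <- sim_model_data()
  spec <- pglmm_spec("log10_mass")
  des <- assemble(dat, spec, ident_C(dat))
  expect_equal(ncol(des$X), 9)                    # intercept + 5 mains + 3 ints
  expect_equal(nrow(des$blocks$species_iid), 6)
  expect_equal(names(des$blocks),
               c("realm", "site", "species_iid", "species_phylo",
                 "slope_tpi_iid", "slope_tpi_phylo"))

  no_year <- assemble(dat, pglmm_spec("log10_mass", include_year = FALSE),
                      ident_C(dat))
  expect_equal(ncol(no_year$X), 8)                # intercept + 7 terms

  dat2 <- dat
  dat2$api[5] <- NA
  des2 <- assemble(dat2, spec, ident_C(dat))
  expect_equal(des2$n_dropped, 1)
  expect_equal(length(des2$y), nrow(dat) - 1)
})

test_that("a duplicated predictor is reported as collinear", {
  dat <- sim_model_data()
  dat$api <- dat$tpi
  expect_error(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
               "collinear")
})

test_that("noise-free data is interpolated exactly", {
  dat <- sim_model_data(n = 300, sd_sp = 0, sd_site = 0, sd_e = 0)
  des <- assemble(dat, pglmm_spec("log10_mass"), ident_C(dat))
  fit <- fit_pglmm(des, vc_intervals = FALSE)
  # the generating coefficients on the z-scale of this sample
  ls <- qr.solve(des$X, des$y)
  expect_lt(max(abs(fit$coefficients$estimate - ls)), 1e-6)
  expect_lt(fit$sigma2, 1e-8)
})

test_that("the sparse likelihood matches dense brute force over random draws", {
  w <- gen_world(tiny_world(seed = 77L, n_species = 5L, obs_per_species = 10L,
                            juvenile_frac = 0, outlier_frac = 0))
  dat <- w$observations
  dat <- dat[seq_len(min(50, nrow(dat))), ]
  des <- assemble(dat, pglmm_spec("log10_mass"), phylo_correlation(w$tree, sort(unique(dat$species_id))))
  set.seed(123)
  for (i in 1:20) {
    beta <- rnorm(ncol(des$X), 0, 0.5)
    sigma2 <- runif(1, 0.2, 2)
    vc <- stats::setNames(runif(length(des$blocks), 0, 1), names(des$blocks))
    expect_equal(mixed_loglik(des, beta, sigma2, vc),
                 dense_mixed_loglik(des, beta, sigma2, vc),
                 tolerance = 1e-6)
  }
})

test_that("with identity phylogeny the fit matches the lme4 oracle", {
  skip_if_not_installed("lme4")
  dat <- sim_model_data(n = 1500, n_sp = 10, n_site = 60, seed = 4)
  des <- assemble(dat, pglmm_spec("log10_mass"), ident_C(dat))
  fit <- fit_pglmm(des, vc_intervals = FALSE)
  m <- lme4::lmer(
    log10_mass ~ tpi + api + alu + ulu + year_z + tpi:api + tpi:alu + tpi:ulu +
      (1 | realm) + (1 | site) + (1 | species_id) + (0 + tpi | species_id),
    data = des$data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  ord <- fit$coefficients$term
  expect_equal(fit$coefficients$estimate,
               unname(lme4::fixef(m)[ord]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  # identifiable sums: the iid+phylo pairs are exchangeable under C = I
  get_v <- function(tab, term) tab$variance[tab$term == term]
  expect_equal(get_v(fit$varcomp, "site"),
               vc$vcov[vc$grp == "site"], tolerance = 1e-3)
  expect_equal(get_v(fit$varcomp, "species_iid") + get_v(fit$varcomp, "species_phylo"),
               sum(vc$vcov[vc$grp %in% c("species_id", "species_id.1") &
                             vc$var1 == "(Intercept)"]), tolerance = 1e-3)
  expect_equal(get_v(fit$varcomp, "residual"),
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("species-level variance is recovered in an identity-phylogeny world", {
  # with a star phylogeny the iid and phylo species terms are exchangeable;
  # their sum should recover the generating species-level variance
  cfg <- tiny_world(seed = 55L, n_species = 25L, obs_per_species = 80L,
                    juvenile_frac = 0, outlier_frac = 0)
  w_rt <- gen_ranges_and_tree(cfg)
  star <- ape::stree(cfg$n_species, "star")
  star$tip.label <- w_rt$tree$tip.label
  star$edge.length <- rep(1, nrow(star$edge))
  cl <- gen_climate(cfg); lu <- gen_landuse(cfg); realm <- gen_realm(cfg)
  obs <- gen_observations(cfg, cl, lu, realm, w_rt$ranges, star)
  des <- assemble(obs, pglmm_spec("log10_mass"),
                  phylo_correlation(star, sort(unique(obs$species_id))))
  fit <- fit_pglmm(des, vc_intervals = FALSE)
  v_sp <- sum(fit$varcomp$variance[fit$varcomp$term %in%
                                     c("species_iid", "species_phylo")])
  truth <- cfg$sigma2[["species_iid"]] + cfg$sigma2[["species_phylo"]]
  # Monte-Carlo standard error of a variance from n_species group effects
  mc_se <- truth * sqrt(2 / (cfg$n_species - 1))
  expect_lt(abs(v_sp - truth), 3 * mc_se)
})

test_that("interval bounds bracket estimates and pd stays in [0.5, 1]", {
  dat <- sim_model_data(seed = 10)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = TRUE)
  co <- fit$coefficients
  expect_true(all(co$conf_low <= co$estimate & co$estimate <= co$conf_high))
  expect_true(all(co$pd >= 0.5 & co$pd <= 1))
  expect_true(all(fit$varcomp$variance >= 0))
})

test_that("partial R2 is the observed-fitted squared correlation", {
  dat <- sim_model_data(seed = 2)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  expect_equal(partial_r2(fit), stats::cor(fit$y, fit$fitted)^2)

  # worked 5-point correlation oracle
  y <- c(1, 2, 3, 4, 10); f <- c(1.2, 1.8, 3.4, 3.9, 9)
  r2_hand <- (sum((y - mean(y)) * (f - mean(f))) /
                sqrt(sum((y - mean(y))^2) * sum((f - mean(f))^2)))^2
  toy <- fit
  toy$y <- y; toy$fitted <- f
  expect_equal(partial_r2(toy), r2_hand)

  toy$fitted <- rep(2, 5)
  expect_warning(r0 <- partial_r2(toy), "constant")
  expect_equal(r0, 0)
})

test_that("tidy, glance and autoplot expose the fit in broom style", {
  dat <- sim_model_data(seed = 6, n = 300)
  fit <- fit_pglmm(assemble(dat, pglmm_spec("log10_mass"), ident_C(dat)),
                   vc_intervals = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "conf_low", "conf_high", "pd") %in% names(td)))
  expect_equal(nrow(tidy(fit, effects = "ran_pars")), 7)
  gl <- glance(fit)
  expect_equal(gl$nobs, length(fit$y))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
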