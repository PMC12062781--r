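#' Brownian-motion phylogenetic correlation matrix
#'
#' Under Brownian motion on the tree, the covariance of two tips is their
#' shared root-to-tip path length; scaling to unit diagonal gives
#' `C[i, j] = shared(i, j) / sqrt(depth_i * depth_j)`. The unit diagonal
#' makes the phylogenetic variance component directly comparable to the
#' independent species component.
#'
#' @param tree A `phylo` tree whose tips include `species`.
#' @param species Character vector giving the species order of the matrix.
#' @return A correlation matrix (rows/cols in `species` order).
#' @export
phylo_correlation <- function(tree, species) {
  missing_tips <- setdiff(species, tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("phylo_correlation: species missing from tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  pruned <- ape::keep.tip(tree, species)
  V <- ape::vcv.phylo(pruned)
  C <- stats::cov2cor(V)[species, species, drop = FALSE]
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda_min <- min(ev)
  if (lambda_min < -1e-8) {
    stop("phylo_correlation: matrix not positive semidefinite (min eigenvalue ",
         signif(lambda_min, 3), ")", call. = FALSE)
  }
  if (lambda_min < 1e-10) {
    # repair a numerically semidefinite matrix with a small ridge
    C <- C + diag(1e-8, nrow(C))
    C <- stats::cov2cor(C)
  }
  C
}

#' Specify a phylogenetic mixed model
#'
#' Gaussian response; fixed effects TPI, API, ALU, ULU, optionally year,
#' and the interactions TPI:API, TPI:ALU, TPI:ULU; random intercepts for
#' realm, site, species (independent) and species (phylogenetically
#' correlated); for each slope predictor, two mutually uncorrelated random
#' slopes — one independent across species and one carrying the
#' phylogenetic correlation.
#'
#' @param response One of `"log10_mass"`, `"log10_length"`,
#'   `"mass_length_ratio"`.
#' @param include_year Include the year covariate (set `FALSE` for the
#'   year-removed sensitivity fit).
#' @param slopes `"tpi"` (default: random slopes on TPI only) or `"all"`
#'   (random slopes on every level-one fixed effect).
#' @return A `pglmm_spec` list.
#' @export
pglmm_spec <- function(response = c("log10_mass", "log10_length", "mass_length_ratio"),
                       include_year = TRUE, slopes = c("tpi", "all")) {
  response <- match.arg(response)
  slopes <- match.arg(slopes)
  mains <- c("tpi", "api", "alu", "ulu", if (include_year) "year_z")
  slope_terms <- if (slopes == "tpi") "tpi" else mains
  structure(list(response = response,
                 mains = mains,
                 interactions = c("tpi:api", "tpi:alu", "tpi:ulu"),
                 slope_terms = slope_terms,
                 include_year = include_year),
            class = "pglmm_spec")
}

#' Assemble model design structures
#'
#' Z-scores the response and the main-effect covariates over the modelled
#' rows, forms interactions as products of the z-scored main effects, and
#' builds the sparse random-effect incidence structures. The
#' phylogenetically correlated terms are "folded": their incidence matrix
#' is post-multiplied by the lower Cholesky factor `L` of `C` so the
#' correlated effects become independent ones on a transformed basis
#' (`Z C Z' = (Z L)(Z L)'`).
#'
#' @param table Cleaned observation tibble with covariates attached (`tpi`,
#'   `api`, `alu`, `ulu`, `realm`, `site` and the response column).
#' @param spec A [pglmm_spec()].
#' @param C Phylogenetic correlation matrix from [phylo_correlation()]
#'   covering the table's species.
#' @return A `pglmm_design` list: `y`, `X`, sparse blocks `Zt` (one per
#'   random term, transposed), block metadata, z-transform parameters, the
#'   retained rows, and the dropped-row count.
#' @export
assemble <- function(table, spec, C) {
  stopifnot(inherits(spec, "pglmm_spec"))
  table$year_z <- as.numeric(table$year)
  cols_needed <- c(spec$response, setdiff(spec$mains, "year_z"),
                   if (spec$include_year) "year_z", "realm", "site", "species_id")
  miss_cols <- setdiff(cols_needed, names(table))
  if (length(miss_cols) > 0) {
    stop("assemble: missing column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(table[cols_needed])
  n_dropped <- sum(!complete)
  dat <- table[complete, , drop = FALSE]
  if (nrow(dat) == 0) stop("assemble: no complete rows", call. = FALSE)

  zcols <- c(spec$response, spec$mains)
  zs <- zscore_columns(dat, zcols)
  dat <- zs$table

  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[spec$mains]))
  for (ia in spec$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    X <- cbind(X, dat[[parts[1]]] * dat[[parts[2]]])
    colnames(X)[ncol(X)] <- ia
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("assemble: rank-deficient fixed design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  species <- sort(unique(dat$species_id))
  missC <- setdiff(species, rownames(C))
  if (length(missC) > 0) {
    stop("assemble: species missing from correlation matrix: ",
         paste(missC, collapse = ", "), call. = FALSE)
  }
  Cs <- C[species, species, drop = FALSE]
  L <- t(chol(Cs))

  fac_Zt <- function(f) {
    f <- factor(f)
    Zt <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                               dims = c(nlevels(f), length(f)),
                               dimnames = list(levels(f), NULL))
    Matrix::drop0(Zt)
  }
  sp_f <- factor(dat$species_id, levels = species)
  Zt_sp <- fac_Zt_levels(sp_f)

  blocks <- list(
    realm = fac_Zt(dat$realm),
    site = fac_Zt(dat$site),
    species_iid = Zt_sp,
    species_phylo = methods::as(t(L) %*% Zt_sp, "CsparseMatrix")
  )
  for (s in spec$slope_terms) {
    xs <- dat[[s]]
    Zt_slope <- Zt_sp %*% Matrix::Diagonal(x = xs)
    blocks[[paste0("slope_", s, "_iid")]] <- methods::as(Zt_slope, "CsparseMatrix")
    blocks[[paste0("slope_", s, "_phylo")]] <-
      methods::as(t(L) %*% Zt_slope, "CsparseMatrix")
  }

  structure(list(y = dat[[spec$response]], X = X, blocks = blocks,
                 block_sizes = vapply(blocks, nrow, 0L),
                 species = species, C = Cs, L = L,
                 z_means = zs$means, z_sds = zs$sds,
                 data = dat, n_dropped = n_dropped, spec = spec),
            class = "pglmm_design")
}

fac_Zt_levels <- function(f) {
  Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                       dims = c(nlevels(f), length(f)),
                       dimnames = list(levels(f), NULL))
}

#' Fit the phylogenetic mixed model by profiled REML
#'
#' The marginal covariance is `sigma^2 (I + sum_k theta_k^2 Z_k Z_k')` on
#' the folded basis; beta and sigma^2 are profiled out analytically and the
#' restricted-likelihood criterion is minimized over the relative
#' standard-deviation ratios `theta` with a bounded derivative-free
#' optimizer. Sparse Cholesky factorization keeps each criterion
#' evaluation linear in the number of non-zeros. Estimates are
#' deterministic: no Monte Carlo is involved.
#'
#' Fixed-effect intervals are Wald intervals on the t distribution with
#' containment degrees of freedom (species-level df for the intercept and
#' any predictor carrying a random slope, residual df otherwise), and `pd`
#' — the probability that the effect has the sign of its estimate — comes
#' from the same asymptotic approximation.
#'
#' @param design A `pglmm_design` from [assemble()].
#' @param reml Use the restricted criterion (default) or plain maximum
#'   likelihood.
#' @param theta_init Optional starting ratios.
#' @param conf_level Interval coverage (default 0.95).
#' @param vc_intervals Compute Wald intervals for the variance components
#'   (needs a numerical Hessian; disable in tight simulation loops).
#' @return A `pglmm_fit` object; see [tidy.pglmm_fit()],
#'   [glance.pglmm_fit()], [partial_r2()].
#' @export
fit_pglmm <- function(design, reml = TRUE, theta_init = NULL, conf_level = 0.95,
                      vc_intervals = TRUE) {
  stopifnot(inherits(design, "pglmm_design"))
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  K <- length(design$blocks)
  sizes <- design$block_sizes
  Zt <- do.call(rbind, design$blocks)
  q <- nrow(Zt)

  ZtZ <- Matrix::forceSymmetric(Zt %*% Matrix::t(Zt))
  ZtX <- as.matrix(Zt %*% X)
  Zty <- as.numeric(Zt %*% y)
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  yty <- sum(y^2)
  Iq <- Matrix::Diagonal(q)
  denom <- if (reml) n - p else n

  eval_crit <- function(theta, want = "crit") {
    d <- rep(theta, times = sizes)
    D <- Matrix::Diagonal(x = d)
    A <- Matrix::forceSymmetric(D %*% ZtZ %*% D + Iq)
    Ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    ldA <- as.numeric(Matrix::determinant(Ch, sqrt = FALSE)$modulus)
    solveL <- function(B) {
      as.matrix(Matrix::solve(Ch, Matrix::solve(Ch, B, system = "P"), system = "L"))
    }
    RZX <- solveL(d * ZtX)
    cu <- drop(solveL(matrix(d * Zty, ncol = 1)))
    M <- XtX - crossprod(RZX)
    RX <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(RX)) return(if (want == "crit") 1e10 else NULL)
    cx <- drop(backsolve(RX, Xty - drop(crossprod(RZX, cu)), transpose = TRUE))
    r2 <- max(yty - sum(cu^2) - sum(cx^2), 1e-300)
    ldRX <- 2 * sum(log(diag(RX)))
    crit <- ldA + (if (reml) ldRX else 0) +
      denom * (1 + log(2 * pi * r2 / denom))
    if (want == "crit") return(crit)
    beta <- drop(backsolve(RX, cx))
    names(beta) <- colnames(X)
    # u on the folded/scaled basis: A u = D Z'(y - X beta)
    rhs <- d * (Zty - drop(ZtX %*% beta))
    u <- drop(Matrix::solve(Ch, rhs))
    sigma2 <- r2 / denom
    vcov_beta <- chol2inv(RX) * sigma2
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    list(crit = crit, beta = beta, sigma2 = sigma2, vcov_beta = vcov_beta,
         u = u, d = d)
  }

  if (is.null(theta_init)) theta_init <- rep(0.5, K)
  opt <- minqa::bobyqa(theta_init, function(th) eval_crit(th),
                       lower = rep(1e-6, K), upper = rep(1e3, K),
                       control = list(rhobeg = 0.2, rhoend = 1e-7, maxfun = 4000))
  if (opt$ierr != 0) {
    stop("fit_pglmm: optimizer failed to converge (ierr=", opt$ierr,
         ", feval=", opt$feval, ", value=", signif(opt$fval, 8), ")", call. = FALSE)
  }
  theta <- opt$par
  sol <- eval_crit(theta, want = "full")
  if (is.null(sol)) stop("fit_pglmm: singular fixed-effects system at optimum",
                         call. = FALSE)

  fitted <- as.numeric(X %*% sol$beta) + as.numeric(Matrix::crossprod(Zt, sol$d * sol$u))
  residuals <- y - fitted
  se <- sqrt(diag(sol$vcov_beta))
  # containment degrees of freedom: terms whose effect is replicated at the
  # species level (the intercept and any predictor carrying a random slope)
  # are judged against n_species - 1; all others against n - p
  n_species <- length(design$species)
  df <- vapply(names(sol$beta), function(tm) {
    if (tm == "(Intercept)" || tm %in% design$spec$slope_terms)
      n_species - 1 else n - p
  }, 0)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = names(sol$beta),
    estimate = unname(sol$beta),
    std_error = unname(se),
    df = unname(df),
    conf_low = unname(sol$beta - tq * se),
    conf_high = unname(sol$beta + tq * se),
    pd = unname(stats::pt(abs(sol$beta) / se, df))
  )
  varcomp <- varcomp_table(theta, sizes, sol$sigma2, eval_crit, zq,
                           intervals = vc_intervals)

  structure(list(coefficients = coefs, vcov = sol$vcov_beta,
                 varcomp = varcomp, sigma2 = sol$sigma2, theta = theta,
                 fitted = fitted, residuals = residuals, y = y,
                 loglik = -opt$fval / 2, reml = reml,
                 conf_level = conf_level,
                 optimizer = list(feval = opt$feval, value = opt$fval),
                 design = design,
                 interval_method = "wald-t-containment", pd_method = "asymptotic-t"),
            class = "pglmm_fit")
}

# Wald intervals for variance components on the log-theta scale; boundary
# estimates (theta at its lower bound) get NA intervals.
varcomp_table <- function(theta, sizes, sigma2, eval_crit, zq, intervals = TRUE) {
  K <- length(theta)
  at_bound <- theta <= 1e-5
  ci_lo <- ci_hi <- rep(NA_real_, K)
  free <- if (intervals) which(!at_bound) else integer(0)
  if (length(free) > 0) {
    f_log <- function(lt) {
      th <- theta
      th[free] <- exp(lt)
      eval_crit(th)
    }
    H <- tryCatch(stats::optimHess(log(theta[free]), f_log), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H / 2), error = function(e) NULL)  # crit is -2 logLik
      if (!is.null(V)) {
        se_log <- suppressWarnings(sqrt(diag(as.matrix(V))))
        ok <- is.finite(se_log)
        # var = theta^2 sigma^2; on the log scale log var = 2 log theta + const
        ci_lo[free[ok]] <- theta[free[ok]]^2 * sigma2 * exp(-2 * zq * se_log[ok])
        ci_hi[free[ok]] <- theta[free[ok]]^2 * sigma2 * exp(2 * zq * se_log[ok])
      }
    }
  }
  tibble::tibble(
    term = c(names(sizes), "residual"),
    variance = c(theta^2 * sigma2, sigma2),
    sd = sqrt(c(theta^2 * sigma2, sigma2)),
    conf_low = c(ci_lo, NA_real_),
    conf_high = c(ci_hi, NA_real_)
  )
}

#' Marginal Gaussian log-likelihood of the mixed model
#'
#' Evaluates the log-density of `y ~ N(X beta, sigma2 (I + sum_k theta_k^2
#' Z_k Z_k'))` through the same sparse Woodbury representation the fitter
#' uses. Intended for checking the sparse path against a dense
#' covariance-matrix evaluation on small problems.
#'
#' @param design A `pglmm_design`.
#' @param beta Fixed-effect vector (in `colnames(design$X)` order).
#' @param sigma2 Residual variance.
#' @param varcomp Named vector of random-term variances, in
#'   `names(design$blocks)` order.
#' @return The log-likelihood (a scalar).
#' @export
mixed_loglik <- function(design, beta, sigma2, varcomp) {
  stopifnot(length(varcomp) == length(design$blocks))
  Zt <- do.call(rbind, design$blocks)
  q <- nrow(Zt)
  n <- length(design$y)
  theta <- sqrt(pmax(varcomp, 0) / sigma2)
  d <- rep(theta, times = design$block_sizes)
  r <- design$y - drop(design$X %*% beta)
  Ztr <- d * as.numeric(Zt %*% r)
  A <- Matrix::forceSymmetric(Matrix::Diagonal(x = d) %*% (Zt %*% Matrix::t(Zt)) %*%
                                Matrix::Diagonal(x = d) + Matrix::Diagonal(q))
  Ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  ldA <- as.numeric(Matrix::determinant(Ch, sqrt = FALSE)$modulus)
  w <- as.matrix(Matrix::solve(Ch, Matrix::solve(Ch, Ztr, system = "P"), system = "L"))
  quad <- (sum(r^2) - sum(w^2)) / sigma2
  -0.5 * (n * log(2 * pi * sigma2) + ldA + quad)
}

#' Conditional partial R-squared of a fit
#'
#' The squared Pearson correlation between the observed (z-scored) response
#' and the fitted values including random effects — a "conditional"
#' variance-explained summary. Not invariant to affine transformation of
#' the fitted values; the plain definition is reported.
#'
#' @param fit A `pglmm_fit`.
#' @return A single number in `[0, 1]`; 0 with a warning when the fitted
#'   values are constant.
#' @export
partial_r2 <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (stats::sd(fit$fitted) == 0) {
    warning("partial_r2: fitted values are constant; returning 0", call. = FALSE)
    return(0)
  }
  stats::cor(fit$y, fit$fitted)^2
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat(sprintf("<pglmm_fit> %s ~ %s | n=%d, species=%d, %s\n",
              x$design$spec$response,
              paste(c(x$design$spec$mains, x$design$spec$interactions), collapse = " + "),
              length(x$y), length(x$design$species),
              if (x$reml) "REML" else "ML"))
  print(x$coefficients, n = Inf)
  cat("Variance components:\n")
  print(x$varcomp, n = Inf)
  invisible(x)
}
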