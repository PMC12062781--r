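#' Pipeline configuration
#'
#' @param out_dir Directory for stage outputs and the manifest.
#' @param seed Global seed propagated to every stochastic stage.
#' @param world A [world_config()] (its own seed is overridden by `seed`).
#' @param metric Size metric to model (`"mass"` or `"length"`).
#' @param mad_k,n_min,site_decimals Cleaning parameters.
#' @param include_year,slopes Model options (see [pglmm_spec()]).
#' @param dw_iter,ppc_sim,boot Diagnostics iteration counts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, world = world_config(),
                            metric = "mass", mad_k = 5, n_min = 100,
                            site_decimals = 4, include_year = TRUE,
                            slopes = "tpi", dw_iter = 200, ppc_sim = 200,
                            boot = 49) {
  world$seed <- as.integer(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their fixed order — `synth` (generate
#' the world and write its artifacts), `clean`, `limits`, `covariates`,
#' `fit`, `diagnose` — each stage reading the previous stage's files from
#' `out_dir`, and writes a JSON manifest (input hashes, per-stage row
#' counts, seed, package version) that makes reruns byte-comparable. Any
#' stage failure propagates with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default: all).
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "clean", "limits", "covariates",
                                    "fit", "diagnose")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("nichetrait")),
                   stages = list())
  log_stage <- function(name, files, counts) {
    hashes <- stats::setNames(as.vector(tools::md5sum(files)), basename(files))
    manifest$stages[[name]] <<- list(files = as.list(hashes),
                                     counts = as.list(counts))
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(name, files) {
    missing <- files[!file.exists(files)]
    if (length(missing) > 0) {
      stop("pipeline stage '", name, "' precondition: missing input file(s): ",
           paste(basename(missing), collapse = ", "), call. = FALSE)
    }
  }

  if ("synth" %in% stages) run_stage("synth", {
    world <- gen_world(config$world)
    write_climate_cube(world$climate$tmax, path("tmax.csv"))
    write_climate_cube(world$climate$ppt, path("ppt.csv"))
    write_climate_cube(world$climate$pet, path("pet.csv"))
    write_climate_cube(world$landuse$cropland, path("cropland.csv"))
    write_climate_cube(world$landuse$pasture, path("pasture.csv"))
    write_climate_cube(world$landuse$urban, path("urban.csv"))
    write_climate_cube(world$realm, path("realm.csv"))
    write_range_masks(world$ranges, path("ranges.csv"))
    ape::write.tree(world$tree, path("tree.nwk"))
    readr::write_csv(world$observations, path("observations_raw.csv"))
    log_stage("synth", path(c("tmax.csv", "ppt.csv", "pet.csv", "ranges.csv",
                              "tree.nwk", "observations_raw.csv")),
              c(n_observations = nrow(world$observations),
                n_species = length(unique(world$ranges$species_id))))
  })

  if ("clean" %in% stages) run_stage("clean", {
    need("clean", path("observations_raw.csv"))
    obs <- readr::read_csv(path("observations_raw.csv"), show_col_types = FALSE)
    cleaned <- clean_observations(obs, metric = config$metric,
                                  mad_k = config$mad_k, n_min = config$n_min,
                                  site_decimals = config$site_decimals)
    readr::write_csv(cleaned$table, path("observations_clean.csv"))
    jsonlite::write_json(
      list(counts = as.list(cleaned$report$counts),
           n_input = cleaned$report$n_input, n_output = cleaned$report$n_output),
      path("cleaning_report.json"), auto_unbox = TRUE, digits = NA)
    log_stage("clean", path(c("observations_clean.csv", "cleaning_report.json")),
              c(n_input = cleaned$report$n_input,
                n_output = cleaned$report$n_output))
  })

  if ("limits" %in% stages) run_stage("limits", {
    need("limits", path(c("tmax.csv", "ppt.csv", "pet.csv", "ranges.csv")))
    tmax <- read_climate_cube(path("tmax.csv"))
    ai <- compute_ai(read_climate_cube(path("ppt.csv")),
                     read_climate_cube(path("pet.csv")))
    ranges <- read_range_masks(path("ranges.csv"))
    limits <- dplyr::bind_rows(
      derive_limits(tmax, ranges, config$world$baseline_years),
      derive_limits(ai, ranges, config$world$baseline_years))
    readr::write_csv(limits, path("limits.csv"))
    log_stage("limits", path("limits.csv"),
              c(n_rows = nrow(limits),
                ai_fence_rate = fencing_adjustment_rate(limits)))
  })

  if ("covariates" %in% stages) run_stage("covariates", {
    need("covariates", path(c("observations_clean.csv", "limits.csv",
                              "tmax.csv", "ppt.csv", "pet.csv",
                              "cropland.csv", "pasture.csv", "urban.csv",
                              "realm.csv")))
    obs <- readr::read_csv(path("observations_clean.csv"), show_col_types = FALSE)
    limits <- readr::read_csv(path("limits.csv"), show_col_types = FALSE)
    tmax <- read_climate_cube(path("tmax.csv"))
    ai <- compute_ai(read_climate_cube(path("ppt.csv")),
                     read_climate_cube(path("pet.csv")))
    obs <- attach_climate_indices(obs, tmax_cube = tmax, ai_cube = ai,
                                  limits = limits)
    obs <- attach_landuse(obs, read_climate_cube(path("cropland.csv")),
                          read_climate_cube(path("pasture.csv")),
                          read_climate_cube(path("urban.csv")))
    obs <- attach_realm(obs, read_climate_cube(path("realm.csv")))
    readr::write_csv(obs, path("observations_model.csv"))
    log_stage("covariates", path("observations_model.csv"),
              c(n_rows = nrow(obs),
                n_missing_index = attr(obs, "n_missing_index")))
  })

  fit <- NULL
  if ("fit" %in% stages) run_stage("fit", {
    need("fit", path(c("observations_model.csv", "tree.nwk")))
    obs <- readr::read_csv(path("observations_model.csv"), show_col_types = FALSE)
    tree <- read_tree(path("tree.nwk"))
    response <- switch(config$metric, mass = "log10_mass",
                       length = "log10_length", config$metric)
    spec <- pglmm_spec(response = response,
                       include_year = config$include_year,
                       slopes = config$slopes)
    C <- phylo_correlation(tree, sort(unique(obs$species_id)))
    design <- assemble(obs, spec, C)
    fit <- fit_pglmm(design)
    readr::write_csv(fit$coefficients, path("fit_coefficients.csv"))
    readr::write_csv(fit$varcomp, path("fit_varcomp.csv"))
    readr::write_csv(tibble::tibble(fitted = fit$fitted,
                                    residual = fit$residuals),
                     path("fit_residuals.csv"))
    jsonlite::write_json(
      list(loglik = fit$loglik, sigma2 = fit$sigma2,
           partial_r2 = partial_r2(fit), n = length(fit$y),
           n_dropped = fit$design$n_dropped),
      path("fit_summary.json"), auto_unbox = TRUE, digits = NA)
    log_stage("fit", path(c("fit_coefficients.csv", "fit_varcomp.csv",
                            "fit_residuals.csv", "fit_summary.json")),
              c(n_rows = length(fit$y), n_dropped = fit$design$n_dropped))
  })

  if ("diagnose" %in% stages) run_stage("diagnose", {
    if (is.null(fit)) stop("the 'fit' stage must run in the same call", call. = FALSE)
    report <- diagnose(fit, seed = config$seed, dw_iter = config$dw_iter,
                       ppc_sim = config$ppc_sim, boot = config$boot)
    jsonlite::write_json(
      list(vif = as.list(report$vif),
           dw_fraction_nonsignificant = report$dw_global$fraction_nonsignificant,
           influence_fraction = report$influence$fraction,
           ppc_coverage = mean(report$ppc$coverage)),
      path("diagnostics.json"), auto_unbox = TRUE, digits = NA)
    log_stage("diagnose", path("diagnostics.json"),
              c(n_flagged = length(report$influence$flagged)))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
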