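#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent nested list.  The
#' configuration describes the whole simulate - extract - fit - predict -
#' evaluate - randomize run: landscape geometry, conservation-network
#' sizes, survey design, per-species true parameters, model structure,
#' randomization settings and the master seed.
#'
#' @param config path to a YAML file, or a list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("seed", "landscape", "network", "survey", "model",
                "species", "rtr", "scenarios")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L)
    stop("pipeline configuration invalid: missing block(s) ",
         paste(missing, collapse = ", "))
  if (length(config$species) == 0L)
    stop("pipeline configuration invalid: empty species block")
  for (sp in config$species) {
    if (is.null(sp$name) || is.null(sp$beta_abund) || is.null(sp$beta_det))
      stop("pipeline configuration invalid: each species needs ",
           "name, beta_abund and beta_det")
    if (!"intercept" %in% names(sp$beta_abund))
      stop("pipeline configuration invalid: species '", sp$name,
           "' beta_abund lacks an intercept")
  }
  bad <- setdiff(unlist(config$scenarios),
                 c("focal_vs_state", "gbca_vs_state", "gbca_vs_focal"))
  if (length(bad) > 0L)
    stop("pipeline configuration invalid: unknown scenario(s) ",
         paste(bad, collapse = ", "))
  config$targets <- config$targets %||% c(0.20, 0.10)
  config$validation <- utils::modifyList(
    list(gof_nboot = 30L, auc_reps = 5L, crossval = TRUE, moran = FALSE),
    config$validation %||% list())
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# landscape_config from the config block
config_landscape <- function(config) {
  lc <- config$landscape
  landscape_config(
    extent = unlist(lc$extent),
    fine_cellsize = lc$fine_cellsize %||% 100,
    coarse_cellsize = lc$coarse_cellsize %||% 1000,
    class_fractions = unlist(lc$class_fractions),
    autocorrelation_range = lc$autocorrelation_range %||% 1500,
    seed = config$seed
  )
}

config_model_spec <- function(config, abund) {
  m <- config$model
  if (missing(abund)) abund <- unlist(m$abund)
  removal_model_spec(
    abund = abund,
    det = unlist(m$det %||% "jdate"),
    offset_area_km2 = m$offset_area_km2 %||% (pi * 0.1^2),
    J = m$J %||% 5L
  )
}

#' Run the full evaluation pipeline
#'
#' Executes simulate, extract, fit, predict, evaluate and randomize stages
#' from a single configuration, writing per-stage CSV artifacts and a JSON
#' summary to `out_dir`.  Fully reproducible from (config, seed): all
#' randomness flows through seed streams derived from the master seed.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param out_dir output directory (created if needed); NULL skips all
#'   file output.
#' @param seed optional master-seed override.
#' @return A list of class `pipeline_result`: fitted models, density
#'   surfaces, conservation network, suitability mask, baseline /
#'   percent-of-population / minimum-set tables, scenario results, and a
#'   `summary` list.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  ## stage: simulate ------------------------------------------------------
  lconf <- config_landscape(config)
  landcover <- generate_landcover(lconf)
  climate <- generate_climate(lconf)
  net <- config$network
  network <- generate_conservation_network(
    lconf, landcover,
    n_focal = net$n_focal %||% 3L,
    gbcas_per_focal = net$gbcas_per_focal %||% 3L,
    focal_area_km2 = net$focal_area_km2 %||% 150,
    gbca_area_km2 = net$gbca_area_km2 %||% 12
  )
  sites <- generate_survey_sites(
    lconf, n_sites = config$survey$n_sites,
    season = unlist(config$survey$season %||% c(140L, 190L))
  )
  emit(sites, "sites.csv")

  ## stage: extract -------------------------------------------------------
  site_cov_raw <- site_buffer_covariates(sites, landcover, climate,
                                         radius_m = config$survey$buffer_radius_m %||% 100)
  std <- standardize(site_cov_raw)
  site_cov <- std$values
  scaling <- std$params
  grid_raw <- grid_cell_covariates(landcover, climate,
                                   coarse_cellsize = lconf$coarse_cellsize)
  grid_std <- standardize(grid_raw, params = scaling,
                          cols = intersect(names(scaling$mean),
                                           names(grid_raw)))$values
  mask <- build_suitability_mask(grid_raw)
  emit(site_cov_raw, "site_covariates.csv")
  emit(grid_raw, "grid_covariates.csv")
  if (!is.null(out_dir))
    write_footprint_csv(network, file.path(out_dir, "network.csv"))

  ## stages: counts, fit, predict, validate ------------------------------
  models <- list(); surfaces <- list(); counts_all <- list()
  validation <- list(); model_rows <- list()
  for (sp in config$species) {
    spec <- if (is.null(sp$abund)) config_model_spec(config)
            else config_model_spec(config,
                                   abund = as.character(unlist(sp$abund)))
    params <- true_parameters(unlist(sp$beta_abund), unlist(sp$beta_det),
                              J = spec$J)
    counts <- simulate_point_counts(
      sites, site_cov, params,
      offset_area_km2 = spec$offset_area_km2,
      seed = child_seed(config$seed, paste0("counts-", sp$name))
    )
    counts_all[[sp$name]] <- counts
    emit(counts, paste0("counts_", sp$name, ".csv"))
    fit <- fit_removal(counts, site_cov, spec, scaling = scaling)
    gof <- gof_parametric_bootstrap(
      fit, nboot = config$validation$gof_nboot,
      seed = child_seed(config$seed, paste0("gof-", sp$name)))
    fit <- overdispersion_adjust(fit, gof$chat)
    val <- list(gof_p = gof$p_value, chat = fit$chat)
    val$spearman <- spearman_obs_pred(fit)$rho
    if (config$validation$auc_reps > 0L) {
      auc <- tryCatch(
        auc_holdout(counts, site_cov, spec,
                    reps = config$validation$auc_reps,
                    seed = child_seed(config$seed, paste0("auc-", sp$name))),
        error = function(e) list(mean_auc = NA_real_))
      val$mean_auc <- auc$mean_auc
    }
    if (isTRUE(config$validation$crossval)) {
      cv <- crossval_holdout(counts, site_cov, spec,
                             seed = child_seed(config$seed,
                                               paste0("cv-", sp$name)))
      val$rmse <- cv$rmse; val$mae <- cv$mae
    }
    if (isTRUE(config$validation$moran)) {
      mor <- residual_moran_correlogram(
        fit, sites, seed = child_seed(config$seed, paste0("moran-", sp$name)))
      val$no_autocorrelation <- mor$no_autocorrelation
    }
    models[[sp$name]] <- fit
    validation[[sp$name]] <- val
    surfaces[[sp$name]] <- predict_surface(fit, grid_std,
                                           species = sp$name)
    if (!is.null(out_dir))
      write_surface_csv(surfaces[[sp$name]],
                        file.path(out_dir, paste0("surface_", sp$name, ".csv")))
    model_rows[[sp$name]] <- data.frame(
      species = sp$name, parameter = names(fit$se),
      estimate = c(fit$beta_abund, fit$beta_det), se = fit$se,
      converged = fit$converged, chat = fit$chat, row.names = NULL)
  }
  emit(do.call(rbind, model_rows), "model_summary.csv")

  ## stage: evaluate ------------------------------------------------------
  focal_fps <- lapply(network$landscapes, function(fl) fl$footprint)
  baseline_rows <- list(); pct_rows <- list(); minset_rows <- list()
  for (sp in names(surfaces)) {
    sf <- surfaces[[sp]]
    for (fl in network$landscapes) {
      b <- baseline_density(sf, fl$footprint, buffer_m = 500)
      baseline_rows[[length(baseline_rows) + 1L]] <- data.frame(
        species = sp, area = fl$name, mean_density = b$mean_density,
        n_cells = b$n_cells)
    }
    baseline_rows[[length(baseline_rows) + 1L]] <- data.frame(
      species = sp, area = "state",
      mean_density = mean(sf$point, na.rm = TRUE),
      n_cells = sum(!is.na(sf$point)))
    pct <- percent_statewide(sf, focal_fps, targets = unlist(config$targets))
    pct$species <- sp
    pct_rows[[length(pct_rows) + 1L]] <- pct
    ms <- minimum_set(sf, target_frac = config$targets[[1]])
    minset_rows[[length(minset_rows) + 1L]] <- data.frame(
      species = sp, n_cells = ms$n_cells,
      achieved_frac = ms$achieved_frac,
      network_cells = sum(vapply(focal_fps, function(f) nrow(f$cells), 0L)))
  }
  baselines <- do.call(rbind, baseline_rows)
  percent <- do.call(rbind, pct_rows)
  minsets <- do.call(rbind, minset_rows)
  emit(baselines, "baselines.csv")
  emit(percent, "percent_statewide.csv")
  emit(minsets, "minimum_set.csv")

  ## stage: randomize -----------------------------------------------------
  scen_results <- list()
  for (sc in unlist(config$scenarios)) {
    scen_results[[sc]] <- run_scenario(
      sc, network, surfaces, mask,
      n_replicates = config$rtr$n_replicates %||% 1000L,
      quantile = config$rtr$quantile %||% 0.90,
      unsuit_frac = config$rtr$unsuit_frac %||% 0.20,
      seed = child_seed(config$seed, paste0("scenario-", sc))
    )
  }
  scen_df <- do.call(rbind, lapply(scen_results, function(s) s$results))
  emit(scen_df, "scenario_results.csv")

  summary <- list(
    seed = config$seed,
    n_sites = nrow(sites),
    species = names(models),
    converged = vapply(models, function(m) m$converged, TRUE),
    chat = vapply(models, function(m) m$chat, 0),
    validation = validation,
    percent_statewide_point = stats::setNames(
      percent$percent[percent$layer == "point"],
      percent$species[percent$layer == "point"]),
    minimum_set_cells = stats::setNames(minsets$n_cells, minsets$species),
    representation_counts = lapply(scen_results, function(s) s$counts)
  )
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(config = config, landcover = landcover, climate = climate,
                 network = network, sites = sites, mask = mask,
                 site_covariates = site_cov, scaling = scaling,
                 grid_covariates = grid_raw, counts = counts_all,
                 models = models, surfaces = surfaces,
                 baselines = baselines, percent = percent,
                 minimum_sets = minsets, scenarios = scen_results,
                 summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", length(x$models), "species,",
      nrow(x$sites), "sites, seed", x$config$seed, "\n")
  for (sp in names(x$models))
    cat(sprintf("  %s: converged=%s c-hat=%.2f pct-of-state=%.1f%% min-set=%d cells\n",
                sp, x$models[[sp]]$converged, x$models[[sp]]$chat,
                x$summary$percent_statewide_point[[sp]],
                x$summary$minimum_set_cells[[sp]]))
  for (sc in names(x$scenarios)) print(x$scenarios[[sc]])
  invisible(x)
}

#' Path to the bundled demo configuration
#'
#' A small, fully synthetic two-species study (one grassland-concentrated
#' species, one spatially uniform species) on a 60 x 60 km landscape.
#'
#' @return File path of the demo YAML configuration.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "grasslandRTR",
              mustWork = TRUE)
}
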