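#' Staged file-based pipeline
#'
#' The analysis is orchestrated as stages decoupled through files under one
#' run directory, so any stage can be re-run alone: `simulate` writes the
#' synthetic inputs, `change` the area series and stable/maximum extents,
#' `awd` the water-depth grids, `constraints` the frequency curves and
#' Gaussian fits, `grd` the grey-incidence table and ranking, and `report`
#' a collated JSON summary. Every stage writes a machine-readable manifest
#' (inputs with checksums, parameters, package version). All analysis
#' stages are deterministic; randomness exists only in `simulate`.
#'
#' @param dir run directory.
#' @param config a [basin_config()] for the simulate stage.
#' @param params named list of stage parameters; recognised entries:
#'   `bin_width_elevation` (m, default 50), `bin_width_slope` (deg, 1),
#'   `bin_width_precipitation` (mm, 10), `bin_width_awd` (mm, 25),
#'   `bin_width_temperature` (degC, 0.5), `flat_threshold` (deg, 0.01),
#'   `awd_threshold` (mm, 400), `rho` (0.5), `normalization` ("mean"),
#'   `variant` ("deng"), `aggregation` ("mean").
#' @return the stage's output directory, invisibly.
#' @name pipeline
NULL

default_params <- function(params = list()) {
  utils::modifyList(list(
    bin_width_elevation = 50, bin_width_slope = 1,
    bin_width_precipitation = 10, bin_width_awd = 25,
    bin_width_temperature = 0.5, flat_threshold = 0.01,
    awd_threshold = 400, rho = 0.5, normalization = "mean",
    variant = "deng", aggregation = "mean"), params)
}

#' Read a pipeline run configuration file
#'
#' YAML file with optional sections `basin` (arguments to [basin_config()])
#' and `params` (stage parameters, see [pipeline]).
#'
#' @param path YAML file.
#' @return list with elements `config` (a `basin_config`) and `params`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  cfg <- do.call(basin_config, if (is.null(y$basin)) list() else y$basin)
  list(config = cfg, params = default_params(
    if (is.null(y$params)) list() else y$params))
}

write_manifest <- function(stage_dir, stage, inputs, params) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("oasisdyn")),
    parameters = params,
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(man, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact %s; run %s first",
                 path, producer), call. = FALSE)
  }
  path
}

mask_paths <- function(dir) {
  ins <- file.path(dir, "inputs")
  ff <- list.files(ins, pattern = "^oasis_[0-9]+\\.asc$", full.names = TRUE)
  if (!length(ff)) {
    stop(sprintf("no oasis masks under %s; run pipeline_simulate first",
                 ins), call. = FALSE)
  }
  yrs <- as.integer(sub("^oasis_([0-9]+)\\.asc$", "\\1", basename(ff)))
  ff[order(yrs)]
}

read_series <- function(dir) {
  ff <- mask_paths(dir)
  yrs <- as.integer(sub("^oasis_([0-9]+)\\.asc$", "\\1", basename(ff)))
  oasis_series(lapply(ff, read_raster, expected_kind = "mask"), sort(yrs))
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(dir, config = basin_config()) {
  ins <- file.path(dir, "inputs")
  dir.create(ins, recursive = TRUE, showWarnings = FALSE)
  basin <- generate_basin(config)
  for (nm in names(basin$stack$layers)) {
    write_raster(basin$stack$layers[[nm]], file.path(ins, paste0(nm, ".asc")))
  }
  for (i in seq_along(basin$series$years)) {
    yr <- basin$series$years[i]
    write_raster(basin$series$masks[[i]],
                 file.path(ins, sprintf("oasis_%d.asc", yr)))
    write_raster(basin$p_by_year[[as.character(yr)]],
                 file.path(ins, sprintf("precip_%d.asc", yr)))
  }
  utils::write.table(basin$runoff, file.path(ins, "runoff.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_panel(basin$panel, file.path(ins, "panel.csv"))
  write_raster(raster_grid(basin$truth$stable_core,
                           basin$stack$geometry$cell_size,
                           basin$stack$geometry$origin,
                           basin$stack$geometry$crs),
               file.path(ins, "truth_stable_core.asc"))
  jsonlite::write_json(
    basin$truth[c("mu_star", "sigma_star", "fringe_mu", "fringe_sigma",
                  "slope_max", "awd_min", "intended_grouping")],
    file.path(ins, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  write_manifest(ins, "simulate", character(0),
                 list(seed = config$seed, shape = config$shape,
                      years = config$years))
  invisible(ins)
}

#' @rdname pipeline
#' @export
pipeline_change <- function(dir, params = list()) {
  params <- default_params(params)
  out <- file.path(dir, "change")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  series <- read_series(dir)
  zones_p <- require_artifact(file.path(dir, "inputs", "basins.asc"),
                              "pipeline_simulate")
  zones <- read_raster(zones_p, "zone")
  areas <- area_series(series, zones)
  utils::write.table(areas, file.path(out, "area_series.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  tot <- areas[areas$zone == "total", ]
  cm <- change_metrics(tot$area_km2[1L], tot$area_km2[nrow(tot)],
                       diff(range(series$years)) + 1L)
  utils::write.table(
    data.frame(from_year = series$years[1L],
               to_year = series$years[length(series$years)],
               percent_change = cm$percent_change, factor = cm$factor,
               annual_increase_km2 = cm$annual_increase),
    file.path(out, "change_metrics.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  n <- length(series$years)
  cmap <- change_map(series$masks[[1L]], series$masks[[n]],
                     series$years[1L], series$years[n])
  write_raster(cmap$categories,
               file.path(out, sprintf("change_%d_%d.asc",
                                      series$years[1L], series$years[n])))
  write_raster(stable_oasis(series), file.path(out, "stable.asc"))
  write_raster(maximum_oasis(series), file.path(out, "maximum.asc"))
  write_manifest(out, "change", c(mask_paths(dir), zones_p), params["rho"])
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_awd <- function(dir, params = list()) {
  params <- default_params(params)
  out <- file.path(dir, "awd")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ins <- file.path(dir, "inputs")
  runoff_p <- require_artifact(file.path(ins, "runoff.csv"),
                               "pipeline_simulate")
  zones_p <- require_artifact(file.path(ins, "service_zones.asc"),
                              "pipeline_simulate")
  runoff <- utils::read.csv(runoff_p, stringsAsFactors = FALSE)
  zones <- read_raster(zones_p, "zone")
  series <- read_series(dir)
  p_by_year <- stats::setNames(lapply(series$years, function(yr) {
    p <- file.path(ins, sprintf("precip_%d.asc", yr))
    read_raster(require_artifact(p, "pipeline_simulate"))
  }), series$years)
  mean_awd <- awd_mean_grid(runoff, zones, series, p_by_year)
  write_raster(mean_awd, file.path(out, "awd_mean.asc"))
  counties <- read_raster(require_artifact(
    file.path(ins, "counties.asc"), "pipeline_simulate"), "zone")
  awd_panel <- regional_awd_series(runoff, zones, series, p_by_year,
                                   counties)
  write_panel(awd_panel, file.path(out, "awd_panel.csv"))
  write_manifest(out, "awd", c(runoff_p, zones_p, mask_paths(dir)),
                 list())
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_constraints <- function(dir, params = list()) {
  params <- default_params(params)
  out <- file.path(dir, "constraints")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ins <- file.path(dir, "inputs")
  series <- read_series(dir)
  dem <- read_raster(require_artifact(file.path(ins, "dem.asc"),
                                      "pipeline_simulate"))
  awd_p <- require_artifact(file.path(dir, "awd", "awd_mean.asc"),
                            "pipeline_awd")
  covs <- list(
    elevation = list(grid = dem, w = params$bin_width_elevation),
    precipitation = list(
      grid = read_raster(require_artifact(
        file.path(ins, "precipitation.asc"), "pipeline_simulate")),
      w = params$bin_width_precipitation),
    awd = list(grid = read_raster(awd_p), w = params$bin_width_awd),
    t_avg = list(grid = read_raster(require_artifact(
      file.path(ins, "t_avg.asc"), "pipeline_simulate")),
      w = params$bin_width_temperature))
  terr <- slope_aspect(dem, params$flat_threshold)
  covs$slope <- list(grid = terr$slope, w = params$bin_width_slope)

  s_mask <- stable_oasis(series)
  m_mask <- maximum_oasis(series)
  fit_rows <- list()
  freq_rows <- list()
  for (nm in names(covs)) {
    for (ext in c("stable", "maximum")) {
      mask <- if (ext == "stable") s_mask else m_mask
      fr <- distribution_frequency(mask, covs[[nm]]$grid, covs[[nm]]$w,
                                   covariate_name = nm)
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        covariate = nm, extent = ext, bin_center = fr$bin_centers,
        frequency = fr$frequencies, stringsAsFactors = FALSE)
      ft <- tryCatch(fit_normal(fr), error = function(e) NULL)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        covariate = nm, extent = ext,
        a = if (is.null(ft)) NA else ft$a,
        mu = if (is.null(ft)) NA else ft$mu,
        sigma = if (is.null(ft)) NA else ft$sigma,
        y0 = if (is.null(ft)) NA else ft$y0,
        r_squared = if (is.null(ft)) NA else ft$r_squared,
        p_value = if (is.null(ft)) NA else ft$p_value,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, freq_rows),
                     file.path(out, "frequency_tables.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, fit_rows),
                     file.path(out, "normal_fits.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  # aspect shares among sloped oasis cells
  acl <- aspect_classes(terr$aspect)
  asp_rows <- lapply(c(stable = "stable", maximum = "maximum"),
                     function(ext) {
    mask <- if (ext == "stable") s_mask else m_mask
    cf <- categorical_frequency(mask, acl, exclude = 0,
                                labels = aspect_class_labels())
    flat <- categorical_frequency(mask, acl,
                                  labels = aspect_class_labels())
    flat_share <- if (any(flat$levels == 0)) {
      flat$frequencies[flat$levels == 0]
    } else 0
    data.frame(extent = ext, class = cf$labels, share = cf$frequencies,
               flat_share_all = flat_share, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, asp_rows),
                     file.path(out, "aspect_shares.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  support <- data.frame(
    extent = c("stable", "maximum"),
    threshold_mm = params$awd_threshold,
    support = c(
      threshold_support(s_mask, covs$awd$grid, params$awd_threshold, "ge"),
      threshold_support(m_mask, covs$awd$grid, params$awd_threshold, "ge")))
  utils::write.table(support, file.path(out, "awd_support.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_manifest(out, "constraints",
                 c(file.path(ins, "dem.asc"), awd_p, mask_paths(dir)),
                 params)
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_grd <- function(dir, params = list()) {
  params <- default_params(params)
  out <- file.path(dir, "grd")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  panel_p <- require_artifact(file.path(dir, "inputs", "panel.csv"),
                              "pipeline_simulate")
  panel <- read_panel(panel_p)
  m <- panel_grd(panel, rho = params$rho,
                 normalization = params$normalization,
                 variant = params$variant)
  full <- data.frame(region = rownames(m), round(unclass(m), 10),
                     check.names = FALSE)
  disp <- data.frame(region = rownames(m), round(unclass(m), 2),
                     check.names = FALSE)
  utils::write.table(full, file.path(out, "grd_matrix_full.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(disp, file.path(out, "grd_matrix.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  rk <- rank_factors(m, params$aggregation)
  utils::write.table(rk, file.path(out, "factor_ranking.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_manifest(out, "grd", panel_p,
                 params[c("rho", "normalization", "variant", "aggregation")])
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(dir, params = list()) {
  params <- default_params(params)
  out <- file.path(dir, "report")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  areas <- utils::read.csv(require_artifact(
    file.path(dir, "change", "area_series.csv"), "pipeline_change"))
  cm <- utils::read.csv(require_artifact(
    file.path(dir, "change", "change_metrics.csv"), "pipeline_change"))
  fits <- utils::read.csv(require_artifact(
    file.path(dir, "constraints", "normal_fits.csv"),
    "pipeline_constraints"))
  support <- utils::read.csv(require_artifact(
    file.path(dir, "constraints", "awd_support.csv"),
    "pipeline_constraints"))
  rk <- utils::read.csv(require_artifact(
    file.path(dir, "grd", "factor_ranking.csv"), "pipeline_grd"))
  summary <- list(
    area_series = areas,
    change_metrics = as.list(cm[1L, ]),
    normal_fits = fits,
    awd_threshold_support = support,
    factor_ranking = rk)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out, "report", character(0), list())
  invisible(out)
}

#' Run the full pipeline end to end
#'
#' `simulate -> change -> awd -> constraints -> grd -> report` in one call.
#'
#' @param dir run directory.
#' @param config a [basin_config()].
#' @param params stage parameters (see [pipeline]).
#' @return the report directory, invisibly.
#' @export
run_pipeline <- function(dir, config = basin_config(), params = list()) {
  pipeline_simulate(dir, config)
  pipeline_change(dir, params)
  pipeline_awd(dir, params)
  pipeline_constraints(dir, params)
  pipeline_grd(dir, params)
  pipeline_report(dir, params)
}
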