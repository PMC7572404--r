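#' Configuration for the synthetic arid-basin generator
#'
#' Defaults describe a ~21.6 x 18 km inland basin at 90 m resolution: a
#' northern plain (1100-1900 m, linear gradient, so candidate cells sample
#' elevation uniformly and the elevation optimum sits 2.7 spreads from
#' either edge) rising into a southern mountain ridge; precipitation
#' increasing with elevation (desert plain well under 200 mm/yr);
#' temperature falling with a 6.5 degC/km lapse. Oasis suitability is
#' Gaussian in elevation (centre `mu_star` = 1500 m, spread `sigma_star` =
#' 150 m), restricted to slopes under `slope_max` = 6 deg, and sustained by
#' allocated runoff so that water depth stays above `awd_min` = 400 mm.
#' Seven periods span 1986-2015. Expansion is drawn at lower elevations
#' with a wider spread than the stable core (`fringe_mu`, `fringe_sigma`),
#' preferring cells adjacent to the existing oasis, so the union extent
#' peaks lower and spreads wider than the intersection — the qualitative
#' signature the constraint analysis must recover.
#'
#' @param shape grid rows and columns.
#' @param cell_size cell edge, metres.
#' @param years analysis years (>= 2, strictly increasing).
#' @param n_core number of stable-core cells.
#' @param fringe_frac total expansion, as a fraction of the core, arriving
#'   over periods 2..n.
#' @param retreat_frac fraction of core size present only in period 1.
#' @param mu_star,sigma_star elevation optimum and spread (m) of the core.
#' @param fringe_mu,fringe_sigma elevation optimum and spread (m) of
#'   expansion cells.
#' @param slope_max slope limit (degrees) for any oasis cell.
#' @param awd_min water-depth threshold (mm) the generator sustains on
#'   oasis cells.
#' @param adjacency_bonus multiplicative sampling bonus for candidate cells
#'   touching the current oasis.
#' @param target_depth_mm mean allocated runoff depth (mm) per station.
#' @param volume_noise_sd relative sd of yearly station volumes.
#' @param pop_noise_sd,laborer_noise_sd relative noise of the
#'   population-like panel series around proportionality to oasis area.
#' @param gdp_growth named growth factors per year for the GDP-like series.
#' @param gdp_noise_sd relative noise of the GDP-like series.
#' @param p_year_sd relative sd of the yearly precipitation multiplier.
#' @param n_basins,n_counties number of vertical-strip basins (= station
#'   service zones) and administrative regions.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `basin_config`.
#' @export
basin_config <- function(shape = c(240, 200), cell_size = 90,
                         years = c(1986, 1990, 1995, 2000, 2005, 2010, 2015),
                         n_core = 2500, fringe_frac = 0.45,
                         retreat_frac = 0.05,
                         mu_star = 1500, sigma_star = 150,
                         fringe_mu = 1440, fringe_sigma = 195,
                         slope_max = 6, awd_min = 400,
                         adjacency_bonus = 3,
                         target_depth_mm = 600, volume_noise_sd = 0.05,
                         pop_noise_sd = 0.02, laborer_noise_sd = 0.015,
                         gdp_growth = c(GDP = 1.07, GDP_primary = 1.045,
                                        GDP_secondary = 1.10,
                                        GDP_tertiary = 1.085),
                         gdp_noise_sd = 0.04, p_year_sd = 0.05,
                         n_basins = 3, n_counties = 6,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$years) < 2L || any(diff(cfg$years) <= 0)) {
    stop("years must be >= 2 and strictly increasing", call. = FALSE)
  }
  stopifnot(cfg$n_core >= 1, cfg$fringe_frac >= 0, cfg$retreat_frac >= 0,
            cfg$sigma_star > 0, cfg$fringe_sigma > 0,
            cfg$volume_noise_sd >= 0, cfg$pop_noise_sd >= 0)
  class(cfg) <- "basin_config"
  cfg
}

# vertical-strip label raster: columns split into n roughly equal bands
strip_zones <- function(nr, nc, n, cell_size, origin, crs) {
  lab <- matrix(rep(ceiling(seq_len(nc) / (nc / n)), each = nr), nr, nc)
  lab[lab > n] <- n
  raster_grid(lab, cell_size, origin, crs)
}

# TRUE where a candidate cell touches (8-neighbourhood) the current mask
touches_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  acc > 0
}

#' Generate a synthetic arid basin with known ground truth
#'
#' Produces co-registered rasters (DEM, mean precipitation, mean/min/max
#' temperature, basin / county / station service-zone labels), a
#' seven-period oasis mask series with a known stable core, gauged runoff
#' records at one "mountain pass" station per basin, yearly precipitation
#' layers, and a county-level driver panel (population, labour, GDP
#' components, per-capita GDP, precipitation, AWD, oasis area) whose
#' grey-incidence ordering is configured: population-like series track
#' oasis area tightly, AWD moderately, GDP-like series follow their own
#' exponential growth. The AWD panel column is computed through the real
#' allocation pipeline ([regional_awd_series()]) from the generated runoff.
#'
#' @param config a [basin_config()].
#' @return list: `stack` (a `grid_stack`), `series` (an [oasis_series()]),
#'   `runoff` (records data.frame), `p_by_year` (list of precipitation
#'   `raster_grid`s named by year), `panel` (a `panel_table`), and `truth`
#'   (stable-core matrix, `mu_star`, `sigma_star`, `slope_max`, `awd_min`,
#'   intended factor grouping).
#' @export
generate_basin <- function(config = basin_config()) {
  stopifnot(inherits(config, "basin_config"))
  set.seed(config$seed)
  nr <- config$shape[1]; nc <- config$shape[2]
  cs <- config$cell_size
  origin <- c(0, nr * cs)
  crs <- "synthetic-equal-area"
  years <- config$years
  np <- length(years)

  # --- terrain: linear plain in the north, quadratic ridge in the south
  plain_frac <- 0.6
  plain_lo <- 1100; plain_hi <- 1900; ridge <- 4200
  t_row <- (seq_len(nr) - 1) / (nr - 1)
  z_row <- ifelse(t_row <= plain_frac,
                  plain_lo + (plain_hi - plain_lo) * t_row / plain_frac,
                  plain_hi + (ridge - plain_hi) *
                    ((t_row - plain_frac) / (1 - plain_frac))^2)
  z <- matrix(z_row, nr, nc) + matrix(stats::rnorm(nr * nc, 0, 4), nr, nc)
  dem <- raster_grid(z, cs, origin, crs)

  # --- climate: orographic precipitation, lapse-rate temperatures
  P_mean <- raster_grid(40 + 0.09 * (z - 1000) +
                          matrix(stats::rnorm(nr * nc, 0, 3), nr, nc),
                        cs, origin, crs)
  t_avg <- raster_grid(17.8 - 0.0065 * z +
                         matrix(stats::rnorm(nr * nc, 0, 0.2), nr, nc),
                       cs, origin, crs)
  t_min <- raster_grid(t_avg$values - 17, cs, origin, crs)
  t_max <- raster_grid(t_avg$values + 14, cs, origin, crs)

  # --- zones: basins double as station service zones; counties refine them
  basins <- strip_zones(nr, nc, config$n_basins, cs, origin, crs)
  counties <- strip_zones(nr, nc, config$n_counties, cs, origin, crs)

  # --- suitability and the oasis series
  terr <- slope_aspect(dem)
  slope_ok <- !is.na(terr$slope$values) &
    terr$slope$values < config$slope_max
  w_core <- exp(-(z - config$mu_star)^2 / (2 * config$sigma_star^2))
  w_fringe <- exp(-(z - config$fringe_mu)^2 / (2 * config$fringe_sigma^2))
  cand <- which(slope_ok & w_core > 1e-6)
  if (length(cand) < config$n_core) {
    stop("config yields too few suitable cells for the stable core",
         call. = FALSE)
  }
  core_idx <- sample(cand, config$n_core, prob = w_core[cand])
  core <- matrix(0, nr, nc); core[core_idx] <- 1

  n_fringe <- round(config$fringe_frac * config$n_core)
  n_retreat <- round(config$retreat_frac * config$n_core)
  pool <- setdiff(which(slope_ok & w_fringe > 1e-6), core_idx)
  if (length(pool) < n_fringe + n_retreat) {
    stop("config yields too few suitable cells for expansion", call. = FALSE)
  }
  adj <- touches_mask(core)
  w_pool <- w_fringe[pool] * (1 + config$adjacency_bonus * adj[pool])
  picked <- sample(pool, n_fringe + n_retreat, prob = w_pool)
  retreat_idx <- picked[seq_len(n_retreat)]
  fringe_idx <- picked[-seq_len(n_retreat)]
  # arrival period of each fringe cell: evenly over periods 2..np
  arrival <- sort(rep_len(2:np, n_fringe))
  masks <- vector("list", np)
  for (p in seq_len(np)) {
    m <- core
    if (p == 1L) {
      m[retreat_idx] <- 1
    } else {
      m[fringe_idx[arrival <= p]] <- 1
    }
    masks[[p]] <- raster_grid(m, cs, origin, crs)
  }
  series <- oasis_series(masks, years)

  # --- runoff gauged at one mountain-pass station per basin; volumes sized
  #     to sustain ~target_depth_mm over each basin's oasis cells
  bz <- basins$values
  rec <- list()
  for (b in seq_len(config$n_basins)) {
    for (p in seq_len(np)) {
      n_cells <- sum(masks[[p]]$values[bz == b] == 1)
      vol <- n_cells * cs^2 * (config$target_depth_mm / 1000) *
        max(0.1, 1 + stats::rnorm(1, 0, config$volume_noise_sd))
      rec[[length(rec) + 1L]] <- data.frame(
        station_id = sprintf("S%d", b), year = years[p],
        volume_m3 = vol, zone_label = b, stringsAsFactors = FALSE)
    }
  }
  runoff <- do.call(rbind, rec)

  # --- yearly precipitation: shared field times a yearly multiplier
  p_mult <- 1 + stats::rnorm(np, 0, config$p_year_sd)
  p_mult <- pmax(0.5, p_mult)
  p_by_year <- stats::setNames(lapply(seq_len(np), function(p) {
    raster_grid(P_mean$values * p_mult[p], cs, origin, crs)
  }), years)

  # --- county panel
  cz <- counties$values
  region_names <- stats::setNames(sprintf("R%d", seq_len(config$n_counties)),
                                  seq_len(config$n_counties))
  cell_km2 <- cs^2 / 1e6
  rows <- list()
  gdp_base <- stats::setNames(
    stats::runif(length(config$gdp_growth), 50, 150),
    names(config$gdp_growth))
  for (ci in seq_len(config$n_counties)) {
    rn <- region_names[[as.character(ci)]]
    area0 <- NULL
    for (p in seq_len(np)) {
      yr <- years[p]
      area <- sum(masks[[p]]$values[cz == ci] == 1) * cell_km2
      if (p == 1L) area0 <- area
      add <- function(v, val) {
        rows[[length(rows) + 1L]] <<- data.frame(
          region = rn, year = yr, variable = v, value = val,
          stringsAsFactors = FALSE)
      }
      add("oasis_area", area)
      pop <- 300 * area * (1 + stats::rnorm(1, 0, config$pop_noise_sd))
      add("total_population", pop)
      add("rural_laborers",
          120 * area * (1 + stats::rnorm(1, 0, config$laborer_noise_sd)))
      gdp_vals <- numeric(0)
      for (g in names(config$gdp_growth)) {
        val <- gdp_base[[g]] * (area0 / 10) *
          config$gdp_growth[[g]]^(yr - years[1]) *
          (1 + stats::rnorm(1, 0, config$gdp_noise_sd))
        gdp_vals[[g]] <- val
        add(g, val)
      }
      add("per_capita_GDP", gdp_vals[["GDP"]] / pop)
      pm <- p_by_year[[as.character(yr)]]$values
      sel <- cz == ci & masks[[p]]$values == 1
      add("precipitation", mean(pm[sel]))
    }
  }
  panel <- do.call(rbind, rows)
  class(panel) <- c("panel_table", "data.frame")
  awd_panel <- regional_awd_series(runoff, basins, series, p_by_year,
                                   counties, region_names)
  panel <- rbind(panel, awd_panel)
  class(panel) <- c("panel_table", "data.frame")

  stack <- assemble_stack(list(
    dem = dem, precipitation = P_mean, t_avg = t_avg, t_min = t_min,
    t_max = t_max, basins = basins, counties = counties,
    service_zones = basins))

  truth <- list(
    stable_core = core,
    mu_star = config$mu_star, sigma_star = config$sigma_star,
    fringe_mu = config$fringe_mu, fringe_sigma = config$fringe_sigma,
    slope_max = config$slope_max, awd_min = config$awd_min,
    intended_grouping = list(
      population_like = c("rural_laborers", "total_population"),
      water = "AWD",
      gdp_like = names(config$gdp_growth)))

  list(stack = stack, series = series, runoff = runoff,
       p_by_year = p_by_year, panel = panel, truth = truth,
       config = config)
}

#' Miniature deterministic fixture
#'
#' An 8 x 8, three-period dataset with hand-checkable values: a 2 x 2
#' stable core, one cell present only in period 1 (retreat), two expansion
#' cells, one service zone whose period-1 runoff volume allocates to an
#' exact 500 mm depth over the 5 period-1 oasis cells, constant 100 mm
#' precipitation, and a one-region panel containing a `mirror` factor equal
#' to oasis area (grey relational degree exactly 1).
#'
#' @return list with the same elements as [generate_basin()] (minus
#'   `p_by_year` yearly structure: precipitation is a single grid).
#' @export
toy_fixture <- function() {
  cs <- 90
  nr <- 8L; nc <- 8L
  origin <- c(0, nr * cs)
  crs <- "synthetic-equal-area"
  years <- c(2000L, 2005L, 2010L)
  core <- matrix(0, nr, nc)
  core[3:4, 3:4] <- 1
  m1 <- core; m1[6, 6] <- 1               # retreat cell
  m2 <- core; m2[5, 3] <- 1               # first expansion
  m3 <- core; m3[5, 3] <- 1; m3[5, 4] <- 1
  masks <- lapply(list(m1, m2, m3), raster_grid,
                  cell_size = cs, origin = origin, crs = crs)
  series <- oasis_series(masks, years)

  dem <- raster_grid(matrix(1400 + 10 * seq_len(nr), nr, nc), cs, origin,
                     crs)
  P <- raster_grid(matrix(100, nr, nc), cs, origin, crs)
  zones <- raster_grid(matrix(1, nr, nc), cs, origin, crs)
  # 5 oasis cells in 2000: 0.5 m x 5 x 8100 m^2 = 20250 m^3 -> 500 mm
  runoff <- data.frame(
    station_id = "S1", year = years,
    volume_m3 = c(5, 5, 6) * cs^2 * 0.5,
    zone_label = 1, stringsAsFactors = FALSE)

  area <- vapply(masks, oasis_area, numeric(1))
  panel <- data.frame(
    region = "R1",
    year = rep(years, 2L),
    variable = rep(c("oasis_area", "mirror"), each = 3L),
    value = c(area, area), stringsAsFactors = FALSE)
  class(panel) <- c("panel_table", "data.frame")

  stack <- assemble_stack(list(dem = dem, precipitation = P,
                               service_zones = zones, counties = zones))
  list(stack = stack, series = series, runoff = runoff,
       precipitation = P, panel = panel,
       truth = list(stable_core = core))
}
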