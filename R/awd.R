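#' Allocate gauged runoff as a depth over the oasis cells of each service zone
#'
#' Each station's annual volume (m^3), gauged at the mountain pass, is
#' spread uniformly over the oasis cells of its service (irrigation) zone:
#' depth = volume / (n cells x cell area), converted to mm. Cells served by
#' several stations receive the sum; non-oasis cells get 0. The allocation
#' conserves volume: sum(depth x cell area) over allocated cells equals the
#' station volume.
#'
#' @param records `data.frame` with columns `station_id`, `year`,
#'   `volume_m3`, `zone_label` (non-negative volumes; `zone_label` links to
#'   `service_zones`).
#' @param service_zones zone label `raster_grid`.
#' @param oasis_mask binary oasis mask for the allocation year, same
#'   geometry.
#' @param year the analysis year; records are filtered to it.
#' @return available-runoff `raster_grid` in mm (0 outside oases; nodata
#'   where the mask is nodata).
#' @export
allocate_runoff <- function(records, service_zones, oasis_mask, year) {
  need <- c("station_id", "year", "volume_m3", "zone_label")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("runoff records missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  stopifnot(is_raster_grid(service_zones), is_raster_grid(oasis_mask))
  check_same_geometry(service_zones, oasis_mask, "zones", "mask")
  check_binary(oasis_mask)
  rec <- records[records$year == year, , drop = FALSE]
  if (!nrow(rec)) {
    stop(sprintf("no runoff records for year %d", year), call. = FALSE)
  }
  if (any(rec$volume_m3 < 0)) {
    stop("runoff volumes must be non-negative", call. = FALSE)
  }
  z <- service_zones$values
  m <- oasis_mask$values
  zone_labels <- unique(z[!is.na(z)])
  missing_zone <- setdiff(unique(rec$zone_label), zone_labels)
  if (length(missing_zone)) {
    stop(sprintf("service zone label(s) not present in the zone raster: %s",
                 paste(missing_zone, collapse = ", ")), call. = FALSE)
  }
  R <- matrix(0, nrow(m), ncol(m))
  R[is.na(m)] <- NA_real_
  cell_m2 <- oasis_mask$cell_size^2
  unallocatable <- character(0)
  for (i in seq_len(nrow(rec))) {
    sel <- !is.na(z) & !is.na(m) & z == rec$zone_label[i] & m == 1
    n_cells <- sum(sel)
    if (n_cells == 0L) {
      if (rec$volume_m3[i] > 0) {
        unallocatable <- c(unallocatable, as.character(rec$station_id[i]))
      }
      next
    }
    depth_mm <- rec$volume_m3[i] / (n_cells * cell_m2) * 1000
    R[sel] <- R[sel] + depth_mm
  }
  if (length(unallocatable)) {
    stop(sprintf(
      "station(s) with positive volume but no oasis cells in their service zone: %s",
      paste(unallocatable, collapse = ", ")), call. = FALSE)
  }
  raster_grid(R, oasis_mask$cell_size, oasis_mask$origin, oasis_mask$crs)
}

#' Accessibility water depth grid
#'
#' The per-cell water index AWD = R + P (mm): allocated upstream runoff
#' depth plus precipitation depth. Nodata propagates.
#'
#' @param R available-runoff `raster_grid` in mm (from [allocate_runoff()]).
#' @param P precipitation `raster_grid` in mm, same geometry.
#' @return AWD `raster_grid` in mm.
#' @export
awd_grid <- function(R, P) {
  stopifnot(is_raster_grid(R), is_raster_grid(P))
  check_same_geometry(R, P, "R", "P")
  raster_grid(R$values + P$values, R$cell_size, R$origin, R$crs)
}

#' Multi-year mean AWD grid
#'
#' Allocates each analysis year's runoff over that year's oasis mask, adds
#' that year's precipitation, and averages the resulting AWD grids across
#' years. This is the water layer used by the stable/maximum constraint
#' analysis, where no single year is privileged.
#'
#' @param records runoff records (see [allocate_runoff()]).
#' @param service_zones zone label `raster_grid`.
#' @param series an [oasis_series()].
#' @param P_by_year a single precipitation `raster_grid` used for all years,
#'   or a list named by year.
#' @return mean AWD `raster_grid` in mm.
#' @export
awd_mean_grid <- function(records, service_zones, series, P_by_year) {
  stopifnot(inherits(series, "oasis_series"))
  acc <- NULL
  for (i in seq_along(series$years)) {
    yr <- series$years[i]
    P <- if (is_raster_grid(P_by_year)) P_by_year
         else P_by_year[[as.character(yr)]]
    if (is.null(P)) stop(sprintf("no precipitation layer for year %d", yr),
                         call. = FALSE)
    R <- allocate_runoff(records, service_zones, series$masks[[i]], yr)
    A <- awd_grid(R, P)
    acc <- if (is.null(acc)) A$values else acc + A$values
  }
  ref <- series$masks[[1L]]
  raster_grid(acc / length(series$years), ref$cell_size, ref$origin,
              ref$crs)
}

#' Regional AWD panel series
#'
#' For each administrative region and analysis year, the mean AWD over that
#' region's oasis cells — the AWD column of the driving-force panel.
#' Regions without oasis cells in a year are flagged with `NA` and a
#' warning rather than dropped.
#'
#' @param records runoff records (see [allocate_runoff()]).
#' @param service_zones station service-zone `raster_grid`.
#' @param series an [oasis_series()].
#' @param P_by_year precipitation: one `raster_grid` or a list named by year.
#' @param admin_zones administrative-region label `raster_grid`.
#' @param region_names optional named character vector mapping zone labels
#'   to region names; defaults to the label numbers.
#' @return a `panel_table` with `variable = "AWD"` rows (value in mm).
#' @export
regional_awd_series <- function(records, service_zones, series, P_by_year,
                                admin_zones, region_names = NULL) {
  stopifnot(is_raster_grid(admin_zones))
  check_same_geometry(series$masks[[1L]], admin_zones, "mask", "admin zones")
  zv <- admin_zones$values
  labs <- sort(unique(zv[!is.na(zv)]))
  rows <- list()
  for (i in seq_along(series$years)) {
    yr <- series$years[i]
    P <- if (is_raster_grid(P_by_year)) P_by_year
         else P_by_year[[as.character(yr)]]
    if (is.null(P)) stop(sprintf("no precipitation layer for year %d", yr),
                         call. = FALSE)
    R <- allocate_runoff(records, service_zones, series$masks[[i]], yr)
    A <- awd_grid(R, P)$values
    m <- series$masks[[i]]$values
    for (l in labs) {
      sel <- !is.na(zv) & !is.na(m) & zv == l & m == 1 & !is.na(A)
      nm <- if (!is.null(region_names)) region_names[[as.character(l)]]
            else as.character(as.integer(l))
      if (!any(sel)) {
        warning(sprintf("region %s has no oasis cells in %d; AWD is NA",
                        nm, yr), call. = FALSE)
        val <- NA_real_
      } else {
        val <- mean(A[sel])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = nm, year = yr, variable = "AWD", value = val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("panel_table", "data.frame")
  out
}
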