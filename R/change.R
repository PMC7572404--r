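#' Oasis area of a binary mask
#'
#' Area in square kilometres: count of oasis (value 1) cells times the cell
#' area. Nodata cells are excluded.
#'
#' @param mask binary `raster_grid` (1 = oasis, 0 = desert).
#' @return area in km^2.
#' @export
oasis_area <- function(mask) {
  stopifnot(is_raster_grid(mask))
  check_binary(mask)
  n1 <- sum(mask$values == 1, na.rm = TRUE)
  n1 * mask$cell_size^2 / 1e6
}

#' Endpoint change metrics
#'
#' Percent change, increase factor and mean annual increase between a start
#' and an end area (or any positive quantity, e.g. population).
#'
#' @param area_start,area_end start and end values; `area_start` must be > 0.
#' @param n_years number of years spanned; default 30, the inclusive span of
#'   a 1986-2015 record.
#' @return list with `percent_change` (%), `factor` (end/start) and
#'   `annual_increase` (units per year).
#' @examples
#' change_metrics(10707.7, 14950.1)  # ~39.6 %, factor ~1.4, ~141 km^2/yr
#' @export
change_metrics <- function(area_start, area_end, n_years = 30) {
  if (!is.numeric(area_start) || area_start <= 0) {
    stop("area_start must be positive", call. = FALSE)
  }
  if (!is.numeric(n_years) || n_years <= 0) {
    stop("n_years must be positive", call. = FALSE)
  }
  list(
    percent_change = 100 * (area_end - area_start) / area_start,
    factor = area_end / area_start,
    annual_increase = (area_end - area_start) / n_years
  )
}

#' Per-cell change map between two periods
#'
#' Labels each cell by its binary transition: 0 stable desert (0 to 0),
#' 1 expansion (0 to 1), 2 retreat (1 to 0), 3 stable oasis (1 to 1).
#' Nodata in either input propagates. By construction the stable-oasis count
#' plus expansions equals the end-period oasis count, and plus retreats the
#' start-period count.
#'
#' @param mask_from,mask_to binary masks on the same geometry.
#' @param from_year,to_year optional year labels attached to the result.
#' @return list of class `change_map`: `categories` (a `raster_grid` with
#'   labels 0-3), `from_year`, `to_year`.
#' @export
change_map <- function(mask_from, mask_to, from_year = NA_integer_,
                       to_year = NA_integer_) {
  stopifnot(is_raster_grid(mask_from), is_raster_grid(mask_to))
  check_same_geometry(mask_from, mask_to, "from", "to")
  check_binary(mask_from, "from mask")
  check_binary(mask_to, "to mask")
  a <- mask_from$values
  b <- mask_to$values
  cat_v <- ifelse(a == 0 & b == 1, 1,
           ifelse(a == 1 & b == 0, 2,
           ifelse(a == 1 & b == 1, 3, 0)))
  cat_v[is.na(a) | is.na(b)] <- NA_real_
  structure(
    list(categories = raster_grid(cat_v, mask_from$cell_size,
                                  mask_from$origin, mask_from$crs),
         from_year = as.integer(from_year), to_year = as.integer(to_year)),
    class = "change_map"
  )
}

#' @export
print.change_map <- function(x, ...) {
  v <- x$categories$values
  tab <- table(factor(v[!is.na(v)], levels = 0:3,
                      labels = c("stable desert", "expansion",
                                 "retreat", "stable oasis")))
  cat(sprintf("change_map %s -> %s\n", x$from_year, x$to_year))
  print(tab)
  invisible(x)
}

#' Stable oasis extent (intersection across periods)
#'
#' Cells classified as oasis in every analysed period. Nodata in any period
#' propagates (partial coverage never counts as stable).
#'
#' @param series an [oasis_series()].
#' @return binary `raster_grid`.
#' @export
stable_oasis <- function(series) {
  stopifnot(inherits(series, "oasis_series"))
  acc <- series$masks[[1L]]$values
  for (i in seq_along(series$masks)[-1L]) {
    acc <- acc * series$masks[[i]]$values  # AND; NA propagates
  }
  ref <- series$masks[[1L]]
  raster_grid(acc, ref$cell_size, ref$origin, ref$crs)
}

#' Maximum oasis extent (union across periods)
#'
#' Cells classified as oasis in at least one period.
#'
#' @param series an [oasis_series()].
#' @return binary `raster_grid`.
#' @export
maximum_oasis <- function(series) {
  stopifnot(inherits(series, "oasis_series"))
  acc <- series$masks[[1L]]$values
  for (i in seq_along(series$masks)[-1L]) {
    b <- series$masks[[i]]$values
    acc <- pmax(acc, b)  # OR; NA propagates through pmax
  }
  ref <- series$masks[[1L]]
  raster_grid(acc, ref$cell_size, ref$origin, ref$crs)
}

#' Zonal oasis areas
#'
#' Oasis area per zone label (basin or county) in km^2, each zone's share of
#' the total in percent, plus a `total` row.
#'
#' @param mask binary oasis mask.
#' @param zones zone label `raster_grid` (non-negative integer labels) on the
#'   same geometry.
#' @param year optional year attached to every row.
#' @return `data.frame` with columns `zone`, `year`, `area_km2`, `share_pct`.
#' @export
zonal_areas <- function(mask, zones, year = NA_integer_) {
  stopifnot(is_raster_grid(mask), is_raster_grid(zones))
  check_same_geometry(mask, zones, "mask", "zones")
  check_binary(mask)
  z <- zones$values
  bad <- !is.na(z) & (z < 0 | z != round(z))
  if (any(bad)) stop("zone labels must be non-negative integers",
                     call. = FALSE)
  ok <- !is.na(mask$values) & !is.na(z)
  cell_km2 <- mask$cell_size^2 / 1e6
  labs <- sort(unique(z[ok]))
  counts <- vapply(labs, function(l) {
    sum(mask$values[ok & z == l] == 1)
  }, numeric(1))
  areas <- counts * cell_km2
  total <- sum(areas)
  share <- if (total > 0) 100 * areas / total else rep(0, length(areas))
  data.frame(
    zone = c(as.character(as.integer(labs)), "total"),
    year = as.integer(year),
    area_km2 = c(areas, total),
    share_pct = c(share, if (total > 0) 100 else 0),
    stringsAsFactors = FALSE
  )
}

#' Area time series over an oasis series
#'
#' Convenience wrapper: [zonal_areas()] per period, stacked.
#'
#' @param series an [oasis_series()].
#' @param zones optional zone raster; when omitted only totals are returned.
#' @return `data.frame` with columns `zone`, `year`, `area_km2`, `share_pct`.
#' @export
area_series <- function(series, zones = NULL) {
  stopifnot(inherits(series, "oasis_series"))
  out <- lapply(seq_along(series$years), function(i) {
    m <- series$masks[[i]]
    if (is.null(zones)) {
      data.frame(zone = "total", year = series$years[i],
                 area_km2 = oasis_area(m), share_pct = 100,
                 stringsAsFactors = FALSE)
    } else {
      zonal_areas(m, zones, series$years[i])
    }
  })
  do.call(rbind, out)
}
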