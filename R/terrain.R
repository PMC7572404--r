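#' Slope and aspect from a DEM (Horn's method)
#'
#' Computes slope and aspect by Horn's 3x3 weighted finite differences, the
#' convention used by most GIS packages. Slope is `atan(|grad z|)` in
#' degrees; aspect is the compass direction of steepest descent, degrees
#' clockwise from north in \[0, 360). Cells flatter than `flat_threshold`
#' get the aspect sentinel -1 (flat). Border cells and cells whose 3x3
#' window touches nodata become nodata in both layers.
#'
#' @param dem elevation `raster_grid` in metres; cell size in metres.
#' @param flat_threshold slope (degrees) below which a cell counts as flat;
#'   default 0.01 deg, a numerically robust stand-in for "slope = 0".
#' @return list of class `terrain_layers`: `slope`, `aspect` (both
#'   `raster_grid`) and `flat_threshold`.
#' @export
slope_aspect <- function(dem, flat_threshold = 0.01) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) {
    stop("DEM must be at least 3 x 3", call. = FALSE)
  }
  cs <- dem$cell_size
  # padded shift: neighbour value at (r+dr, c+dc), NA outside
  shift <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    r_src <- seq_len(nr) + dr
    c_src <- seq_len(nc) + dc
    r_ok <- r_src >= 1L & r_src <= nr
    c_ok <- c_src >= 1L & c_src <= nc
    out[r_ok, c_ok] <- z[r_src[r_ok], c_src[c_ok]]
    out
  }
  a <- shift(-1, -1); b <- shift(-1, 0); cc <- shift(-1, 1)
  d <- shift(0, -1);                     f <- shift(0, 1)
  g <- shift(1, -1);  h <- shift(1, 0);  i <- shift(1, 1)
  # p: eastward gradient; q: southward gradient (row index grows southward)
  p <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  q <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  p[is.na(z)] <- NA_real_
  q[is.na(z)] <- NA_real_
  slope_deg <- atan(sqrt(p^2 + q^2)) * 180 / pi
  # downslope direction in (east, north) coordinates is (-p, q)
  aspect_deg <- (atan2(-p, q) * 180 / pi) %% 360
  aspect_deg[!is.na(slope_deg) & slope_deg < flat_threshold] <- -1
  structure(
    list(slope = raster_grid(slope_deg, cs, dem$origin, dem$crs),
         aspect = raster_grid(aspect_deg, cs, dem$origin, dem$crs),
         flat_threshold = flat_threshold),
    class = "terrain_layers"
  )
}

#' Aspect class labels
#'
#' Eight 45-degree sectors centred on the cardinal and intercardinal
#' directions, half-open on the clockwise side: N = \[337.5, 360) U
#' \[0, 22.5), NE = \[22.5, 67.5), and so on. The flat sentinel -1 maps to
#' class 0.
#'
#' @param aspect aspect `raster_grid` from [slope_aspect()] (degrees in
#'   \[0, 360) or -1 for flat).
#' @return `raster_grid` with integer codes 0-8; the code-to-name mapping
#'   (`0 = flat`, `1 = N`, ..., `8 = NW`) is attached as attribute `labels`
#'   and returned by [aspect_class_labels()].
#' @export
aspect_classes <- function(aspect) {
  stopifnot(is_raster_grid(aspect))
  v <- aspect$values
  bad <- !is.na(v) & v != -1 & (v < 0 | v >= 360)
  if (any(bad)) {
    stop("aspect values must lie in [0, 360) or be the flat sentinel -1",
         call. = FALSE)
  }
  cls <- floor(((v + 22.5) %% 360) / 45) + 1
  cls[!is.na(v) & v == -1] <- 0
  out <- raster_grid(cls, aspect$cell_size, aspect$origin, aspect$crs)
  attr(out, "labels") <- aspect_class_labels()
  out
}

#' @rdname aspect_classes
#' @export
aspect_class_labels <- function() {
  c("0" = "flat", "1" = "N", "2" = "NE", "3" = "E", "4" = "SE",
    "5" = "S", "6" = "SW", "7" = "W", "8" = "NW")
}
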