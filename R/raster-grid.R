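#' Raster grid objects
#'
#' A `raster_grid` is a single co-registered 2D layer: a numeric matrix of
#' cell values (with `NA` marking nodata), a square cell size in metres, the
#' projected coordinate of the top-left corner, and an opaque CRS tag that is
#' compared only for equality. Rows run north to south (row index increases
#' southward), columns west to east. All layers entering an analysis must
#' share one geometry exactly; the package never resamples.
#'
#' @param values numeric matrix; `NA` is nodata.
#' @param cell_size cell edge length in metres (default 90, the grid scale at
#'   which the constraint statistics are computed).
#' @param origin numeric length-2, projected x/y of the top-left corner.
#' @param crs character tag for the coordinate reference system; only tested
#'   for equality between layers.
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(0:3, 2, 2), cell_size = 90)
#' grid_geometry(g)
#' @export
raster_grid <- function(values, cell_size = 90, origin = c(0, 0),
                        crs = "local") {
  if (!is.matrix(values)) {
    values <- as.matrix(values)
  }
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("origin must be a numeric length-2 vector (x, y)", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = as.character(crs)[1L]),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells, cell size %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @rdname raster_grid
#' @param x a `raster_grid`.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' @rdname raster_grid
#' @export
grid_geometry <- function(x) {
  stopifnot(is_raster_grid(x))
  list(shape = dim(x$values), cell_size = x$cell_size,
       origin = x$origin, crs = x$crs)
}

#' Nodata mask of a grid
#'
#' @param x a `raster_grid`.
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(x) {
  stopifnot(is_raster_grid(x))
  is.na(x$values)
}

# Geometry equality with an absolute 1e-6 m tolerance on origin; returns NULL
# when equal, otherwise the name of the first differing attribute.
geometry_mismatch <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$values), dim(b$values))) return("shape")
  if (abs(a$cell_size - b$cell_size) > tol) return("cell_size")
  if (any(abs(a$origin - b$origin) > tol)) return("origin")
  if (!identical(a$crs, b$crs)) return("crs")
  NULL
}

check_same_geometry <- function(a, b, what_a = "first", what_b = "second") {
  bad <- geometry_mismatch(a, b)
  if (!is.null(bad)) {
    stop(sprintf("geometry mismatch between %s and %s layer: %s differs",
                 what_a, what_b, bad), call. = FALSE)
  }
  invisible(TRUE)
}

# A binary mask may contain only 0/1 outside nodata.
check_binary <- function(x, what = "mask") {
  v <- x$values
  bad <- !is.na(v) & v != 0 & v != 1
  if (any(bad)) {
    stop(sprintf("%s is not binary: %d cells outside {0, 1}",
                 what, sum(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordered multi-period oasis mask series
#'
#' Bundles binary oasis masks for two or more analysis years on one shared
#' geometry. Years must be strictly increasing.
#'
#' @param masks list of binary `raster_grid` masks, one per period.
#' @param years integer vector of the same length, strictly increasing.
#' @return an object of class `oasis_series`.
#' @export
oasis_series <- function(masks, years) {
  if (!is.list(masks) || length(masks) < 2L) {
    stop("an oasis series needs at least 2 period masks", call. = FALSE)
  }
  years <- as.integer(years)
  if (length(years) != length(masks) || any(diff(years) <= 0)) {
    stop("years must match the masks and be strictly increasing",
         call. = FALSE)
  }
  for (i in seq_along(masks)) {
    if (!is_raster_grid(masks[[i]])) {
      stop("each mask must be a raster_grid", call. = FALSE)
    }
    check_binary(masks[[i]], sprintf("period %d mask", years[i]))
    if (i > 1L) {
      check_same_geometry(masks[[1L]], masks[[i]],
                          sprintf("period %d", years[1L]),
                          sprintf("period %d", years[i]))
    }
  }
  structure(list(years = years, masks = masks), class = "oasis_series")
}

#' @export
print.oasis_series <- function(x, ...) {
  cat(sprintf("oasis_series: %d periods (%s)\n", length(x$years),
              paste(x$years, collapse = ", ")))
  invisible(x)
}

#' Assemble co-registered layers into a stack
#'
#' Verifies that every layer shares the geometry of the first (shape, cell
#' size, origin within 1e-6 m, equal CRS tag) and returns them as a named
#' stack. A mismatch is an error naming the offending layer and attribute —
#' never a silent resample.
#'
#' @param grids named list of `raster_grid` layers.
#' @return an object of class `grid_stack` with elements `layers` and
#'   `geometry`.
#' @export
assemble_stack <- function(grids) {
  if (!is.list(grids) || length(grids) < 1L) {
    stop("assemble_stack needs at least one grid", call. = FALSE)
  }
  nm <- names(grids)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all layers must be named", call. = FALSE)
  }
  for (i in seq_along(grids)) {
    if (!is_raster_grid(grids[[i]])) {
      stop(sprintf("layer '%s' is not a raster_grid", nm[i]), call. = FALSE)
    }
  }
  ref <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    bad <- geometry_mismatch(ref, grids[[i]])
    if (!is.null(bad)) {
      stop(sprintf("layer '%s' does not match the stack geometry: %s differs",
                   nm[i], bad), call. = FALSE)
    }
  }
  structure(list(layers = grids, geometry = grid_geometry(ref)),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("grid_stack: %d layers (%s), %d x %d cells at %g m\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              g$shape[1], g$shape[2], g$cell_size))
  invisible(x)
}
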