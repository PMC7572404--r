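#' Read a single-band raster from an ESRI ASCII grid
#'
#' Reads an Arc/Info ASCII grid (`.asc`): a six-line header (`ncols`,
#' `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' optional `NODATA_value`) followed by row-major cell values, north row
#' first. Cells equal to the nodata sentinel become `NA`.
#'
#' `expected_kind` enforces the layer contract on read: a `"mask"` may hold
#' only 0/1 outside nodata, a `"zone"` only non-negative integer labels;
#' `"continuous"` accepts any numeric value.
#'
#' @param path path to an existing ASCII grid file.
#' @param expected_kind one of `"continuous"`, `"mask"`, `"zone"`.
#' @param crs CRS tag to attach; ASCII grids carry no projection metadata.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path,
                        expected_kind = c("continuous", "mask", "zone"),
                        crs = "local") {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) {
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(tok) == 2L && tolower(tok[1L]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
          "yllcenter", "cellsize", "nodata_value")) {
      hdr[[tolower(tok[1L])]] <- suppressWarnings(as.numeric(tok[2L]))
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop(sprintf("unreadable ASCII grid header in %s", path), call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (is.na(nc) || is.na(nr) || nc < 1L || nr < 1L || cs <= 0) {
    stop(sprintf("unreadable ASCII grid header in %s", path), call. = FALSE)
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  body <- paste(lines[(n_hdr + 1L):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body),
                                               "[[:space:]]+")[[1L]]))
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop(sprintf("ASCII grid %s: non-numeric cell values", path),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  # top-left origin: yll is the bottom edge
  g <- raster_grid(m, cell_size = cs, origin = c(xll, yll + nr * cs),
                   crs = crs)
  if (expected_kind == "mask") {
    bad <- !is.na(m) & m != 0 & m != 1
    if (any(bad)) {
      stop(sprintf("%s read as mask but holds %d values outside {0, 1}",
                   path, sum(bad)), call. = FALSE)
    }
  } else if (expected_kind == "zone") {
    bad <- !is.na(m) & (m < 0 | m != round(m))
    if (any(bad)) {
      stop(sprintf("%s read as zones but holds %d non-integer or negative labels",
                   path, sum(bad)), call. = FALSE)
    }
  }
  g
}

#' Write a raster to an ESRI ASCII grid
#'
#' Inverse of [read_raster()]: `read_raster(write_raster(g))` reproduces the
#' grid (bit-identical for integer-valued layers, within formatting precision
#' for floats). Nodata cells are written as -9999.
#'
#' @param grid a [raster_grid()].
#' @param path output path; the parent directory must exist.
#' @param format only `"ascii"` is supported.
#' @param digits significant digits for cell values (default 10).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = "ascii", digits = 10) {
  stopifnot(is_raster_grid(grid))
  format <- match.arg(format, "ascii")
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nodata <- -9999
  if (any(!is.na(v) & v == nodata)) {
    stop("grid contains the nodata sentinel -9999 as a data value",
         call. = FALSE)
  }
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  out <- v
  out[is.na(out)] <- nodata
  rows <- apply(out, 1L, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a long-form panel table
#'
#' Reads a comma- or tab-delimited text file with a header row and columns
#' `region`, `year`, `variable`, `value` — the per-region annual series
#' (population, labour, GDP components, precipitation, AWD, oasis area)
#' feeding the grey incidence analysis. Duplicate (region, year, variable)
#' triples are an error.
#'
#' @param path path to the delimited file; the delimiter (comma or tab) is
#'   detected from the header line.
#' @return a `data.frame` of class `panel_table` with columns `region`
#'   (character), `year` (integer), `variable` (character), `value` (numeric).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("panel file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_panel_table(df)
}

#' @rdname read_panel
#' @param df a data.frame with the four panel columns, to validate and tag.
#' @export
as_panel_table <- function(df) {
  need <- c("region", "year", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("panel is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[need]
  df$region <- as.character(df$region)
  yr <- suppressWarnings(as.integer(as.character(df$year)))
  if (anyNA(yr)) stop("panel column 'year' has non-integer entries",
                      call. = FALSE)
  df$year <- yr
  val <- suppressWarnings(as.numeric(as.character(df$value)))
  if (anyNA(val) && any(is.na(val) & !is.na(df$value))) {
    stop("panel column 'value' has non-numeric entries", call. = FALSE)
  }
  df$value <- val
  key <- paste(df$region, df$year, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate panel entry: %s",
                 gsub("\r", " / ", d)), call. = FALSE)
  }
  class(df) <- c("panel_table", "data.frame")
  df
}

#' Write a panel table as delimited text
#'
#' @param panel a `panel_table`.
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  utils::write.table(panel, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
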