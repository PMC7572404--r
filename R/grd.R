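#' Dimensionless normalization of a time series
#'
#' Grey relational analysis compares series shapes, so each series is first
#' made dimensionless: `"mean"` divides by the series mean (robust when the
#' first value is small), `"initial"` divides by the first value.
#'
#' @param x numeric series.
#' @param method `"mean"` or `"initial"`.
#' @return dimensionless series of the same length.
#' @export
normalize_series <- function(x, method = c("mean", "initial")) {
  method <- match.arg(method)
  if (!is.numeric(x) || length(x) < 1L || anyNA(x)) {
    stop("series must be numeric with no missing values", call. = FALSE)
  }
  d <- if (method == "mean") mean(x) else x[1L]
  if (d == 0) {
    stop(sprintf("cannot normalize: %s of the series is zero",
                 if (method == "mean") "mean" else "initial value"),
         call. = FALSE)
  }
  x / d
}

#' Deng's degree of grey incidence
#'
#' For a normalized reference series `x0` and normalized comparators `xi`,
#' the grey relational coefficient at each time k is
#' `xi(k) = (Dmin + rho Dmax) / (Di(k) + rho Dmax)` with
#' `Di(k) = |x0(k) - xi(k)|` and `Dmin`/`Dmax` the global extrema of the
#' absolute differences over all comparators and times; the grey relational
#' degree (GRD) is the mean coefficient over time. `rho` in (0, 1] is the
#' distinguishing coefficient (conventionally 0.5). When every comparator
#' equals the reference (`Dmax = 0`) all degrees are 1.
#'
#' @param reference normalized numeric series (length >= 2).
#' @param comparators list of normalized series of the same length (or a
#'   single series).
#' @param rho distinguishing coefficient in (0, 1].
#' @return named numeric vector of degrees in (0, 1], one per comparator.
#' @examples
#' x0 <- normalize_series(c(1, 2, 3))
#' x1 <- normalize_series(c(3, 2, 1))
#' grey_relational_degree(x0, list(rev = x1), rho = 0.5)  # 5/9
#' @export
grey_relational_degree <- function(reference, comparators, rho = 0.5) {
  if (!is.list(comparators)) comparators <- list(comparators)
  if (!length(comparators)) stop("no comparators given", call. = FALSE)
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  n <- length(reference)
  if (n < 2L) stop("series must have length >= 2", call. = FALSE)
  for (i in seq_along(comparators)) {
    if (length(comparators[[i]]) != n) {
      stop("all comparators must match the reference length", call. = FALSE)
    }
  }
  D <- vapply(comparators, function(xi) abs(reference - xi), numeric(n))
  D <- matrix(D, nrow = n)
  d_min <- min(D)
  d_max <- max(D)
  if (d_max == 0) {
    gam <- rep(1, length(comparators))
  } else {
    xi_mat <- (d_min + rho * d_max) / (D + rho * d_max)
    gam <- colMeans(xi_mat)
  }
  names(gam) <- names(comparators)
  gam
}

#' Grey relational degrees from a panel table
#'
#' Computes, independently for each region, the GRD between the reference
#' variable (oasis area) and each factor, over the years common to all
#' series in that region. `Dmin`/`Dmax` are taken within each region's
#' comparator set, so rows are self-contained. A missing (region, variable)
#' series yields an `NA` cell and a warning, never a silent drop.
#'
#' The `"relative"` variant applies Deng's coefficient to the zero-start
#' images of initial-value-normalized series (each series divided by its
#' first value, minus 1), emphasising relative growth rates.
#'
#' @param panel a `panel_table` (see [read_panel()]).
#' @param reference_variable variable name of the reference series.
#' @param factors factor variable names; default all non-reference
#'   variables.
#' @param rho distinguishing coefficient.
#' @param normalization `"mean"` or `"initial"` (ignored by the
#'   `"relative"` variant, which is defined on initial-value images).
#' @param variant `"deng"` (default) or `"relative"`.
#' @return object of class `grd_matrix`: numeric matrix regions x factors
#'   with attributes `rho`, `normalization`, `variant`.
#' @export
panel_grd <- function(panel, reference_variable = "oasis_area",
                      factors = NULL, rho = 0.5,
                      normalization = c("mean", "initial"),
                      variant = c("deng", "relative")) {
  normalization <- match.arg(normalization)
  variant <- match.arg(variant)
  panel <- as_panel_table(as.data.frame(panel))
  vars <- unique(panel$variable)
  if (!reference_variable %in% vars) {
    stop(sprintf("reference variable '%s' not in panel",
                 reference_variable), call. = FALSE)
  }
  if (is.null(factors)) factors <- setdiff(vars, reference_variable)
  regions <- unique(panel$region)
  out <- matrix(NA_real_, length(regions), length(factors),
                dimnames = list(regions, factors))
  prep <- function(x) {
    if (variant == "relative") x / x[1L] - 1
    else normalize_series(x, normalization)
  }
  for (r in regions) {
    sub <- panel[panel$region == r, , drop = FALSE]
    get_series <- function(v) {
      s <- sub[sub$variable == v, , drop = FALSE]
      s <- s[order(s$year), , drop = FALSE]
      s[!is.na(s$value), , drop = FALSE]
    }
    ref <- get_series(reference_variable)
    if (nrow(ref) < 2L) {
      warning(sprintf("region %s: reference series too short; row is NA", r),
              call. = FALSE)
      next
    }
    avail <- list()
    for (f in factors) {
      s <- get_series(f)
      yrs <- intersect(ref$year, s$year)
      if (length(yrs) < 2L) {
        warning(sprintf("region %s: factor %s missing or too short", r, f),
                call. = FALSE)
        next
      }
      avail[[f]] <- s
    }
    if (!length(avail)) next
    # common year grid across reference and available factors
    yrs <- ref$year
    for (f in names(avail)) yrs <- intersect(yrs, avail[[f]]$year)
    yrs <- sort(yrs)
    if (length(yrs) < 2L) next
    x0 <- prep(ref$value[match(yrs, ref$year)])
    comp <- lapply(avail, function(s) prep(s$value[match(yrs, s$year)]))
    gam <- grey_relational_degree(x0, comp, rho = rho)
    out[r, names(gam)] <- gam
  }
  structure(out, class = c("grd_matrix", "matrix"),
            rho = rho, normalization = normalization, variant = variant)
}

#' @export
print.grd_matrix <- function(x, ...) {
  cat(sprintf("grd_matrix (%s variant, rho = %g, %s normalization)\n",
              attr(x, "variant"), attr(x, "rho"), attr(x, "normalization")))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Rank driving factors by aggregate grey relational degree
#'
#' Aggregates each factor's GRD across regions (mean or median) and sorts
#' descending. Exact ties share a rank and are flagged; tied factors are
#' listed alphabetically.
#'
#' @param matrix a `grd_matrix` from [panel_grd()].
#' @param aggregation `"mean"` or `"median"` across regions (NA cells
#'   dropped).
#' @return `data.frame` with columns `factor`, `gamma`, `rank`, `tied`,
#'   ordered best first.
#' @export
rank_factors <- function(matrix, aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  if (!inherits(matrix, "grd_matrix") || !length(matrix)) {
    stop("need a non-empty grd_matrix", call. = FALSE)
  }
  m <- unclass(matrix)
  agg <- apply(m, 2L, if (aggregation == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  })
  ord <- order(-agg, names(agg))
  agg <- agg[ord]
  rk <- rank(-agg, ties.method = "min")
  data.frame(factor = names(agg), gamma = unname(agg),
             rank = as.integer(rk),
             tied = duplicated(rk) | duplicated(rk, fromLast = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}
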