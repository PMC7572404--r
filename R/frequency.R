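#' Distribution frequency of oasis cells along a covariate
#'
#' The constraint statistic: for each covariate bin, the fraction of valid
#' oasis cells falling in it, out of all oasis cells with a valid covariate
#' value. Bins are half-open `[lo + k w, lo + (k+1) w)`. Cells that are
#' nodata in either layer are excluded from numerator and denominator.
#' Zero-frequency bins inside the observed range are kept; bins outside it
#' are dropped.
#'
#' @param mask binary oasis mask.
#' @param covariate continuous `raster_grid` on the same geometry (elevation
#'   m, slope degrees, precipitation/AWD mm, temperature degC, ...).
#' @param bin_width bin width in covariate units; must be > 0.
#' @param range optional `c(lo, hi)`; defaults to bin edges aligned to
#'   multiples of `bin_width` covering the observed oasis values.
#' @param covariate_name label carried into the result.
#' @return object of class `frequency_distribution`: `covariate_name`,
#'   `bin_centers`, `frequencies` (sum to 1), `counts`, `n_oasis_cells`,
#'   `bin_width`.
#' @export
distribution_frequency <- function(mask, covariate, bin_width,
                                   range = NULL,
                                   covariate_name = "covariate") {
  stopifnot(is_raster_grid(mask), is_raster_grid(covariate))
  check_same_geometry(mask, covariate, "mask", "covariate")
  check_binary(mask)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  ok <- !is.na(mask$values) & !is.na(covariate$values) & mask$values == 1
  x <- covariate$values[ok]
  if (!length(x)) stop("no valid oasis cells", call. = FALSE)
  if (is.null(range)) {
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling((max(x) + 1e-12) / bin_width) * bin_width
  } else {
    lo <- range[1]; hi <- range[2]
    x <- x[x >= lo & x < hi]
    if (!length(x)) stop("no valid oasis cells inside range", call. = FALSE)
  }
  k <- floor((x - lo) / bin_width)
  nb <- max(k) + 1L
  counts <- tabulate(k + 1L, nbins = nb)
  # drop leading empty bins (outside the observed range)
  first <- which(counts > 0)[1L]
  counts <- counts[first:nb]
  centers <- lo + (seq.int(first - 1L, nb - 1L) + 0.5) * bin_width
  structure(
    list(covariate_name = covariate_name,
         bin_centers = centers,
         frequencies = counts / length(x),
         counts = counts,
         n_oasis_cells = length(x),
         bin_width = bin_width),
    class = "frequency_distribution"
  )
}

#' @export
print.frequency_distribution <- function(x, ...) {
  cat(sprintf("frequency_distribution of %s: %d bins, %d oasis cells\n",
              x$covariate_name, length(x$frequencies), x$n_oasis_cells))
  invisible(x)
}

#' Distribution frequency over categorical classes
#'
#' Fraction of oasis cells per class label (e.g. aspect sectors). Classes
#' listed in `exclude` are removed from numerator and denominator — e.g.
#' `exclude = 0` drops flat cells so shares are among sloped oasis cells
#' only, the "slope oasis" view.
#'
#' @param mask binary oasis mask.
#' @param classes label `raster_grid` on the same geometry.
#' @param exclude label values excluded from the denominator.
#' @param labels optional named character vector mapping codes to names (as
#'   from [aspect_class_labels()]).
#' @return object of class `categorical_frequency`: `levels`, `labels`,
#'   `frequencies`, `counts`, `n_oasis_cells`.
#' @export
categorical_frequency <- function(mask, classes, exclude = NULL,
                                  labels = NULL) {
  stopifnot(is_raster_grid(mask), is_raster_grid(classes))
  check_same_geometry(mask, classes, "mask", "classes")
  check_binary(mask)
  ok <- !is.na(mask$values) & !is.na(classes$values) & mask$values == 1
  cl <- classes$values[ok]
  if (!is.null(exclude)) cl <- cl[!(cl %in% exclude)]
  if (!length(cl)) {
    stop("empty denominator: no oasis cells in the retained classes",
         call. = FALSE)
  }
  lev <- sort(unique(cl))
  counts <- vapply(lev, function(l) sum(cl == l), numeric(1))
  lab <- if (!is.null(labels)) unname(labels[as.character(lev)])
         else as.character(lev)
  structure(
    list(levels = lev, labels = lab,
         frequencies = counts / length(cl),
         counts = counts, n_oasis_cells = length(cl)),
    class = "categorical_frequency"
  )
}

#' Fit a Gaussian curve to a distribution-frequency profile
#'
#' Least-squares fit of `f(x) = y0 + a exp(-(x - mu)^2 / (2 sigma^2))` to
#' the (bin centre, frequency) pairs, the "fitted normal distribution
#' curve" of the constraint analysis. Initialised at the frequency-weighted
#' mean and sd, `a0` = max frequency, `y0` = 0; refit from jittered starts
#' on non-convergence. Reports r-squared and the F-test p-value of the
#' fitted curve against the constant model.
#'
#' @param freq a `frequency_distribution`.
#' @param with_offset include the baseline offset `y0` (default TRUE;
#'   frequency curves typically carry flat tails).
#' @param max_restarts bounded number of jittered re-initialisations.
#' @return object of class `normal_fit`: `a`, `mu`, `sigma`, `y0`,
#'   `r_squared`, `p_value`, `fitted`, `n_bins`.
#' @export
fit_normal <- function(freq, with_offset = TRUE, max_restarts = 10L) {
  stopifnot(inherits(freq, "frequency_distribution"))
  x <- freq$bin_centers
  y <- freq$frequencies
  if (sum(y > 0) < 5L) {
    stop("need at least 5 bins with non-zero frequency", call. = FALSE)
  }
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- sqrt(sum(w * (x - mu0)^2))
  if (sd0 <= 0) sd0 <- freq$bin_width
  a0 <- max(y)
  dat <- data.frame(x = x, y = y)
  form <- if (with_offset) {
    y ~ y0 + a * exp(-(x - mu)^2 / (2 * sigma^2))
  } else {
    y ~ a * exp(-(x - mu)^2 / (2 * sigma^2))
  }
  starts <- list(c(a = a0, mu = mu0, sigma = sd0))
  fit <- NULL
  for (r in seq_len(max_restarts + 1L)) {
    st <- starts[[1L]]
    if (r > 1L) {  # jitter deterministically by restart index
      st["mu"] <- mu0 + (r - 6) * 0.4 * freq$bin_width
      st["sigma"] <- sd0 * c(0.5, 0.75, 1.5, 2, 3, 0.33, 4, 1.25, 0.9, 2.5)[
        ((r - 2L) %% 10L) + 1L]
    }
    start <- as.list(st)
    if (with_offset) start$y0 <- 0
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = if (with_offset) {
                          c(a = 0, mu = -Inf, sigma = 1e-9, y0 = -Inf)
                        } else c(a = 0, mu = -Inf, sigma = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Gaussian fit did not converge after bounded restarts",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  # constant input: the curve carries no information beyond the mean
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  p_par <- length(cf)
  df1 <- p_par - 1L
  df2 <- length(y) - p_par
  p_val <- if (df2 <= 0) {
    NA_real_
  } else if (ss_tot <= 0) {
    1
  } else if (ss_res <= .Machine$double.eps * ss_tot) {
    0
  } else {
    fstat <- ((ss_tot - ss_res) / df1) / (ss_res / df2)
    stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(a = unname(cf["a"]), mu = unname(cf["mu"]),
         sigma = abs(unname(cf["sigma"])),
         y0 = if (with_offset) unname(cf["y0"]) else 0,
         r_squared = r2, p_value = p_val,
         fitted = yhat, n_bins = length(y)),
    class = "normal_fit"
  )
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf(
    "normal_fit: a = %.4g, mu = %.4g, sigma = %.4g, y0 = %.4g\n  r^2 = %.4f, F-test p = %.3g (%d bins)\n",
    x$a, x$mu, x$sigma, x$y0, x$r_squared, x$p_value, x$n_bins))
  invisible(x)
}

#' Stable-vs-maximum constraint comparison
#'
#' Runs the frequency + Gaussian-fit pipeline on both the stable
#' (intersection) and maximum (union) oasis extents of a series and reports
#' the fitted peak locations and spreads side by side. A wider maximum
#' spread (`sigma_maximum > sigma_stable`) is the "flatter curve" signature
#' of expansion into marginal conditions.
#'
#' @param series an [oasis_series()].
#' @param covariate continuous `raster_grid`.
#' @param bin_width bin width in covariate units.
#' @param with_offset passed to [fit_normal()].
#' @param covariate_name label for the reports.
#' @return list of class `stable_maximum_comparison` with elements `stable`
#'   and `maximum` (each `freq` + `fit`), `peak_stable`, `peak_maximum`,
#'   `sigma_stable`, `sigma_maximum`, `maximum_flatter` (logical).
#' @export
compare_stable_maximum <- function(series, covariate, bin_width,
                                   with_offset = TRUE,
                                   covariate_name = "covariate") {
  s_mask <- stable_oasis(series)
  m_mask <- maximum_oasis(series)
  fs <- distribution_frequency(s_mask, covariate, bin_width,
                               covariate_name = covariate_name)
  fm <- distribution_frequency(m_mask, covariate, bin_width,
                               covariate_name = covariate_name)
  nf_s <- fit_normal(fs, with_offset = with_offset)
  nf_m <- fit_normal(fm, with_offset = with_offset)
  structure(
    list(stable = list(freq = fs, fit = nf_s),
         maximum = list(freq = fm, fit = nf_m),
         peak_stable = nf_s$mu, peak_maximum = nf_m$mu,
         sigma_stable = nf_s$sigma, sigma_maximum = nf_m$sigma,
         maximum_flatter = nf_m$sigma > nf_s$sigma),
    class = "stable_maximum_comparison"
  )
}

#' Fraction of oasis cells beyond a covariate threshold
#'
#' For a hydrologic or thermal limit (e.g. water depth >= 400 mm), the
#' fraction of valid oasis cells whose covariate satisfies it.
#'
#' @param mask binary oasis mask.
#' @param covariate continuous `raster_grid` on the same geometry.
#' @param threshold covariate value.
#' @param direction `"ge"` (covariate >= threshold) or `"le"`.
#' @return fraction in \[0, 1\].
#' @export
threshold_support <- function(mask, covariate, threshold,
                              direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(is_raster_grid(mask), is_raster_grid(covariate))
  check_same_geometry(mask, covariate, "mask", "covariate")
  check_binary(mask)
  ok <- !is.na(mask$values) & !is.na(covariate$values) & mask$values == 1
  x <- covariate$values[ok]
  if (!length(x)) stop("empty denominator: no valid oasis cells",
                       call. = FALSE)
  if (direction == "ge") mean(x >= threshold) else mean(x <= threshold)
}
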