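# grid and panel builders used across the suite

rg <- function(m, cs = 90, origin = c(0, nrow(as.matrix(m)) * cs),
               crs = "local") {
  raster_grid(as.matrix(m), cs, origin, crs)
}

random_mask <- function(nr, nc, p = 0.4, na_frac = 0) {
  v <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  if (na_frac > 0) {
    v[sample(length(v), round(na_frac * length(v)))] <- NA_real_
  }
  rg(v)
}

random_series <- function(nr, nc, n_periods = 7, years = NULL) {
  if (is.null(years)) years <- seq_len(n_periods) * 5 + 1980
  oasis_series(lapply(seq_len(n_periods),
                      function(i) random_mask(nr, nc)), years)
}

# independent per-element loop oracle for Deng's grey relational degree
grd_loop_oracle <- function(x0, comparators, rho = 0.5) {
  n <- length(x0)
  deltas <- list()
  for (xi in comparators) {
    d <- numeric(n)
    for (k in seq_len(n)) d[k] <- abs(x0[k] - xi[k])
    deltas[[length(deltas) + 1L]] <- d
  }
  d_min <- Inf; d_max <- -Inf
  for (d in deltas) for (k in seq_len(n)) {
    if (d[k] < d_min) d_min <- d[k]
    if (d[k] > d_max) d_max <- d[k]
  }
  if (d_max == 0) return(rep(1, length(comparators)))
  out <- numeric(length(comparators))
  for (i in seq_along(deltas)) {
    s <- 0
    for (k in seq_len(n)) {
      s <- s + (d_min + rho * d_max) / (deltas[[i]][k] + rho * d_max)
    }
    out[i] <- s / n
  }
  out
}
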