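# Shared fixture builders; everything is generated in code.

tiny_scenario <- function(n_sites = 30, years = 2005:2006, seed = 1L, ...) {
  phenology_scenario(n_sites = n_sites, years = years, seed = seed, ...)
}

# Single-site daily climate table with constant or supplied variables.
make_daily <- function(years, tmean = 10, prcp = 0, sw = 200, lw = 300,
                       s_id = "A") {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  n <- length(dates)
  tibble::tibble(
    s_id = s_id,
    date = dates,
    year = as.integer(format(dates, "%Y")),
    doy = as.POSIXlt(dates)$yday + 1L,
    tmean = rep_len(tmean, n),
    prcp = rep_len(prcp, n),
    sw = rep_len(sw, n),
    lw = rep_len(lw, n)
  )
}

# Spatially correlated Gaussian field drawn independently of the package's
# own sampler (plain Cholesky of an exponential covariance).
oracle_gp <- function(lon, lat, range_km, sd = 1) {
  d <- outer(seq_along(lon), seq_along(lon), function(i, j) {
    p1 <- cbind(lon[i], lat[i]) * pi / 180
    p2 <- cbind(lon[j], lat[j]) * pi / 180
    a <- sin((p2[, 2] - p1[, 2]) / 2)^2 +
      cos(p1[, 2]) * cos(p2[, 2]) * sin((p2[, 1] - p1[, 1]) / 2)^2
    2 * 6371.0088 * asin(sqrt(pmin(pmax(a, 0), 1)))
  })
  cmat <- exp(-d / range_km) + diag(1e-8, length(lon))
  sd * as.vector(t(chol(cmat)) %*% rnorm(length(lon)))
}

random_coords <- function(n) {
  tibble::tibble(lon = runif(n, 5, 15), lat = runif(n, 47, 53))
}
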