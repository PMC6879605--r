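# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "phenospace_validation_error")
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

days_in_year <- function(year) {
  ifelse(is_leap_year(year), 366L, 365L)
}

# Great-circle distance matrix in km between points given in decimal degrees.
dist_haversine_km <- function(lon, lat) {
  r_earth <- 6371.0088
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lon)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r_earth * asin(sqrt(a))
}

# Local equirectangular projection to km, used where a planar coordinate
# system is required (nlme correlation structures). Adequate at the regional
# extents this package targets (a few hundred km).
project_local_km <- function(lon, lat) {
  lat0 <- mean(lat) * pi / 180
  tibble::tibble(
    x_km = (lon - mean(lon)) * 111.320 * cos(lat0),
    y_km = (lat - mean(lat)) * 110.574
  )
}

# Draw one realisation of a zero-mean Gaussian random field at the given
# coordinates, with unit marginal variance and the requested correlation
# family on great-circle distances. range_km <= 0 degenerates to iid noise.
gp_field <- function(lon, lat, range_km, family = "exponential") {
  n <- length(lon)
  if (range_km <= 0 || family == "independent") {
    return(stats::rnorm(n))
  }
  d <- dist_haversine_km(lon, lat)
  h <- d / range_km
  corr <- switch(family,
    exponential = exp(-h),
    gaussian = exp(-h^2),
    spherical = ifelse(h < 1, 1 - 1.5 * h + 0.5 * h^3, 0),
    rational_quadratic = 1 / (1 + h^2),
    linear = pmax(1 - h, 0),
    abort_validation(paste0("unknown spatial correlation family: ", family))
  )
  ch <- chol(corr + diag(1e-8, n))
  as.vector(t(ch) %*% stats::rnorm(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reorder a per-site daily table by (site, date) only when needed: generated
# tables are already sorted and ordering millions of strings is costly.
order_site_date <- function(df) {
  f <- match(df$s_id, unique(df$s_id))
  dn <- as.numeric(df$date)
  sorted <- !is.unsorted(f) && all(diff(dn)[diff(f) == 0] > 0)
  if (sorted) df else df[order(f, dn), ]
}
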