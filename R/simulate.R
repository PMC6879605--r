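#' Generate a synthetic site network
#'
#' Draws site coordinates uniformly inside the scenario's bounding box,
#' elevations skewed towards the low end of the configured range (observation
#' networks are lowland-dominated), a grid-cell mean elevation per site (the
#' elevation at which gridded climate is delivered, differing from the true
#' site elevation), and cyclic species labels.
#'
#' @param scenario A [phenology_scenario()].
#' @return A tibble with columns `s_id`, `lon`, `lat`, `alt`, `grid_alt`,
#'   `species`.
#' @export
simulate_site_network <- function(scenario) {
  stopifnot(inherits(scenario, "phenology_scenario"))
  n <- scenario$n_sites
  with_preserved_seed(scenario$seed + 1L, {
    lon <- stats::runif(n, scenario$lon_range[1], scenario$lon_range[2])
    lat <- stats::runif(n, scenario$lat_range[1], scenario$lat_range[2])
    alt <- round(scenario$elev_range_m[1] +
                   stats::runif(n)^2 * diff(scenario$elev_range_m))
    grid_alt <- pmax(0, round(alt + stats::rnorm(n, 0, 60)))
    tibble::tibble(
      s_id = sprintf("S%05d", seq_len(n)),
      lon = lon, lat = lat,
      alt = alt, grid_alt = grid_alt,
      species = rep_len(scenario$species, n)
    )
  })
}

#' Generate daily climate and monthly soil moisture for a site network
#'
#' Produces gridded-product-like daily weather for every site, at the site's
#' grid-cell elevation (`grid_alt`), from one year before the first scenario
#' year (so that chilling and preseason windows of the first year are covered)
#' through the last scenario year. Temperature is a sinusoidal annual cycle
#' plus a latitude gradient, elevation lapse, a spatially correlated site
#' anomaly, a shared annual anomaly and AR(1) daily noise. Shortwave radiation
#' is daily-mean top-of-atmosphere irradiance times a stochastic atmospheric
#' transmissivity whose site means are spatially correlated and differ between
#' spring and summer. Longwave radiation increases linearly with temperature.
#' Precipitation is a Bernoulli-gamma process with spatially correlated,
#' season-specific wetness. Monthly soil moisture comes from a single-layer
#' bucket driven by monthly precipitation minus a temperature-based demand
#' proxy.
#'
#' @param sites Site table from [simulate_site_network()].
#' @param scenario The [phenology_scenario()] that produced `sites`.
#' @return A list of class `pheno_climate` with elements `daily` (tibble:
#'   `s_id`, `date`, `year`, `doy`, `tmean`, `prcp`, `sw`, `lw`) and `soil`
#'   (tibble: `s_id`, `year`, `month`, `sm` with `sm` in `[0, 1]`).
#' @export
simulate_daily_climate <- function(sites, scenario) {
  stopifnot(inherits(scenario, "phenology_scenario"))
  if (nrow(sites) == 0) abort_validation("`sites` must be non-empty")
  w <- scenario$weather
  n <- nrow(sites)
  years <- (min(scenario$years) - 1L):max(scenario$years)
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  nd <- length(dates)
  plt <- as.POSIXlt(dates)
  doy <- plt$yday + 1L
  yr <- plt$year + 1900L

  with_preserved_seed(scenario$seed + 2L, {
    # spatially correlated site fields (exponential covariance on great-circle
    # distances; the family fitted downstream nests this structure)
    t_anom <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km) * w$t_site_sd
    clear_spring <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km) * w$sw_site_sd
    clear_summer <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km) * w$sw_site_sd
    wet_spring <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km) * w$wet_site_sd
    wet_summer <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km) * w$wet_site_sd
    year_eff <- stats::rnorm(length(years), 0, w$t_year_sd)
    names(year_eff) <- as.character(years)

    # deterministic temperature cycle, days x sites
    cyc <- w$t_amplitude * cos(2 * pi * (doy - w$t_peak_doy) / 365.25)
    base_site <- w$t_base - w$t_lat_gradient * (sites$lat - w$lat0) -
      scenario$lapse_rate * sites$grid_alt / 1000 + t_anom
    tdet <- outer(cyc, rep(1, n)) + outer(rep(1, nd), base_site) +
      year_eff[as.character(yr)]

    # AR(1) daily anomalies, iterated over days, vectorised across sites
    eps <- matrix(0, nd, n)
    innov <- matrix(stats::rnorm(nd * n, 0, w$t_innov_sd), nd, n)
    eps[1, ] <- innov[1, ] / sqrt(max(1 - w$t_ar1^2, 1e-12))
    if (nd > 1) {
      for (d in 2:nd) eps[d, ] <- w$t_ar1 * eps[d - 1, ] + innov[d, ]
    }
    tmean <- tdet + eps

    # shortwave: top-of-atmosphere irradiance x transmissivity
    ra <- toa_radiation(sites$lat, doy)  # days x sites, W m-2
    blend <- stats::plogis((doy - 150) / 15)  # 0 = spring fields, 1 = summer
    clear_site <- outer(1 - blend, clear_spring) + outer(blend, clear_summer)
    tau <- stats::plogis(stats::qlogis(w$sw_clearness) + clear_site +
                           matrix(stats::rnorm(nd * n, 0, w$sw_day_sd), nd, n))
    sw <- ra * tau

    # longwave: smooth increasing function of temperature plus noise
    lw <- pmax(w$lw_intercept + w$lw_slope * tmean +
                 matrix(stats::rnorm(nd * n, 0, w$lw_noise_sd), nd, n), 0)

    # precipitation: occurrence x gamma amounts with seasonal wetness fields
    wet_site <- outer(1 - blend, wet_spring) + outer(blend, wet_summer)
    p_wet <- stats::plogis(stats::qlogis(w$p_wet) + wet_site)
    occ <- matrix(stats::runif(nd * n), nd, n) < p_wet
    amt <- matrix(
      stats::rgamma(nd * n, shape = w$prcp_shape,
                    scale = w$wet_day_mm * exp(0.5 * as.vector(wet_site)) /
                      w$prcp_shape),
      nd, n
    )
    prcp <- ifelse(occ, amt, 0)

    daily <- tibble::tibble(
      s_id = rep(sites$s_id, each = nd),
      date = rep(dates, n),
      year = rep(yr, n),
      doy = rep(doy, n),
      tmean = as.vector(tmean),
      prcp = as.vector(prcp),
      sw = as.vector(sw),
      lw = as.vector(lw)
    )

    # monthly soil-moisture bucket
    mon <- plt$mon + 1L
    key <- yr * 100L + mon
    ukey <- sort(unique(key))
    p_m <- rowsum(prcp, key)               # months x sites (mm)
    t_m <- rowsum(tmean, key) / as.vector(table(key))
    pet_m <- pmax(15 + 6 * t_m, 0)         # mm, demand proxy
    wtr <- matrix(0, length(ukey), n)
    wprev <- rep(w$sm_capacity_mm, n)
    for (m in seq_along(ukey)) {
      wprev <- pmin(w$sm_capacity_mm, pmax(0, wprev + p_m[m, ] - pet_m[m, ]))
      wtr[m, ] <- wprev
    }
    soil <- tibble::tibble(
      s_id = rep(sites$s_id, each = length(ukey)),
      year = rep(ukey %/% 100L, n),
      month = rep(ukey %% 100L, n),
      sm = as.vector(wtr) / w$sm_capacity_mm
    )
    structure(list(daily = daily, soil = soil), class = "pheno_climate")
  })
}

# Daily-mean extraterrestrial solar irradiance (W m-2), days x sites.
toa_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  g <- 2 * pi * doy / 365
  dr <- 1 + 0.033 * cos(g)
  delta <- 0.409 * sin(g - 1.39)
  cws <- pmin(pmax(-outer(tan(delta), tan(phi)), -1), 1)
  ws <- acos(cws)
  (1361 / pi) * dr * (ws * outer(sin(delta), sin(phi)) +
                        outer(cos(delta), cos(phi)) * sin(ws))
}

#' @export
print.pheno_climate <- function(x, ...) {
  cat("<pheno_climate>\n")
  cat("  daily:", nrow(x$daily), "records,",
      dplyr::n_distinct(x$daily$s_id), "sites,",
      format(min(x$daily$date)), "to", format(max(x$daily$date)), "\n")
  cat("  soil: monthly,", nrow(x$soil), "records\n")
  invisible(x)
}

#' Generate leaf-unfolding observations from the adaptive thermal-time rule
#'
#' Assigns each site a true heat requirement
#' `GDDreq* = gddreq_mean + gddreq_scale * sum(coef_k * z_k) + e`, where `z_k`
#' are the site's standardized long-term background covariates (computed from
#' the generated climate over fixed reference windows) and `e` is a spatially
#' correlated Gaussian residual with the scenario's structure and range. Each
#' year's LU is then the first day on which growing degree days accumulated
#' from 1 January (threshold 5 degC, at the true site elevation) reach
#' `GDDreq*`, plus integer-rounded Gaussian observation noise. Site-years in
#' which the requirement is never reached are emitted as missing and dropped
#' with a message.
#'
#' @param sites Site table from [simulate_site_network()].
#' @param climate `pheno_climate` from [simulate_daily_climate()].
#' @param scenario The generating [phenology_scenario()].
#' @return A list with `observations` (tibble: `s_id`, `lon`, `lat`, `alt`,
#'   `species`, `year`, `day`) and `ground_truth` (tibble: `s_id`,
#'   `gdd_req_true` and the standardized covariates `z_*` used; attributes
#'   `coefficients`, `structure_name`, `spatial_range_km`).
#' @export
simulate_lu_observations <- function(sites, climate, scenario) {
  stopifnot(inherits(scenario, "phenology_scenario"),
            inherits(climate, "pheno_climate"))
  daily <- correct_temperature_sites(climate$daily, sites,
                                     lapse_rate = scenario$lapse_rate)
  coefs <- scenario$gddreq_coefficients

  # long-term background covariates over fixed reference windows
  z <- NULL
  if (length(coefs) > 0) {
    pre <- seasonal_means(daily, window = "preseason", reference_lu_doy = 120,
                          years = scenario$years, soil_moisture = climate$soil,
                          exclude_extremes = FALSE)
    grw <- seasonal_means(daily, window = "growing",
                          years = scenario$years, soil_moisture = climate$soil,
                          exclude_extremes = FALSE)
    cov_tbl <- tibble::tibble(
      s_id = pre$s_id,
      TP = pre$temp, SWP = pre$sw, LWP = pre$lw, PP = pre$prcp, SMP = pre$sm,
      TG = grw$temp, SWG = grw$sw, LWG = grw$lw, PG = grw$prcp, SMG = grw$sm
    )
    cov_tbl <- cov_tbl[match(sites$s_id, cov_tbl$s_id), ]
    z <- vapply(names(coefs), function(v) as.vector(scale(cov_tbl[[v]])),
                numeric(nrow(sites)))
  }

  with_preserved_seed(scenario$seed + 3L, {
    noise <- gp_field(sites$lon, sites$lat, scenario$spatial_range_km,
                      family = scenario$structure_name) *
      scenario$noise_sd_gddreq
    gdd_true <- scenario$gddreq_mean + noise
    if (!is.null(z)) {
      gdd_true <- gdd_true + scenario$gddreq_scale * as.vector(z %*% coefs)
    }
    gdd_true <- pmax(gdd_true, 0)

    # per-year LU: first day the cumulative GDD curve reaches the requirement
    dd <- order_site_date(daily)
    site_levels <- unique(dd$s_id)
    obs <- vector("list", length(scenario$years))
    req <- gdd_true[match(site_levels, sites$s_id)]
    for (i in seq_along(scenario$years)) {
      y <- scenario$years[i]
      sel <- dd$year == y
      tm <- matrix(dd$tmean[sel], ncol = length(site_levels))
      gdd <- apply(pmax(tm - 5, 0), 2, cumsum)
      idx <- colSums(sweep(gdd, 2, req, "<")) + 1L
      idx[idx > nrow(gdd)] <- NA_integer_
      lu <- idx + as.integer(round(stats::rnorm(length(idx), 0,
                                                scenario$noise_sd_lu)))
      lu <- pmin(pmax(lu, 1L), nrow(gdd))
      obs[[i]] <- tibble::tibble(s_id = site_levels, year = y, day = lu)
    }
    observations <- dplyr::bind_rows(obs)
    n_missing <- sum(is.na(observations$day))
    if (n_missing > 0) {
      message(n_missing, " site-year(s) never reached their heat requirement",
              " and were dropped")
      observations <- observations[!is.na(observations$day), ]
    }
    observations <- dplyr::arrange(
      dplyr::inner_join(
        observations,
        sites[, c("s_id", "lon", "lat", "alt", "species")],
        by = "s_id"
      )[, c("s_id", "lon", "lat", "alt", "species", "year", "day")],
      .data$s_id, .data$year
    )

    ground_truth <- tibble::tibble(s_id = sites$s_id, gdd_req_true = gdd_true)
    if (!is.null(z)) {
      for (v in colnames(z)) ground_truth[[paste0("z_", v)]] <- z[, v]
    }
    attr(ground_truth, "coefficients") <- coefs
    attr(ground_truth, "structure_name") <- scenario$structure_name
    attr(ground_truth, "spatial_range_km") <- scenario$spatial_range_km
    attr(ground_truth, "gddreq_scale") <- scenario$gddreq_scale
    list(observations = observations, ground_truth = ground_truth)
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper chaining [simulate_site_network()],
#' [simulate_daily_climate()] and [simulate_lu_observations()].
#'
#' @param scenario A [phenology_scenario()].
#' @return A list of class `pheno_study`: `scenario`, `sites`, `climate`,
#'   `observations`, `ground_truth`.
#' @export
#' @examples
#' \donttest{
#' sc <- phenology_scenario(n_sites = 40, years = 2001:2008, seed = 7)
#' study <- simulate_phenology_study(sc)
#' head(study$observations)
#' }
simulate_phenology_study <- function(scenario) {
  sites <- simulate_site_network(scenario)
  climate <- simulate_daily_climate(sites, scenario)
  lu <- simulate_lu_observations(sites, climate, scenario)
  structure(
    list(scenario = scenario, sites = sites, climate = climate,
         observations = lu$observations, ground_truth = lu$ground_truth),
    class = "pheno_study"
  )
}

#' @export
print.pheno_study <- function(x, ...) {
  cat("<pheno_study>\n")
  print(x$scenario)
  cat("  observations:", nrow(x$observations), "LU records\n")
  invisible(x)
}
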