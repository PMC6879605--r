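#' Define a synthetic phenology study scenario
#'
#' A scenario bundles every parameter of the synthetic site-network generator:
#' the size and spatial layout of the network, the statistical structure of the
#' background-climate fields, and the adaptive thermal-time mechanism that
#' produces leaf-unfolding (LU) dates. The generating rule is the classic
#' growing-degree-day model — LU is the first day on which accumulated degree
#' days (daily mean temperature above 5 degC, from 1 January) reach the site's
#' heat requirement — but the heat requirement itself varies across sites as a
#' linear function of standardized long-term background covariates plus a
#' spatially correlated residual, emulating adaptation of buds to local
#' background climate.
#'
#' @param n_sites Number of sites (>= 2).
#' @param years Integer vector of observation years (default 1970:2016, the
#'   period the package's analyses summarise).
#' @param seed Integer seed; identical scenarios with identical seeds reproduce
#'   byte-identical outputs.
#' @param lon_range,lat_range Bounding box of the site network, decimal degrees.
#' @param elev_range_m Range of site elevations (m); elevations are drawn
#'   skewed towards the low end, as in lowland-dominated observation networks.
#' @param spatial_range_km Length scale (km) of the spatial autocorrelation of
#'   climate-normal anomalies and of the heat-requirement residual field.
#' @param lapse_rate Temperature lapse rate, degC per km (default 6.4).
#' @param gddreq_coefficients Named numeric vector of effect sizes (in units of
#'   `gddreq_scale` degC-days per standard deviation of the covariate) linking
#'   the site heat requirement to standardized background covariates. Allowed
#'   names: TP, TG, SWP, SWG, LWP, LWG, PP, PG, SMP, SMG.
#' @param gddreq_mean Network-mean heat requirement (degC-days).
#' @param gddreq_scale Scale (degC-days) multiplying `gddreq_coefficients`.
#' @param noise_sd_gddreq Standard deviation (degC-days) of the spatially
#'   correlated residual of the site heat requirement.
#' @param noise_sd_lu Standard deviation (days) of additive integer-rounded
#'   Gaussian observation noise on LU dates.
#' @param structure_name Spatial correlation family of the heat-requirement
#'   residual field: one of "exponential", "gaussian", "spherical",
#'   "rational_quadratic", "linear", "independent".
#' @param species Character vector of species labels; sites are assigned labels
#'   cyclically. Labels are replicate groups sharing one mechanism.
#' @param weather Named list overriding individual generator weather constants
#'   (see [scenario_weather()]).
#'
#' @return An object of class `phenology_scenario`.
#' @seealso [simulate_phenology_study()]
#' @export
#' @examples
#' phenology_scenario(n_sites = 50, years = 2001:2010, seed = 42)
phenology_scenario <- function(n_sites = 500,
                               years = 1970:2016,
                               seed = 1L,
                               lon_range = c(4, 16),
                               lat_range = c(47, 53),
                               elev_range_m = c(0, 500),
                               spatial_range_km = 100,
                               lapse_rate = 6.4,
                               gddreq_coefficients = c(SWP = 0.5, PP = -0.3),
                               gddreq_mean = 220,
                               gddreq_scale = 60,
                               noise_sd_gddreq = 20,
                               noise_sd_lu = 2,
                               structure_name = "exponential",
                               species = "Fagus sylvatica",
                               weather = list()) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 2) {
    abort_validation("`n_sites` must be a single number >= 2")
  }
  if (length(years) < 1 || anyNA(years)) {
    abort_validation("`years` must be a non-empty integer vector")
  }
  if (noise_sd_lu < 0 || noise_sd_gddreq < 0 || spatial_range_km < 0) {
    abort_validation("variance parameters must be >= 0")
  }
  families <- c("exponential", "gaussian", "spherical", "rational_quadratic",
                "linear", "independent")
  structure_name <- match.arg(structure_name, families)
  allowed <- c("TP", "TG", "SWP", "SWG", "LWP", "LWG", "PP", "PG", "SMP", "SMG")
  if (length(gddreq_coefficients) > 0) {
    if (is.null(names(gddreq_coefficients)) ||
        !all(names(gddreq_coefficients) %in% allowed)) {
      abort_validation(paste0(
        "`gddreq_coefficients` must be named with covariates among: ",
        paste(allowed, collapse = ", ")
      ))
    }
  }
  w <- utils::modifyList(scenario_weather(), weather)
  structure(
    list(
      n_sites = as.integer(n_sites),
      years = sort(as.integer(years)),
      seed = as.integer(seed),
      lon_range = lon_range,
      lat_range = lat_range,
      elev_range_m = elev_range_m,
      spatial_range_km = spatial_range_km,
      lapse_rate = lapse_rate,
      gddreq_coefficients = gddreq_coefficients,
      gddreq_mean = gddreq_mean,
      gddreq_scale = gddreq_scale,
      noise_sd_gddreq = noise_sd_gddreq,
      noise_sd_lu = noise_sd_lu,
      structure_name = structure_name,
      species = species,
      weather = w
    ),
    class = "phenology_scenario"
  )
}

#' Generator weather constants
#'
#' Default constants of the synthetic daily-weather model: a sinusoidal annual
#' temperature cycle with a latitude gradient and elevation lapse, AR(1) daily
#' anomalies and a shared annual anomaly; shortwave radiation as top-of-
#' atmosphere irradiance times a stochastic transmissivity with spatially
#' correlated, season-specific site means; longwave radiation as a linear
#' function of temperature plus noise; precipitation as a Bernoulli-gamma
#' process with spatially correlated wetness; and a monthly soil-moisture
#' bucket driven by precipitation minus a temperature-based demand proxy.
#'
#' @return Named list of constants.
#' @export
scenario_weather <- function() {
  list(
    t_base = 11.2,        # degC annual-mean at lat0, sea level
    lat0 = 50,
    t_lat_gradient = 0.55, # degC per degree latitude
    t_amplitude = 9,      # degC seasonal half-amplitude
    t_peak_doy = 196,
    t_site_sd = 0.8,      # degC spatially correlated site anomaly
    t_year_sd = 0.8,      # degC shared annual anomaly
    t_ar1 = 0.7,
    t_innov_sd = 2.2,     # degC daily AR(1) innovation
    sw_clearness = 0.55,  # mean atmospheric transmissivity
    sw_site_sd = 0.85,    # logit-scale spatial sd of seasonal clearness
    sw_day_sd = 0.4,      # logit-scale daily clearness noise
    lw_intercept = 250,   # W m-2 at 0 degC
    lw_slope = 4,         # W m-2 per degC
    lw_noise_sd = 10,
    p_wet = 0.4,          # base wet-day probability
    wet_site_sd = 0.4,    # logit-scale spatial sd of seasonal wetness
    wet_day_mm = 5,       # mean wet-day amount, mm
    prcp_shape = 0.7,     # gamma shape of wet-day amounts
    sm_capacity_mm = 150  # soil bucket for monthly soil moisture
  )
}

#' @export
print.phenology_scenario <- function(x, ...) {
  cat("<phenology_scenario>\n")
  cat("  sites:", x$n_sites, " years:", min(x$years), "-", max(x$years),
      " seed:", x$seed, "\n")
  cat("  box: lon", paste(x$lon_range, collapse = ".."),
      " lat", paste(x$lat_range, collapse = ".."),
      " elev", paste(x$elev_range_m, collapse = ".."), "m\n")
  cat("  heat requirement:", x$gddreq_mean, "+",
      paste(sprintf("%+.2f*%s", unname(x$gddreq_coefficients),
                    names(x$gddreq_coefficients)), collapse = " "),
      sprintf("(x %g)", x$gddreq_scale),
      "+ noise sd", x$noise_sd_gddreq, "\n")
  cat("  spatial structure:", x$structure_name,
      " range:", x$spatial_range_km, "km\n")
  invisible(x)
}
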