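#' Correct gridded temperature to site elevation
#'
#' Applies a constant lapse rate to move grid-cell temperature to the site's
#' elevation: `T' = T - lapse_rate * (site_elevation - grid_elevation) / 1000`.
#' Only the temperature column is altered.
#'
#' @param series Daily climate tibble with a `tmean` column (degC).
#' @param site_elevation,grid_elevation Elevations in m (scalars, or vectors
#'   recycled along rows).
#' @param lapse_rate Lapse rate in degC per km (default 6.4).
#' @return `series` with corrected `tmean`.
#' @export
#' @examples
#' x <- tibble::tibble(tmean = c(10, 12))
#' correct_temperature(x, site_elevation = 500, grid_elevation = 0)
correct_temperature <- function(series, site_elevation, grid_elevation,
                                lapse_rate = 6.4) {
  if (any(!is.finite(site_elevation)) || any(!is.finite(grid_elevation))) {
    abort_validation("elevations must be finite")
  }
  series$tmean <- series$tmean -
    lapse_rate * (site_elevation - grid_elevation) / 1000
  series
}

#' Correct a multi-site daily series to site elevations
#'
#' Joins the site table by `s_id` and applies [correct_temperature()] with
#' each site's `alt` (true elevation) and `grid_alt` (grid-cell mean
#' elevation).
#'
#' @param daily Daily climate tibble with `s_id` and `tmean`.
#' @param sites Site tibble with `s_id`, `alt`, `grid_alt`.
#' @inheritParams correct_temperature
#' @return `daily` with corrected `tmean`.
#' @export
correct_temperature_sites <- function(daily, sites, lapse_rate = 6.4) {
  m <- match(daily$s_id, sites$s_id)
  if (anyNA(m)) abort_validation("`daily` contains sites absent from `sites`")
  correct_temperature(daily, sites$alt[m], sites$grid_alt[m], lapse_rate)
}

#' Astronomical day length
#'
#' Sunrise-to-sunset duration (centre of the solar disc crossing the
#' configured horizon elevation; no atmospheric refraction unless a negative
#' `horizon` is supplied) from the standard solar-declination / hour-angle
#' formulation, with Spencer's Fourier series for the declination. Polar day
#' and night clamp to 24 and 0 h.
#'
#' @param latitude Latitude in decimal degrees, `|latitude| <= 90`.
#' @param day_of_year Integer day of year in 1..366.
#' @param horizon Solar elevation (degrees) defining sunrise/sunset; 0 for the
#'   astronomical definition, -0.833 to emulate refraction plus solar radius.
#' @return Day length in hours, in `[0, 24]`. Vectorised over both arguments.
#' @export
#' @examples
#' day_length(50, 172)  # near the June solstice
day_length <- function(latitude, day_of_year, horizon = 0) {
  if (any(abs(latitude) > 90)) {
    abort_validation("`latitude` must lie in [-90, 90]")
  }
  if (any(day_of_year < 1 | day_of_year > 366)) {
    abort_validation("`day_of_year` must lie in 1..366")
  }
  g <- 2 * pi * (day_of_year - 1) / 365
  delta <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- latitude * pi / 180
  h0 <- horizon * pi / 180
  cosh <- (sin(h0) - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
  cosh <- pmin(pmax(cosh, -1), 1)
  24 / pi * acos(cosh)
}

#' Flag non-extreme years
#'
#' Retains years whose window value lies within `median +/- 2 * IQR` of the
#' across-year distribution; with fewer than 3 years the rule is inactive and
#' all years are retained.
#'
#' @param x Numeric vector of per-year window values.
#' @return Logical vector, `TRUE` for retained years.
#' @export
#' @examples
#' exclude_extreme_years(c(rep(10, 20), 40))
exclude_extreme_years <- function(x) {
  if (length(x) < 3) return(rep(TRUE, length(x)))
  med <- stats::median(x, na.rm = TRUE)
  iqr <- stats::IQR(x, na.rm = TRUE)
  keep <- abs(x - med) <= 2 * iqr
  keep & !is.na(x)
}

#' Long-term seasonal-window climate means
#'
#' Summarises daily climate over one of two windows, per year and then
#' averaged across years: the growing season (a fixed day-of-year window,
#' default days 180-250 inclusive) or the preseason (the 90 days ending the
#' day before a reference leaf-unfolding day, computed on real calendar dates
#' so the window may reach into the previous year). Temperature, radiation and
#' soil moisture are averaged within the window; precipitation is summed
#' within the window and the totals averaged across years. Years whose window
#' coverage is incomplete are skipped; by default years with extreme window
#' temperature (outside median +/- 2 IQR) are excluded.
#'
#' @param daily Daily climate tibble (`s_id`, `date`, `year`, `doy`, `tmean`,
#'   `prcp`, `sw`, `lw`). If `year`/`doy` are absent they are derived from
#'   `date`.
#' @param window `"growing"` or `"preseason"`.
#' @param reference_lu_doy For the preseason window: a single day of year, or
#'   a tibble (`s_id`, `median_lu`) giving each site's long-term median LU.
#' @param years Years to include (window-anchor years). Default: all years in
#'   `daily` (for the preseason, all but the first, which lacks a complete
#'   window only if data start on 1 January of the first year).
#' @param soil_moisture Optional monthly soil-moisture tibble (`s_id`, `year`,
#'   `month`, `sm`); months are expanded to days before windowing.
#' @param growing_window Length-2 integer vector of day-of-year bounds,
#'   inclusive.
#' @param preseason_days Length of the preseason window in days.
#' @param exclude_extremes Apply [exclude_extreme_years()] to each variable's
#'   per-year values before averaging.
#' @return Tibble with one row per site: `s_id`, `temp`, `sw`, `lw`, `prcp`,
#'   `sm` (NA if no soil moisture supplied), `n_years`.
#' @export
seasonal_means <- function(daily, window = c("growing", "preseason"),
                           reference_lu_doy = NULL, years = NULL,
                           soil_moisture = NULL,
                           growing_window = c(180L, 250L),
                           preseason_days = 90L,
                           exclude_extremes = TRUE) {
  window <- match.arg(window)
  if (!"year" %in% names(daily)) daily$year <- as.integer(format(daily$date, "%Y"))
  if (!"doy" %in% names(daily)) daily$doy <- as.POSIXlt(daily$date)$yday + 1L

  if (window == "growing") {
    sub <- daily[daily$doy >= growing_window[1] & daily$doy <= growing_window[2], ]
    sub$wyear <- sub$year
    expected <- growing_window[2] - growing_window[1] + 1L
  } else {
    if (is.null(reference_lu_doy)) {
      abort_validation("preseason window needs `reference_lu_doy`")
    }
    if (is.data.frame(reference_lu_doy)) {
      m <- match(daily$s_id, reference_lu_doy$s_id)
      lu <- round(reference_lu_doy$median_lu[m])
    } else {
      lu <- rep(round(reference_lu_doy[1]), nrow(daily))
    }
    # window of anchor year y covers the preseason_days days before doy(lu)
    rel_same <- daily$doy - lu                      # membership in own year
    rel_next <- daily$doy - days_in_year(daily$year) - lu  # in next year's window
    in_same <- !is.na(lu) & rel_same >= -preseason_days & rel_same <= -1
    in_next <- !is.na(lu) & rel_next >= -preseason_days & rel_next <= -1
    keep <- in_same | in_next
    sub <- daily[keep, ]
    sub$wyear <- ifelse(in_next[keep], sub$year + 1L, sub$year)
    expected <- preseason_days
  }
  if (!is.null(years)) sub <- sub[sub$wyear %in% years, ]

  if (!is.null(soil_moisture)) {
    sid_levels <- unique(c(sub$s_id, soil_moisture$s_id))
    month_sub <- as.POSIXlt(sub$date)$mon + 1L
    key_sub <- match(sub$s_id, sid_levels) * 1e6 + sub$year * 12 + month_sub
    key_sm <- match(soil_moisture$s_id, sid_levels) * 1e6 +
      soil_moisture$year * 12 + soil_moisture$month
    sub$sm <- soil_moisture$sm[match(key_sub, key_sm)]
  } else {
    sub$sm <- NA_real_
  }

  per_year <- sub |>
    dplyr::group_by(.data$s_id, .data$wyear) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      temp = mean(.data$tmean), sw = mean(.data$sw), lw = mean(.data$lw),
      prcp = sum(.data$prcp), sm = mean(.data$sm),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_days == expected)

  summarise_var <- function(x) {
    if (exclude_extremes) x <- x[exclude_extreme_years(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  per_year |>
    dplyr::group_by(.data$s_id) |>
    dplyr::summarise(
      temp = summarise_var(.data$temp),
      sw = summarise_var(.data$sw),
      lw = summarise_var(.data$lw),
      prcp = summarise_var(.data$prcp),
      sm = if (all(is.na(.data$sm))) NA_real_ else
        summarise_var(.data$sm[!is.na(.data$sm)]),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Growing-season evapotranspiration ratio (aridity index)
#'
#' A simplified Priestley-Taylor supply/demand water balance (not the full
#' SPLASH model): daily potential evapotranspiration is
#' `PET = alpha * s/(s + gamma) * Rn` converted to mm/day, with `s` the slope
#' of the saturation-vapour curve at the daily mean temperature, `gamma` the
#' psychrometric constant and `Rn` a net-radiation proxy
#' `(1 - albedo) * SW + LW_in - eps * sigma * T_K^4` clamped at zero. Actual
#' evapotranspiration is limited by a single-layer soil bucket: daily supply
#' is `supply_rate * W / capacity`, `AET = min(PET, supply, W + P)`, and the
#' bucket is updated by `W' = min(capacity, W + P - AET)` (overflow runs off).
#' The index is `sum(AET) / sum(PET)` over the growing-season window, per
#' year, averaged across years.
#'
#' @param daily Daily climate tibble (`s_id`, `date`, `tmean`, `prcp`, `sw`,
#'   `lw`).
#' @param growing_window Day-of-year bounds of the growing season, inclusive.
#' @param soil_capacity Bucket capacity in mm (default 150).
#' @param pt_alpha Priestley-Taylor coefficient (default 1.26).
#' @param albedo Surface shortwave albedo.
#' @param supply_rate Maximum supply rate at a full bucket, mm/day.
#' @param initial_fraction Initial bucket fill as a fraction of capacity.
#' @return Tibble `s_id`, `alpha_e`, `n_years`; `alpha_e` is NA where the
#'   growing-season PET sum is zero.
#' @export
alpha_e <- function(daily, growing_window = c(180L, 250L),
                    soil_capacity = 150, pt_alpha = 1.26, albedo = 0.17,
                    supply_rate = 25.2, initial_fraction = 1) {
  if (!"year" %in% names(daily)) daily$year <- as.integer(format(daily$date, "%Y"))
  if (!"doy" %in% names(daily)) daily$doy <- as.POSIXlt(daily$date)$yday + 1L
  d <- order_site_date(daily)
  sids <- unique(d$s_id)
  n <- length(sids)
  nd <- nrow(d) / n
  if (nd != round(nd)) {
    abort_validation("all sites must share the same daily date coverage")
  }
  tm <- matrix(d$tmean, nrow = nd)
  sw <- matrix(d$sw, nrow = nd)
  lw <- matrix(d$lw, nrow = nd)
  pr <- matrix(d$prcp, nrow = nd)
  doy <- d$doy[seq_len(nd)]
  yr <- d$year[seq_len(nd)]

  pet <- pet_priestley_taylor(tm, sw, lw, pt_alpha = pt_alpha, albedo = albedo)
  wtr <- rep(initial_fraction * soil_capacity, n)
  aet <- matrix(0, nd, n)
  for (i in seq_len(nd)) {
    supply <- supply_rate * wtr / soil_capacity
    a <- pmin(pet[i, ], supply, wtr + pr[i, ])
    wtr <- pmin(soil_capacity, wtr + pr[i, ] - a)
    aet[i, ] <- a
  }
  in_gw <- doy >= growing_window[1] & doy <= growing_window[2]
  pet_y <- rowsum(pet[in_gw, , drop = FALSE], yr[in_gw])
  aet_y <- rowsum(aet[in_gw, , drop = FALSE], yr[in_gw])
  ratio <- ifelse(pet_y > 0, aet_y / pet_y, NA_real_)
  tibble::tibble(
    s_id = sids,
    alpha_e = colMeans(ratio, na.rm = TRUE),
    n_years = colSums(!is.na(ratio))
  )
}

# Daily Priestley-Taylor PET in mm/day from matrices of temperature (degC)
# and incoming short/longwave radiation (W m-2).
pet_priestley_taylor <- function(tmean, sw, lw, pt_alpha = 1.26,
                                 albedo = 0.17) {
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))   # kPa
  s <- 4098 * es / (tmean + 237.3)^2                    # kPa / degC
  gamma <- 0.0665
  rn <- pmax((1 - albedo) * sw + lw - 0.98 * 5.67e-8 * (tmean + 273.15)^4, 0)
  pmax(pt_alpha * s / (s + gamma) * rn * 0.0864 / 2.45, 0)
}

#' Assemble per-site long-term background-climate predictors
#'
#' Computes the full predictor set used by the spatial regression: preseason
#' and growing-season long-term means of temperature (TP, TG), shortwave (SWP,
#' SWG) and longwave (LWP, LWG) radiation, window precipitation totals (PP,
#' PG), soil moisture (SMP, SMG), day length at the site's median LU date
#' (DL), and the growing-season evapotranspiration ratio (alpha_e). The
#' preseason is the 90 days ending the day before each site's long-term
#' median LU.
#'
#' @param daily Daily climate tibble with lapse-corrected `tmean`.
#' @param sites Site tibble (`s_id`, `lat`).
#' @param median_lu Tibble (`s_id`, `median_lu`), e.g. from
#'   [summarize_sites()].
#' @param soil_moisture Monthly soil-moisture tibble (`s_id`, `year`, `month`,
#'   `sm`), or NULL.
#' @param years Years over which normals are computed.
#' @inheritParams seasonal_means
#' @inheritParams alpha_e
#' @return Tibble with one row per site in `median_lu`: `s_id`, `TP`, `TG`,
#'   `SWP`, `SWG`, `LWP`, `LWG`, `PP`, `PG`, `SMP`, `SMG`, `DL`, `alpha_e`.
#' @export
climate_normals <- function(daily, sites, median_lu, soil_moisture = NULL,
                            years = NULL, growing_window = c(180L, 250L),
                            preseason_days = 90L, exclude_extremes = TRUE,
                            soil_capacity = 150) {
  pre <- seasonal_means(daily, "preseason", reference_lu_doy = median_lu,
                        years = years, soil_moisture = soil_moisture,
                        growing_window = growing_window,
                        preseason_days = preseason_days,
                        exclude_extremes = exclude_extremes)
  grw <- seasonal_means(daily, "growing", years = years,
                        soil_moisture = soil_moisture,
                        growing_window = growing_window,
                        exclude_extremes = exclude_extremes)
  ae <- alpha_e(daily, growing_window = growing_window,
                soil_capacity = soil_capacity)
  out <- median_lu[, c("s_id", "median_lu")]
  out$DL <- day_length(sites$lat[match(out$s_id, sites$s_id)],
                       round(out$median_lu))
  pre_m <- match(out$s_id, pre$s_id)
  grw_m <- match(out$s_id, grw$s_id)
  ae_m <- match(out$s_id, ae$s_id)
  tibble::tibble(
    s_id = out$s_id,
    TP = pre$temp[pre_m], TG = grw$temp[grw_m],
    SWP = pre$sw[pre_m], SWG = grw$sw[grw_m],
    LWP = pre$lw[pre_m], LWG = grw$lw[grw_m],
    PP = pre$prcp[pre_m], PG = grw$prcp[grw_m],
    SMP = pre$sm[pre_m], SMG = grw$sm[grw_m],
    DL = out$DL,
    alpha_e = ae$alpha_e[ae_m]
  )
}
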