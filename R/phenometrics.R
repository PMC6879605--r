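#' Cumulative growing-degree-day series
#'
#' Accumulates `max(T - threshold, 0)` from day `t0` onwards:
#' `GDD_d = sum_{t0..d} max(T_d - threshold, 0)`. Days before `t0` contribute
#' zero and the returned series is zero there. A day exactly at the threshold
#' contributes zero.
#'
#' @param temps Numeric vector of daily mean temperatures (degC) for one year;
#'   element `i` is day-of-year `i`.
#' @param t0 Day of year at which accumulation starts (default 1, 1 January).
#' @param threshold Base temperature in degC (default 5).
#' @return Numeric vector of the same length: the cumulative degree-day
#'   series, non-decreasing from `t0`.
#' @export
#' @examples
#' gdd_series(rep(10, 5))  # 5, 10, 15, 20, 25
gdd_series <- function(temps, t0 = 1L, threshold = 5) {
  if (t0 < 1 || t0 > length(temps)) {
    abort_validation("`t0` must index into `temps`")
  }
  if (anyNA(temps[t0:length(temps)])) {
    abort_validation("`temps` has missing days after `t0`; no gap-filling")
  }
  inc <- pmax(temps - threshold, 0)
  inc[seq_len(t0 - 1L)] <- 0
  cumsum(inc)
}

#' Heat requirement at the observed leaf-unfolding date
#'
#' Reads the cumulative growing-degree-day curve at the observed LU day: the
#' heat requirement is the accumulated forcing on the day leaves unfold.
#'
#' @param lu_doy Observed LU day of year.
#' @param gdd Cumulative series from [gdd_series()].
#' @param t0 Accumulation start day used to build `gdd`.
#' @return Heat requirement in degC-days.
#' @export
estimate_gdd_req <- function(lu_doy, gdd, t0 = 1L) {
  if (lu_doy < t0) abort_validation("`lu_doy` precedes the accumulation start")
  if (lu_doy > length(gdd)) abort_validation("`lu_doy` is outside the series")
  gdd[lu_doy]
}

#' Predict the leaf-unfolding date from a heat requirement
#'
#' Forward application of the thermal-time rule: the predicted LU day is the
#' first day on which the cumulative degree-day curve reaches the
#' requirement.
#'
#' @param gdd_req Heat requirement in degC-days (>= 0).
#' @param gdd Cumulative series from [gdd_series()].
#' @param t0 Accumulation start day used to build `gdd`.
#' @return Day of year, or `NA_integer_` if the requirement is never reached.
#' @export
predict_lu <- function(gdd_req, gdd, t0 = 1L) {
  if (gdd_req < 0) abort_validation("`gdd_req` must be >= 0")
  n <- length(gdd)
  if (t0 > n) abort_validation("`t0` must index into `gdd`")
  hit <- which(gdd[t0:n] >= gdd_req)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(t0 + hit[1] - 1L)
}

#' Count chilling days in a temperature record
#'
#' Number of days with mean temperature inside the chilling band, endpoints
#' inclusive (`low <= T <= high`). Days below the band (frost) and above it
#' do not count.
#'
#' @param temps Numeric vector of daily mean temperatures covering the window
#'   of interest, with no gaps.
#' @param low,high Band limits in degC (defaults 0 and 5).
#' @return Integer count.
#' @export
count_chilling_days <- function(temps, low = 0, high = 5) {
  if (anyNA(temps)) abort_validation("gap in temperature coverage")
  sum(temps >= low & temps <= high)
}

#' Number of chilling days before leaf unfolding
#'
#' Counts days with mean temperature in `[low, high]` from 1 November of the
#' year preceding leaf unfolding through the LU date, both endpoints
#' inclusive.
#'
#' @param daily Daily tibble for one site with `date` and `tmean`.
#' @param lu_year Calendar year of the LU observation.
#' @param lu_doy LU day of year.
#' @param low,high Chilling band in degC.
#' @return Integer count of chilling days.
#' @export
ncd <- function(daily, lu_year, lu_doy, low = 0, high = 5) {
  start <- as.Date(paste0(lu_year - 1L, "-11-01"))
  end <- as.Date(paste0(lu_year, "-01-01")) + (lu_doy - 1L)
  sel <- daily$date >= start & daily$date <= end
  n_expected <- as.integer(end - start) + 1L
  if (sum(sel) != n_expected) {
    abort_validation("daily record does not fully cover 1 Nov .. LU date")
  }
  count_chilling_days(daily$tmean[sel], low = low, high = high)
}

#' Site-level phenology summaries with retention filters
#'
#' Computes, for every (site, species), the long-term medians of LU date,
#' per-year heat requirement and per-year chilling days, after applying the
#' retention filters: LU observations outside the plausible spring window
#' (default days 80-152, two interquartiles around the network median) are
#' dropped as responses to extreme events, and sites are retained only with
#' more than `min_years - 1` remaining observations (default: more than 5,
#' i.e. at least 6). The heat-requirement median is the median of per-year
#' requirements, not the requirement at the median LU.
#'
#' @param observations LU tibble (`s_id`, `species`, `year`, `day`); a
#'   `species` column is optional.
#' @param daily Daily climate tibble with lapse-corrected `tmean` (`s_id`,
#'   `date`, `year`, `doy`).
#' @param t0 GDD accumulation start day of year.
#' @param threshold GDD base temperature, degC.
#' @param lu_window Inclusive day-of-year window outside which LU
#'   observations are dropped.
#' @param min_years Minimum retained years for a site to be kept.
#' @param chill_band Chilling band in degC.
#' @return Tibble with one row per retained (site, species): `s_id`,
#'   `species`, `median_lu`, `median_gddreq`, `median_ncd`, `n_years`,
#'   `sd_lu`, `sd_gddreq`. Sites failing the filters are absent.
#' @export
summarize_sites <- function(observations, daily, t0 = 1L, threshold = 5,
                            lu_window = c(80L, 152L), min_years = 6L,
                            chill_band = c(0, 5)) {
  obs <- observations
  if (!"species" %in% names(obs)) obs$species <- "all"
  obs <- obs[obs$day >= lu_window[1] & obs$day <= lu_window[2], ]
  obs <- obs |>
    dplyr::group_by(.data$s_id, .data$species) |>
    dplyr::filter(dplyr::n() >= min_years) |>
    dplyr::ungroup()
  if (nrow(obs) == 0) {
    return(tibble::tibble(
      s_id = character(), species = character(), median_lu = numeric(),
      median_gddreq = numeric(), median_ncd = numeric(), n_years = integer(),
      sd_lu = numeric(), sd_gddreq = numeric()
    ))
  }

  if (!"year" %in% names(daily)) daily$year <- as.integer(format(daily$date, "%Y"))
  if (!"doy" %in% names(daily)) daily$doy <- as.POSIXlt(daily$date)$yday + 1L
  keep_sites <- unique(obs$s_id)
  d <- daily[daily$s_id %in% keep_sites, ]
  d <- order_site_date(d)

  # cumulative forcing and chilling within each site-year
  d <- d |>
    dplyr::group_by(.data$s_id, .data$year) |>
    dplyr::mutate(
      gdd = cumsum(pmax(.data$tmean - threshold, 0) * (.data$doy >= t0)),
      cum_chill = cumsum(.data$tmean >= chill_band[1] &
                           .data$tmean <= chill_band[2])
    ) |>
    dplyr::ungroup()

  # chilling days accumulated in Nov-Dec, keyed to the following spring
  novdec <- d |>
    dplyr::filter(.data$doy > days_in_year(.data$year) - 61L) |>
    dplyr::group_by(.data$s_id, .data$year) |>
    dplyr::summarise(
      chill_nd = sum(.data$tmean >= chill_band[1] &
                       .data$tmean <= chill_band[2]),
      n_nd = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(spring_year = .data$year + 1L)

  at_lu <- dplyr::inner_join(
    obs, d[, c("s_id", "year", "doy", "gdd", "cum_chill")],
    by = c("s_id", "year", day = "doy")
  )
  at_lu <- dplyr::left_join(
    at_lu, novdec[, c("s_id", "spring_year", "chill_nd", "n_nd")],
    by = c("s_id", year = "spring_year")
  )
  at_lu$ncd <- ifelse(!is.na(at_lu$n_nd) & at_lu$n_nd == 61L,
                      at_lu$chill_nd + at_lu$cum_chill, NA_real_)

  at_lu |>
    dplyr::group_by(.data$s_id, .data$species) |>
    dplyr::summarise(
      median_lu = stats::median(.data$day),
      median_gddreq = stats::median(.data$gdd),
      median_ncd = stats::median(.data$ncd, na.rm = TRUE),
      n_years = dplyr::n(),
      sd_lu = stats::sd(.data$day),
      sd_gddreq = stats::sd(.data$gdd),
      .groups = "drop"
    )
}
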