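test_that("lapse correction follows the configured gradient exactly", {
  x <- make_daily(2005, tmean = 10)
  up <- correct_temperature(x, site_elevation = 500, grid_elevation = 0)
  expect_equal(unique(up$tmean), 10 - 3.2)
  same <- correct_temperature(x, site_elevation = 300, grid_elevation = 300)
  expect_identical(same$tmean, x$tmean)
  down <- correct_temperature(x, site_elevation = 0, grid_elevation = 250)
  expect_equal(unique(down$tmean), 11.6)
  # linearity: +dh then -dh restores the series exactly
  back <- correct_temperature(correct_temperature(x, 700, 0), 0, 700)
  expect_equal(back$tmean, x$tmean, tolerance = 1e-12)
  expect_error(correct_temperature(x, NaN, 0),
               class = "phenospace_validation_error")
})

test_that("day length matches equatorial, equinox and hemispheric symmetries", {
  expect_equal(day_length(0, 80), 12, tolerance = 0.2)
  expect_equal(day_length(0, 172), 12, tolerance = 0.2)
  expect_equal(day_length(50, 80), 12, tolerance = 0.3)
  # same declination: DL(lat) + DL(-lat) = 24 h exactly
  for (d in c(20, 100, 172, 300)) {
    expect_equal(day_length(50, d) + day_length(-50, d), 24,
                 tolerance = 1e-9)
  }
  # polar clamps
  expect_equal(day_length(85, 172), 24)
  expect_equal(day_length(85, 355), 0)
  expect_error(day_length(95, 100), class = "phenospace_validation_error")
  expect_error(day_length(50, 0), class = "phenospace_validation_error")
})

test_that("day length agrees with the geosphere reference under its horizon convention", {
  skip_if_not_installed("geosphere")
  for (lat in c(-40, 0, 30, 50, 60)) {
    for (d in c(15, 80, 172, 266, 355)) {
      expect_equal(day_length(lat, d, horizon = -0.833),
                   geosphere::daylength(lat, d), tolerance = 0.1)
    }
  }
})

test_that("seasonal windows cover exactly the documented day ranges", {
  # tmean equal to the day of year exposes the window bounds through the mean
  x <- make_daily(2005:2007)
  x$tmean <- as.numeric(x$doy)
  grw <- seasonal_means(x, "growing")
  expect_equal(grw$temp, mean(180:250))
  pre <- seasonal_means(x, "preseason", reference_lu_doy = 120)
  expect_equal(pre$temp, mean(30:119))
  # constant series: both windows return the constant
  y <- make_daily(2005:2007, tmean = 8)
  expect_equal(seasonal_means(y, "growing")$temp, 8)
  expect_equal(seasonal_means(y, "preseason", reference_lu_doy = 120)$temp, 8)
  # 2 mm every day: growing-season total = 71 days x 2 mm
  z <- make_daily(2005:2007, prcp = 2)
  expect_equal(seasonal_means(z, "growing")$prcp, 142)
})

test_that("seasonal means are invariant to permuting input rows", {
  x <- make_daily(2005:2007)
  x$tmean <- sin(x$doy / 20) * 10
  x$prcp <- (x$doy %% 7 == 0) * 3
  set.seed(1)
  shuffled <- x[sample(nrow(x)), ]
  expect_equal(seasonal_means(x, "growing"),
               seasonal_means(shuffled, "growing"))
})

test_that("extreme-year rule drops only far outliers and stays inactive below 3 years", {
  expect_true(all(exclude_extreme_years(rep(5, 10))))
  ordinary <- 10 + rep(c(-0.5, -0.25, 0, 0.25, 0.5), 4)
  vals <- c(ordinary, median(ordinary) + 10 * IQR(ordinary))
  keep <- exclude_extreme_years(vals)
  expect_false(keep[21])
  expect_true(all(keep[1:20]))
  expect_true(all(exclude_extreme_years(c(1, 100))))
})

test_that("evapotranspiration ratio hits its supply and demand limits", {
  wet <- make_daily(2005, tmean = 15, prcp = 20, sw = 250, lw = 320)
  expect_equal(alpha_e(wet)$alpha_e, 1.0)
  dry <- make_daily(2005, tmean = 15, prcp = 0, sw = 250, lw = 320)
  expect_equal(alpha_e(dry, initial_fraction = 0)$alpha_e, 0.0)
})

test_that("evapotranspiration ratio matches an independent day-by-day bucket oracle", {
  set.seed(3)
  x <- make_daily(2005:2006)
  n <- nrow(x)
  x$tmean <- 10 + 9 * cos(2 * pi * (x$doy - 196) / 365.25) + rnorm(n, 0, 2)
  x$sw <- pmax(rnorm(n, 180, 60), 0)
  x$lw <- 250 + 4 * x$tmean
  x$prcp <- ifelse(runif(n) < 0.3, rgamma(n, 0.7, scale = 6), 0)

  got <- alpha_e(x)$alpha_e

  # scalar re-implementation of the documented water balance
  cap <- 150; w <- cap
  pet_day <- function(t, sw, lw) {
    es <- 0.6108 * exp(17.27 * t / (t + 237.3))
    s <- 4098 * es / (t + 237.3)^2
    rn <- max((1 - 0.17) * sw + lw - 0.98 * 5.67e-8 * (t + 273.15)^4, 0)
    max(1.26 * s / (s + 0.0665) * rn * 0.0864 / 2.45, 0)
  }
  pet <- aet <- numeric(n)
  for (i in seq_len(n)) {
    pet[i] <- pet_day(x$tmean[i], x$sw[i], x$lw[i])
    supply <- 25.2 * w / cap
    aet[i] <- min(pet[i], supply, w + x$prcp[i])
    w <- min(cap, w + x$prcp[i] - aet[i])
  }
  in_gw <- x$doy >= 180 & x$doy <= 250
  per_year <- vapply(unique(x$year), function(y) {
    s <- in_gw & x$year == y
    sum(aet[s]) / sum(pet[s])
  }, numeric(1))
  expect_equal(got, mean(per_year), tolerance = 1e-9)
})

test_that("evapotranspiration ratio is non-decreasing in precipitation", {
  set.seed(4)
  x <- make_daily(2005, tmean = 16, sw = 230, lw = 320)
  x$prcp <- rgamma(nrow(x), 0.7, scale = 2)
  lo <- alpha_e(x)$alpha_e
  x2 <- x; x2$prcp <- x$prcp * 3
  hi <- alpha_e(x2)$alpha_e
  expect_gte(hi, lo)
})

test_that("climate normals assemble the full predictor set", {
  sc <- tiny_scenario(n_sites = 8, years = 2005:2007, seed = 9)
  st <- suppressMessages(simulate_phenology_study(sc))
  daily <- correct_temperature_sites(st$climate$daily, st$sites)
  sm <- summarize_sites(st$observations, daily, min_years = 2)
  nm <- climate_normals(daily, st$sites, sm[, c("s_id", "median_lu")],
                        soil_moisture = st$climate$soil, years = sc$years)
  expect_setequal(names(nm), c("s_id", "TP", "TG", "SWP", "SWG", "LWP",
                               "LWG", "PP", "PG", "SMP", "SMG", "DL",
                               "alpha_e"))
  expect_true(all(nm$alpha_e >= 0 & nm$alpha_e <= 1, na.rm = TRUE))
  expect_true(all(is.finite(nm$TG)))
  expect_true(all(nm$TG > nm$TP, na.rm = TRUE))
})
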