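test_that("scenario validation rejects degenerate inputs", {
  expect_error(phenology_scenario(n_sites = 0),
               class = "phenospace_validation_error")
  expect_error(phenology_scenario(n_sites = 10, years = integer()),
               class = "phenospace_validation_error")
  expect_error(phenology_scenario(n_sites = 10, noise_sd_lu = -1),
               class = "phenospace_validation_error")
  expect_error(phenology_scenario(n_sites = 10,
                                  gddreq_coefficients = c(BOGUS = 1)),
               class = "phenospace_validation_error")
})

test_that("identical scenario and seed reproduce identical outputs", {
  sc <- tiny_scenario(n_sites = 25, seed = 42)
  a <- suppressMessages(simulate_phenology_study(sc))
  b <- suppressMessages(simulate_phenology_study(sc))
  expect_identical(a$sites, b$sites)
  expect_identical(a$climate$daily, b$climate$daily)
  expect_identical(a$observations, b$observations)
  expect_identical(a$ground_truth$gdd_req_true, b$ground_truth$gdd_req_true)
})

test_that("minimal network has distinct coordinates", {
  sites <- simulate_site_network(tiny_scenario(n_sites = 2))
  expect_equal(nrow(sites), 2)
  expect_false(sites$lon[1] == sites$lon[2] && sites$lat[1] == sites$lat[2])
  expect_true(all(sites$alt >= 0))
})

test_that("daily climate covers the real calendar including leap years", {
  sc <- tiny_scenario(n_sites = 3, years = 2003:2004, seed = 2)
  sites <- simulate_site_network(sc)
  cl <- simulate_daily_climate(sites, sc)
  per_site <- table(cl$daily$s_id)
  # one preceding year (2002, 365 d) + 2003 (365) + 2004 (366, leap)
  expect_true(all(per_site == 365 + 365 + 366))
  expect_true(all(cl$daily$prcp >= 0))
  expect_true(all(cl$daily$sw >= 0))
  expect_true(all(diff(cl$daily$date[cl$daily$s_id == sites$s_id[1]]) == 1))
  expect_true(all(cl$soil$sm >= 0 & cl$soil$sm <= 1))
})

test_that("with all noise off temperature is exactly the deterministic cycle", {
  sc <- tiny_scenario(
    n_sites = 2, years = 2005:2005, seed = 3,
    weather = list(t_ar1 = 0, t_innov_sd = 0, t_year_sd = 0, t_site_sd = 0)
  )
  sites <- simulate_site_network(sc)
  cl <- simulate_daily_climate(sites, sc)
  w <- sc$weather
  one <- cl$daily[cl$daily$s_id == sites$s_id[1], ]
  expected <- w$t_base - w$t_lat_gradient * (sites$lat[1] - w$lat0) -
    sc$lapse_rate * sites$grid_alt[1] / 1000 +
    w$t_amplitude * cos(2 * pi * (one$doy - w$t_peak_doy) / 365.25)
  expect_equal(one$tmean, expected, tolerance = 1e-12)
})

test_that("a 1000 m elevation difference shifts mean temperature by -6.4 degC", {
  sc <- tiny_scenario(
    n_sites = 2, years = 2005:2005, seed = 4,
    weather = list(t_ar1 = 0, t_innov_sd = 0, t_year_sd = 0, t_site_sd = 0)
  )
  sites <- simulate_site_network(sc)
  sites$lon <- c(10, 10); sites$lat <- c(50, 50)
  sites$grid_alt <- c(0, 1000)
  cl <- simulate_daily_climate(sites, sc)
  m <- tapply(cl$daily$tmean, cl$daily$s_id, mean)
  expect_equal(unname(m[sites$s_id[2]] - m[sites$s_id[1]]), -6.4,
               tolerance = 1e-9)
})

test_that("degenerate mechanism gives one shared heat requirement", {
  sc <- tiny_scenario(n_sites = 10, years = 2005:2006, seed = 5,
                      gddreq_coefficients = numeric(),
                      noise_sd_gddreq = 0, noise_sd_lu = 0)
  st <- suppressMessages(simulate_phenology_study(sc))
  expect_true(all(st$ground_truth$gdd_req_true == sc$gddreq_mean))
})

test_that("positive SWP coefficient with zero noise makes r(GDDreq*, SWP) = 1", {
  sc <- tiny_scenario(n_sites = 12, years = 2005:2006, seed = 6,
                      gddreq_coefficients = c(SWP = 0.5),
                      noise_sd_gddreq = 0, noise_sd_lu = 0)
  st <- suppressMessages(simulate_phenology_study(sc))
  expect_equal(cor(st$ground_truth$gdd_req_true, st$ground_truth$z_SWP), 1,
               tolerance = 1e-12)
})

test_that("noise-free round trip recovers the true requirement within one day's increment", {
  sc <- tiny_scenario(n_sites = 8, years = 2005:2006, seed = 7,
                      gddreq_coefficients = numeric(),
                      noise_sd_gddreq = 0, noise_sd_lu = 0)
  st <- suppressMessages(simulate_phenology_study(sc))
  daily <- correct_temperature_sites(st$climate$daily, st$sites)
  req <- st$ground_truth$gdd_req_true
  for (i in seq_len(nrow(st$observations))) {
    ob <- st$observations[i, ]
    temps <- daily$tmean[daily$s_id == ob$s_id & daily$year == ob$year]
    g <- gdd_series(temps)
    r_hat <- estimate_gdd_req(ob$day, g)
    r_true <- req[st$ground_truth$s_id == ob$s_id]
    expect_gte(r_hat, r_true)
    if (ob$day > 1) expect_lt(g[ob$day - 1], r_true)
  }
})

test_that("generated spatial residuals show range-dependent semivariogram structure", {
  base <- list(n_sites = 120, years = 2005:2005,
               gddreq_coefficients = numeric(), noise_sd_gddreq = 25)
  sc_sp <- do.call(tiny_scenario, c(base, list(seed = 8, spatial_range_km = 300)))
  sc_iid <- do.call(tiny_scenario, c(base, list(seed = 8, spatial_range_km = 0)))
  st_sp <- suppressMessages(simulate_phenology_study(sc_sp))
  st_iid <- suppressMessages(simulate_phenology_study(sc_iid))
  sv <- function(st) {
    gt <- st$ground_truth
    sites <- st$sites
    empirical_semivariogram(gt$gdd_req_true, sites$lon, sites$lat,
                            n_bins = 6)
  }
  v_sp <- sv(st_sp); v_iid <- sv(st_iid)
  # correlated field: near-distance semivariance well below the far bins
  expect_lt(v_sp$gamma[1], 0.6 * mean(v_sp$gamma[5:6]))
  # iid field: flat within sampling error
  expect_gt(v_iid$gamma[1], 0.6 * mean(v_iid$gamma[5:6]))
})
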