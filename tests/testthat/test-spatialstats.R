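test_that("collinearity screen flags duplicated information and rejects constants", {
  set.seed(21)
  x <- tibble::tibble(a = rnorm(50))
  x$b <- x$a
  x$c <- rnorm(50)
  out <- correlation_screen(x)
  ab <- out[out$var1 == "a" & out$var2 == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$flagged)
  expect_error(correlation_screen(tibble::tibble(a = rnorm(10), k = rep(1, 10))),
               regexp = "k", class = "phenospace_validation_error")
  # independent columns at large n: nothing flagged
  y <- tibble::as_tibble(as.data.frame(matrix(rnorm(10000 * 4), ncol = 4)))
  expect_false(any(correlation_screen(y)$flagged))
  expect_true(all(abs(correlation_screen(y)$r) < 0.05))
})

test_that("elastic net shrinks to empty under a huge penalty and to least squares near zero", {
  set.seed(22)
  n <- 300
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 4), ncol = 4)))
  names(x) <- paste0("x", 1:4)
  y <- 1.5 * x$x1 - 0.8 * x$x3 + rnorm(n, 0, 0.5)
  expect_warning(out <- elastic_net_select(x, y, lambda = 1e6))
  expect_equal(nrow(out), 0)
  near0 <- elastic_net_select(x, y, lambda = 1e-8)
  ols <- coef(lm(y ~ ., data = cbind(x, y = y)))[-1]
  expect_equal(near0$coefficient[match(names(ols), near0$predictor)],
               unname(ols), tolerance = 1e-2)
})

test_that("elastic net recovers a strong single signal among decoys", {
  set.seed(23)
  n <- 500
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 9), ncol = 9)))
  names(x) <- c("x1", paste0("d", 1:8))
  y <- 2 * x$x1 + rnorm(n, 0, 0.1)
  sel <- elastic_net_select(x, y, seed = 23)
  expect_true("x1" %in% sel$predictor)
})

test_that("variance inflation factors match their closed forms", {
  set.seed(20)
  n <- 200
  # exactly orthogonal, mean-centred pair via QR against the intercept
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), ncol = 2))))[, 2:3]
  expect_equal(unname(vif(data.frame(a = q[, 1], b = q[, 2]))), c(1, 1),
               tolerance = 1e-10)
  # sample correlation exactly 0.9: VIF = 1 / (1 - 0.81)
  x2 <- 0.9 * q[, 1] + sqrt(1 - 0.81) * q[, 2]
  v <- vif(data.frame(a = q[, 1], b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  # perfect collinearity reports Inf, not an error
  expect_equal(unname(vif(data.frame(a = q[, 1], b = 2 * q[, 1]))),
               c(Inf, Inf))
  expect_error(vif(data.frame(a = rnorm(5))),
               class = "phenospace_validation_error")
})

test_that("VIF equals the diagonal of the inverse correlation matrix", {
  set.seed(24)
  for (i in 1:20) {
    n <- 60
    base <- matrix(rnorm(n * 5), ncol = 5)
    base[, 2] <- base[, 1] * 0.7 + base[, 2] * 0.5
    base[, 4] <- base[, 3] * -0.6 + base[, 4] * 0.6
    x <- as.data.frame(scale(base))
    expect_equal(unname(vif(x)), unname(diag(solve(cor(base)))),
                 tolerance = 1e-10)
  }
})

test_that("stepwise VIF removes the weakest collinear predictor and terminates", {
  set.seed(25)
  n <- 400
  z <- rnorm(n)
  x <- tibble::tibble(
    good = z + rnorm(n, 0, 0.3),
    bad = z + rnorm(n, 0, 0.3),
    other = rnorm(n)
  )
  y <- x$good + rnorm(n, 0, 0.4)   # y tracks "good", not "bad"
  red <- step_vif(x, y)
  expect_true("good" %in% names(red))
  expect_false("bad" %in% names(red))
  log <- attr(red, "removals")
  expect_equal(log$removed, "bad")
  # all VIF below threshold: untouched
  w <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 3), ncol = 3)))
  expect_equal(names(step_vif(w, rnorm(n))), names(w))
  # three mutually collinear predictors terminate in at most p - 1 removals
  v <- tibble::tibble(a = z + rnorm(n, 0, 0.1), b = z + rnorm(n, 0, 0.1),
                      c = z + rnorm(n, 0, 0.1))
  red3 <- step_vif(v, z)
  expect_lte(nrow(attr(red3, "removals")), 2)
  if (ncol(red3) >= 2) expect_true(all(vif(red3) <= 4))
})

test_that("semivariogram is zero for identical residuals and flat for white noise", {
  set.seed(26)
  co <- random_coords(80)
  v0 <- empirical_semivariogram(rep(3, 80), co$lon, co$lat, n_bins = 5)
  expect_true(all(v0$gamma[v0$n_pairs > 0] == 0))
  res <- rnorm(500, 0, 2)
  co2 <- random_coords(500)
  v <- empirical_semivariogram(res, co2$lon, co2$lat, n_bins = 8)
  keep <- v$n_pairs > 100
  expect_true(all(abs(v$gamma[keep] - 4) / 4 < 0.35))
  expect_error(empirical_semivariogram(rnorm(5), runif(5), runif(5)),
               class = "phenospace_validation_error")
})

test_that("independent-structure GLS equals ordinary least squares", {
  set.seed(27)
  n <- 120
  co <- random_coords(n)
  x <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  y <- 1 + 0.5 * x$a - 0.2 * x$b + rnorm(n)
  g <- gls_fit(x, y, co, "independent")
  ols <- coef(lm(y ~ a + b, data = cbind(x, y = y)))
  expect_equal(unname(g$coefficients[c("(Intercept)", "a", "b")]),
               unname(ols[c("(Intercept)", "a", "b")]), tolerance = 1e-8)
})

test_that("exponential structure with vanishing range converges to OLS", {
  set.seed(28)
  n <- 100
  co <- random_coords(n)
  x <- tibble::tibble(a = rnorm(n))
  y <- 2 * x$a + rnorm(n)
  g <- gls_fit(x, y, co, "exponential", nugget = FALSE, fixed_range = 1e-4)
  ols <- coef(lm(y ~ a, data = cbind(x, y = y)))
  expect_equal(unname(g$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("structure selection minimises AIC over converged fits", {
  set.seed(32)
  n <- 60
  co <- random_coords(n)
  x <- tibble::tibble(a = rnorm(n))
  y <- x$a + rnorm(n)
  f_ind <- gls_fit(x, y, co, "independent")
  f_exp <- gls_fit(x, y, co, "exponential", nugget = FALSE)
  best <- select_structure(list(f_ind, f_exp))
  expect_equal(best$aic, min(f_ind$aic, f_exp$aic))
  # a lone converged candidate wins by default
  expect_equal(select_structure(list(f_exp))$family, "exponential")
  # nothing converged: an informative error
  broken <- f_exp
  broken$converged <- FALSE
  expect_error(select_structure(list(broken)),
               class = "phenospace_fit_error")
})

test_that("importance decomposition matches closed forms and sums to R2", {
  set.seed(29)
  n <- 150
  co <- random_coords(n)
  # single predictor: share equals the model R2
  x1 <- tibble::tibble(a = rnorm(n))
  y1 <- 0.8 * x1$a + rnorm(n)
  imp1 <- relative_importance(gls_fit(x1, y1, co, "independent"))
  expect_equal(imp1$share, attr(imp1, "r2"), tolerance = 1e-10)
  # two orthogonal, centred predictors: share_j = r(x_j, y)^2
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), ncol = 2))))[, 2:3] *
    sqrt(n - 1)
  x2 <- tibble::tibble(a = q[, 1], b = q[, 2])
  y2 <- 0.6 * x2$a - 0.3 * x2$b + rnorm(n, 0, 0.7)
  imp2 <- relative_importance(gls_fit(x2, y2, co, "independent"))
  expect_equal(imp2$share, c(cor(x2$a, y2)^2, cor(x2$b, y2)^2),
               tolerance = 1e-8)
  expect_equal(sum(imp2$share), attr(imp2, "r2"), tolerance = 1e-10)
  # shares stay non-negative and sum to R2 under correlated predictors
  z <- rnorm(n)
  x3 <- tibble::tibble(a = z + rnorm(n, 0, 0.5), b = z + rnorm(n, 0, 0.5),
                       c = rnorm(n))
  y3 <- x3$a + 0.5 * x3$c + rnorm(n)
  imp3 <- relative_importance(gls_fit(x3, y3, co, "independent"))
  expect_true(all(imp3$share >= 0))
  expect_equal(sum(imp3$share), attr(imp3, "r2"), tolerance = 1e-6)
})

test_that("importance guards against combinatorial explosion", {
  set.seed(30)
  n <- 40
  co <- random_coords(n)
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 16), ncol = 16)))
  y <- rnorm(n)
  expect_error(relative_importance(gls_fit(x, y, co, "independent")),
               class = "phenospace_validation_error")
})

test_that("bootstrap intervals are deterministic, validated, and tighten with n", {
  set.seed(31)
  make_model <- function(n) {
    co <- random_coords(n)
    x <- tibble::tibble(a = rnorm(n), b = rnorm(n))
    y <- x$a + 0.4 * x$b + rnorm(n, 0, 0.05)
    gls_fit(x, y, co, "independent")
  }
  m <- make_model(100)
  expect_error(bootstrap_importance_ci(m, n_boot = 99),
               class = "phenospace_validation_error")
  ci1 <- bootstrap_importance_ci(m, n_boot = 100, seed = 5)
  ci2 <- bootstrap_importance_ci(m, n_boot = 100, seed = 5)
  expect_identical(ci1, ci2)
  big <- bootstrap_importance_ci(make_model(900), n_boot = 100, seed = 5)
  expect_lt(mean(big$ci_hi - big$ci_lo), mean(ci1$ci_hi - ci1$ci_lo))
})
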