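#' Assemble a standardized design matrix for the spatial regression
#'
#' Joins site phenology summaries with climate normals, selects a response
#' (median LU or median heat requirement) and the candidate predictor set,
#' drops rows with any missing cell, and standardizes every predictor to mean
#' 0 and sd 1 (recording the scaling). The heat requirement never appears as
#' a predictor when it is the response; for the LU response the predictor set
#' additionally contains `GDDreq` and both responses share `NCD`.
#'
#' @param summaries Tibble from [summarize_sites()].
#' @param normals Tibble from [climate_normals()].
#' @param sites Site tibble with `s_id`, `lon`, `lat`.
#' @param response `"median_lu"` or `"median_gddreq"`.
#' @param predictors Optional character vector restricting the predictor set.
#' @return List of class `pheno_design`: `x` (standardized predictor tibble),
#'   `y` (response vector), `coords` (tibble `lon`, `lat`), `s_id`,
#'   `response`, `scaling` (tibble `predictor`, `mean`, `sd`).
#' @export
build_design_matrix <- function(summaries, normals, sites,
                                response = c("median_lu", "median_gddreq"),
                                predictors = NULL) {
  response <- match.arg(response)
  df <- dplyr::inner_join(summaries, normals, by = "s_id")
  df$NCD <- df$median_ncd
  df$GDDreq <- df$median_gddreq
  base_preds <- c("NCD", "TP", "TG", "SWP", "SWG", "LWP", "LWG",
                  "PP", "PG", "SMP", "SMG", "DL", "alpha_e")
  if (response == "median_lu") base_preds <- c("GDDreq", base_preds)
  preds <- predictors %||% base_preds
  if (response == "median_gddreq" && "GDDreq" %in% preds) {
    abort_validation("the heat requirement cannot predict itself")
  }
  cols <- c("s_id", response, preds)
  m <- match(df$s_id, sites$s_id)
  df$lon <- sites$lon[m]
  df$lat <- sites$lat[m]
  df <- df[stats::complete.cases(df[, c(cols, "lon", "lat")]), ]

  keep <- vapply(preds, function(p) stats::sd(df[[p]]) > 0, logical(1))
  if (any(!keep)) {
    message("dropping constant predictor(s): ",
            paste(preds[!keep], collapse = ", "))
    preds <- preds[keep]
  }
  x <- df[, preds]
  scaling <- tibble::tibble(
    predictor = preds,
    mean = vapply(x, mean, numeric(1)),
    sd = vapply(x, stats::sd, numeric(1))
  )
  x <- tibble::as_tibble(lapply(x, function(v) as.vector(scale(v))))
  structure(
    list(x = x, y = df[[response]], coords = df[, c("lon", "lat")],
         s_id = df$s_id, response = response, scaling = scaling),
    class = "pheno_design"
  )
}

#' @export
print.pheno_design <- function(x, ...) {
  cat("<pheno_design> response:", x$response, " n:", length(x$y),
      " predictors:", paste(names(x$x), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise collinearity screen
#'
#' Pearson correlations between all predictor pairs; pairs at or above the
#' threshold are flagged. The screen is diagnostic: removal authority rests
#' with the elastic net and the VIF stepwise stage.
#'
#' @param x Tibble/data frame of numeric predictors (>= 3 rows).
#' @param threshold Absolute correlation at or above which a pair is flagged.
#' @return Tibble (`var1`, `var2`, `r`, `flagged`), one row per pair, with
#'   the full correlation matrix as attribute `"matrix"`.
#' @export
correlation_screen <- function(x, threshold = 0.7) {
  if (inherits(x, "pheno_design")) x <- x$x
  if (nrow(x) < 3) abort_validation("need at least 3 rows")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    abort_validation(paste0("zero-variance predictor(s): ",
                            paste(names(x)[sds == 0], collapse = ", ")))
  }
  cm <- stats::cor(as.matrix(x))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = rownames(cm)[idx[, 1]],
    var2 = colnames(cm)[idx[, 2]],
    r = cm[idx],
    flagged = abs(cm[idx]) >= threshold
  )
  attr(out, "matrix") <- cm
  out
}

#' Elastic-net predictor selection
#'
#' Selects predictors with nonzero coefficients in a penalized elastic-net
#' regression. By default the penalty is chosen by k-fold cross-validation
#' with the one-standard-error rule; a fixed `lambda` bypasses the
#' cross-validation. Folds are drawn deterministically from `seed`.
#'
#' @param x Standardized predictor tibble or matrix.
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso; default 0.5).
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty.
#' @param rule `"1se"` (default) or `"min"`: which cross-validated penalty to
#'   use.
#' @return Tibble (`predictor`, `coefficient`) of the nonzero coefficients at
#'   the chosen penalty (empty, with a warning, if everything is shrunk
#'   away); the penalty is attached as attribute `"lambda"`.
#' @export
elastic_net_select <- function(x, y, alpha = 0.5, nfolds = 10, seed = 1L,
                               lambda = NULL, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  xm <- as.matrix(x)
  if (is.null(lambda)) {
    nfolds <- max(3L, min(nfolds, floor(length(y) / 3)))
    foldid <- with_preserved_seed(seed, {
      sample(rep_len(seq_len(nfolds), length(y)))
    })
    cv <- glmnet::cv.glmnet(xm, y, alpha = alpha, foldid = foldid,
                            standardize = FALSE)
    lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xm, y, alpha = alpha, standardize = FALSE)
  }
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = xm, y = y,
                              alpha = alpha, standardize = FALSE))[-1, 1]
  sel <- cf[cf != 0]
  if (length(sel) == 0) {
    warning("elastic net shrank every predictor to zero")
  }
  out <- tibble::tibble(predictor = names(sel), coefficient = unname(sel))
  attr(out, "lambda") <- lambda
  out
}

#' Variance inflation factors
#'
#' For each predictor `j`, regresses it on all other predictors and returns
#' `VIF_j = 1 / (1 - R_j^2)`. Perfect collinearity yields `Inf` rather than
#' an error.
#'
#' @param x Tibble/data frame/matrix of >= 2 numeric predictors, with more
#'   rows than columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  p <- ncol(x)
  if (p < 2) abort_validation("need at least 2 predictors")
  if (nrow(x) <= p) abort_validation("need more rows than predictors")
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, as.matrix(x[, -j, drop = FALSE])), x[[j]])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[[j]] - mean(x[[j]]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(x))
}

#' Stepwise VIF reduction
#'
#' Iteratively removes, among predictors whose VIF exceeds the threshold, the
#' one with the weakest absolute correlation with the response, recomputing
#' VIFs after each removal, until every VIF is at or below the threshold.
#'
#' @param x Tibble of standardized predictors.
#' @param y Response vector.
#' @param threshold VIF above which a predictor is eligible for removal
#'   (default 4).
#' @return `x` with the offending columns removed; the removal log (tibble
#'   `step`, `removed`, `vif`, `r_with_y`) is attached as attribute
#'   `"removals"`.
#' @export
step_vif <- function(x, y, threshold = 4) {
  log <- tibble::tibble(step = integer(), removed = character(),
                        vif = numeric(), r_with_y = numeric())
  step <- 0L
  while (ncol(x) >= 2) {
    v <- vif(x)
    high <- names(v)[v > threshold]
    if (length(high) == 0) break
    r <- vapply(high, function(p) stats::cor(x[[p]], y), numeric(1))
    drop <- high[which.min(abs(r))]
    step <- step + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = step, removed = drop, vif = unname(v[drop]),
      r_with_y = unname(r[drop])
    ))
    x <- x[, setdiff(names(x), drop)]
  }
  attr(x, "removals") <- log
  x
}

#' Empirical semivariogram on great-circle distances
#'
#' Bins all point pairs by great-circle distance and returns the classical
#' semivariance estimate `gamma(h) = mean(0.5 * (r_i - r_j)^2)` per bin.
#' Empty bins are returned with a pair count of 0.
#'
#' @param values Numeric vector (typically regression residuals).
#' @param lon,lat Coordinates in decimal degrees.
#' @param n_bins Number of distance bins.
#' @param max_dist Largest pair distance considered (km); default half the
#'   maximum pairwise distance.
#' @return Tibble of class `pheno_semivariogram` (`dist`, `gamma`,
#'   `n_pairs`): bin-centre distance, semivariance (NA in empty bins), pair
#'   count.
#' @export
empirical_semivariogram <- function(values, lon, lat, n_bins = 15,
                                    max_dist = NULL) {
  n <- length(values)
  if (n < 10) abort_validation("need at least 10 points")
  d <- dist_haversine_km(lon, lat)
  iu <- upper.tri(d)
  dd <- d[iu]
  sq <- 0.5 * outer(values, values, "-")[iu]^2
  max_dist <- max_dist %||% (max(dd) / 2)
  keep <- dd <= max_dist & dd > 0
  brk <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dd[keep], brk, include.lowest = TRUE, labels = FALSE)
  g <- tapply(sq[keep], factor(bin, levels = seq_len(n_bins)), mean)
  cnt <- tabulate(bin, nbins = n_bins)
  out <- tibble::tibble(
    dist = (brk[-1] + brk[-length(brk)]) / 2,
    gamma = as.numeric(g),
    n_pairs = cnt
  )
  class(out) <- c("pheno_semivariogram", class(out))
  out
}

.structure_families <- c("independent", "linear", "exponential", "spherical",
                         "gaussian", "rational_quadratic")

cor_struct_for <- function(family, init_range, nugget = TRUE) {
  value <- if (nugget) c(init_range, 0.1) else init_range
  switch(family,
    independent = NULL,
    linear = nlme::corLin(value, form = ~ x_km + y_km, nugget = nugget),
    exponential = nlme::corExp(value, form = ~ x_km + y_km, nugget = nugget),
    spherical = nlme::corSpher(value, form = ~ x_km + y_km, nugget = nugget),
    gaussian = nlme::corGaus(value, form = ~ x_km + y_km, nugget = nugget),
    rational_quadratic = nlme::corRatio(value, form = ~ x_km + y_km,
                                        nugget = nugget),
    abort_validation(paste0("unknown structure family: ", family))
  )
}

#' Spatially correlated generalized least squares fit
#'
#' Maximum-likelihood GLS of the (standardized) predictors on the response,
#' with residual correlation following one of the classical geostatistical
#' families of pairwise inter-site distance: independent, linear,
#' exponential, spherical, Gaussian or rational quadratic, with an optional
#' fitted nugget. Site coordinates are projected to planar km locally before
#' fitting. The AIC counts the regression coefficients, the residual
#' variance and the correlation parameters.
#'
#' @param x Tibble of predictors (use the output of [step_vif()]).
#' @param y Response vector.
#' @param coords Tibble with `lon`, `lat` per row.
#' @param structure_family One of `"independent"`, `"linear"`,
#'   `"exponential"`, `"spherical"`, `"gaussian"`, `"rational_quadratic"`.
#' @param nugget Fit a nugget parameter (default TRUE).
#' @param fixed_range Optional fixed correlation range (km); the range is
#'   then not estimated (used for limiting-case checks).
#' @return Object of class `pheno_gls`: `fit` (the underlying `nlme::gls`
#'   fit, or NULL), `family`, `converged`, `coefficients`, `aic`, `log_lik`,
#'   `range_km`, `nugget`, `n`, `predictors`, `data`.
#' @export
gls_fit <- function(x, y, coords, structure_family = "exponential",
                    nugget = TRUE, fixed_range = NULL) {
  structure_family <- match.arg(structure_family, .structure_families)
  df <- as.data.frame(x)
  preds <- names(df)
  df$.y <- y
  pr <- project_local_km(coords$lon, coords$lat)
  df$x_km <- pr$x_km
  df$y_km <- pr$y_km
  # identical coordinates break distance-based correlation structures
  dup <- duplicated(df[, c("x_km", "y_km")])
  if (any(dup) && structure_family != "independent") {
    df$x_km[dup] <- df$x_km[dup] + stats::runif(sum(dup), 0.05, 0.2)
    df$y_km[dup] <- df$y_km[dup] + stats::runif(sum(dup), 0.05, 0.2)
  }
  form <- stats::reformulate(c(preds, "1"), response = ".y")

  cs <- NULL
  if (structure_family != "independent") {
    init <- fixed_range %||% stats::median(
      dist_haversine_km(coords$lon, coords$lat)[upper.tri(diag(nrow(df)))]
    )
    init <- max(init, 1e-3)
    if (!is.null(fixed_range)) {
      value <- if (nugget) c(fixed_range, 0.05) else fixed_range
      cs <- switch(structure_family,
        linear = nlme::corLin(value, form = ~ x_km + y_km, nugget = nugget,
                              fixed = TRUE),
        exponential = nlme::corExp(value, form = ~ x_km + y_km,
                                   nugget = nugget, fixed = TRUE),
        spherical = nlme::corSpher(value, form = ~ x_km + y_km,
                                   nugget = nugget, fixed = TRUE),
        gaussian = nlme::corGaus(value, form = ~ x_km + y_km,
                                 nugget = nugget, fixed = TRUE),
        rational_quadratic = nlme::corRatio(value, form = ~ x_km + y_km,
                                            nugget = nugget, fixed = TRUE)
      )
    } else {
      cs <- cor_struct_for(structure_family, init, nugget = nugget)
    }
  }

  fit <- tryCatch(
    nlme::gls(form, data = df, correlation = cs, method = "ML",
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(fit = NULL, family = structure_family, converged = FALSE,
           coefficients = NULL, aic = Inf, log_lik = NA_real_,
           range_km = NA_real_, nugget = NA_real_, n = nrow(df),
           predictors = preds, data = df,
           message = conditionMessage(fit)),
      class = "pheno_gls"
    ))
  }
  range_km <- nug <- NA_real_
  if (structure_family != "independent") {
    cp <- stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)
    rn <- cp[grepl("range", names(cp), ignore.case = TRUE)]
    range_km <- if (length(rn) > 0) unname(rn[1]) else unname(cp[1])
    if (nugget && length(cp) > 1) nug <- unname(cp[length(cp)])
    if (!nugget) nug <- 0
  }
  structure(
    list(fit = fit, family = structure_family, converged = TRUE,
         coefficients = stats::coef(fit), aic = stats::AIC(fit),
         log_lik = as.numeric(stats::logLik(fit)),
         range_km = range_km, nugget = nug, n = nrow(df),
         predictors = preds, data = df),
    class = "pheno_gls"
  )
}

#' @export
print.pheno_gls <- function(x, ...) {
  cat("<pheno_gls>", x$family,
      if (!x$converged) "(not converged)" else
        sprintf("AIC %.2f  range %.1f km  nugget %.3f",
                x$aic, x$range_km, x$nugget),
      " n:", x$n, "\n")
  if (x$converged) print(round(x$coefficients, 4))
  invisible(x)
}

#' Select the best spatial correlation structure by AIC
#'
#' Among converged fits, returns the one with minimum AIC; ties are broken
#' towards fewer parameters and then a fixed family order.
#'
#' @param fits List of `pheno_gls` objects (e.g. one per candidate family).
#' @return The selected `pheno_gls`.
#' @export
select_structure <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    rlang::abort("no candidate spatial structure converged",
                 class = "phenospace_fit_error")
  }
  aic <- vapply(conv, function(f) f$aic, numeric(1))
  npar <- vapply(conv, function(f) attr(stats::logLik(f$fit), "df"),
                 numeric(1))
  fam <- vapply(conv, function(f) f$family, character(1))
  ord <- order(round(aic, 8), npar, match(fam, .structure_families))
  conv[[ord[1]]]
}

#' Relative importance of predictors in a spatial regression
#'
#' Decomposes the model's coefficient of determination into non-negative
#' per-predictor shares by LMG (Shapley-value) averaging of incremental
#' R-squared over all predictor orderings, computed on whitened data: both
#' sides of the regression are pre-multiplied by the inverse Cholesky factor
#' of the fitted spatial correlation matrix, so the decomposition is taken in
#' the metric in which the residuals are exchangeable. The shares sum to the
#' whitened-model R-squared.
#'
#' @param model A converged `pheno_gls`.
#' @return Object of class `pheno_importance`: tibble (`predictor`,
#'   `coefficient`, `share`, `share_pct_of_r2`) with attributes `r2`,
#'   `family`, `aic`, `n`, `range_km`, `nugget`.
#' @export
relative_importance <- function(model) {
  stopifnot(inherits(model, "pheno_gls"))
  if (!model$converged) {
    rlang::abort("model did not converge", class = "phenospace_fit_error")
  }
  preds <- model$predictors
  p <- length(preds)
  if (p > 15) abort_validation("more than 15 predictors: LMG is combinatorial")
  df <- model$data
  xm <- as.matrix(df[, preds, drop = FALSE])
  y <- df$.y
  n <- length(y)

  cmat <- spatial_cor_matrix(model)
  lower <- t(chol(cmat))
  ones_w <- forwardsolve(lower, rep(1, n))
  xw <- forwardsolve(lower, xm)
  yw <- forwardsolve(lower, y)

  rss_of <- function(cols) {
    q <- cbind(ones_w, xw[, cols, drop = FALSE])
    sum(stats::lm.fit(q, yw)$residuals^2)
  }
  rss0 <- rss_of(integer(0))
  nsub <- bitwShiftL(1L, p)
  rss <- numeric(nsub)
  sizes <- integer(nsub)
  for (mask in 0:(nsub - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    rss[mask + 1L] <- rss_of(cols)
    sizes[mask + 1L] <- length(cols)
  }
  r2 <- 1 - rss / rss0

  wgt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
               lfactorial(p))
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(nsub - 1L), bit) == 0L)  # masks lacking j
    inc <- r2[without + bit] - r2[without]
    shares[j] <- sum(wgt[sizes[without] + 1L] * inc)
  }
  r2_full <- r2[nsub]

  out <- tibble::tibble(
    predictor = preds,
    coefficient = unname(model$coefficients[preds]),
    share = shares,
    share_pct_of_r2 = if (r2_full > 0) 100 * shares / r2_full else
      rep(NA_real_, p)
  )
  class(out) <- c("pheno_importance", class(out))
  attr(out, "r2") <- r2_full
  attr(out, "family") <- model$family
  attr(out, "aic") <- model$aic
  attr(out, "n") <- model$n
  attr(out, "range_km") <- model$range_km
  attr(out, "nugget") <- model$nugget
  out
}

# Fitted spatial correlation matrix of a pheno_gls (identity when
# independent).
spatial_cor_matrix <- function(model) {
  n <- model$n
  if (model$family == "independent" || is.null(model$fit$modelStruct$corStruct)) {
    return(diag(n))
  }
  cs <- model$fit$modelStruct$corStruct
  cm <- nlme::corMatrix(cs)
  if (is.list(cm)) cm <- cm[[1]]
  cm
}

#' Bootstrap confidence intervals for importance shares
#'
#' Site-resampling bootstrap: sites (rows) are resampled with replacement,
#' the GLS is refitted with the selected predictors and the chosen structure
#' family held fixed (parameters re-estimated), importance shares are
#' recomputed, and percentile intervals are formed. Resampled duplicate
#' coordinates are jittered by a fraction of a km so distance-based
#' structures remain valid; degenerate replicates (a constant predictor, or
#' a failed refit) are skipped and counted.
#'
#' @param model A converged `pheno_gls`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble (`predictor`, `share`, `ci_lo`, `ci_hi`) with attribute
#'   `"n_skipped"`.
#' @export
bootstrap_importance_ci <- function(model, n_boot = 200, seed = 1L,
                                    conf = 0.95) {
  stopifnot(inherits(model, "pheno_gls"))
  if (n_boot < 100) abort_validation("`n_boot` must be >= 100")
  preds <- model$predictors
  df <- model$data
  n <- nrow(df)
  point <- relative_importance(model)
  with_preserved_seed(seed, {
    reps <- matrix(NA_real_, n_boot, length(preds))
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bd <- df[idx, ]
      if (any(vapply(bd[preds], stats::sd, numeric(1)) == 0)) {
        skipped <- skipped + 1L
        next
      }
      dup <- duplicated(bd[, c("x_km", "y_km")])
      bd$x_km[dup] <- bd$x_km[dup] + stats::runif(sum(dup), 0.05, 0.2)
      bd$y_km[dup] <- bd$y_km[dup] + stats::runif(sum(dup), 0.05, 0.2)
      refit <- gls_fit(bd[, preds, drop = FALSE], bd$.y,
                       km_to_coords(bd), structure_family = model$family)
      if (!refit$converged) {
        skipped <- skipped + 1L
        next
      }
      imp <- tryCatch(relative_importance(refit), error = function(e) NULL)
      if (is.null(imp)) {
        skipped <- skipped + 1L
        next
      }
      reps[b, ] <- imp$share[match(preds, imp$predictor)]
    }
    a <- (1 - conf) / 2
    ok <- stats::complete.cases(reps)
    out <- tibble::tibble(
      predictor = preds,
      share = point$share,
      ci_lo = apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = a),
      ci_hi = apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                    probs = 1 - a)
    )
    attr(out, "n_skipped") <- skipped
    out
  })
}

# Inverse of the local projection is not needed exactly: gls_fit reprojects,
# so hand back planar km as pseudo lon/lat on a matching scale.
km_to_coords <- function(df) {
  tibble::tibble(lon = df$x_km / 111.320, lat = df$y_km / 110.574)
}
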