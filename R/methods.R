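#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an importance decomposition
#'
#' @param x A `pheno_importance` from [relative_importance()].
#' @param ... Unused.
#' @return A tibble with one row per predictor: `predictor`, `coefficient`,
#'   `share`, `share_pct_of_r2`.
#' @export
tidy.pheno_importance <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("predictor", "coefficient", "share",
                                 "share_pct_of_r2")])
}

#' One-row summary of an importance decomposition
#'
#' @inheritParams tidy.pheno_importance
#' @return A one-row tibble: `r2`, `n_predictors`, `structure`, `aic`, `n`.
#' @export
glance.pheno_importance <- function(x, ...) {
  tibble::tibble(
    r2 = attr(x, "r2"),
    n_predictors = nrow(x),
    structure = attr(x, "family"),
    aic = attr(x, "aic"),
    n = attr(x, "n")
  )
}

#' Tidy a spatial GLS fit
#'
#' @param x A `pheno_gls` from [gls_fit()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.pheno_gls <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric(), statistic = numeric(),
                          p_value = numeric()))
  }
  tt <- summary(x$fit)$tTable
  tibble::tibble(
    term = rownames(tt),
    estimate = tt[, "Value"],
    std_error = tt[, "Std.Error"],
    statistic = tt[, "t-value"],
    p_value = tt[, "p-value"]
  )
}

#' One-row summary of a spatial GLS fit
#'
#' @inheritParams tidy.pheno_gls
#' @return A one-row tibble: `structure`, `converged`, `aic`, `log_lik`,
#'   `range_km`, `nugget`, `n`.
#' @export
glance.pheno_gls <- function(x, ...) {
  tibble::tibble(
    structure = x$family, converged = x$converged, aic = x$aic,
    log_lik = x$log_lik, range_km = x$range_km, nugget = x$nugget, n = x$n
  )
}

#' @export
print.pheno_importance <- function(x, ...) {
  cat(sprintf("<pheno_importance> R2 = %.3f (%s structure, n = %d)\n",
              attr(x, "r2"), attr(x, "family"), attr(x, "n")))
  print(tidy(x))
  invisible(x)
}

#' Plot an importance decomposition
#'
#' Horizontal bars of each predictor's share of the model R-squared, signed
#' by the direction of its GLS coefficient, with optional bootstrap
#' confidence intervals.
#'
#' @param object A `pheno_importance`.
#' @param ci Optional tibble from [bootstrap_importance_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_importance <- function(object, ci = NULL, ...) {
  df <- tidy(object)
  df$direction <- ifelse(df$coefficient >= 0, "positive", "negative")
  df$predictor <- stats::reorder(df$predictor, df$share)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$share, y = .data$predictor,
                                        fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "#c23b22",
                                          negative = "#3b6bc2")) +
    ggplot2::labs(
      x = expression("share of spatial variance (" * R^2 * ")"),
      y = NULL,
      title = sprintf("R² = %.2f (%s residual structure)",
                      attr(object, "r2"), attr(object, "family"))
    )
  if (!is.null(ci)) {
    cdf <- dplyr::left_join(df, ci[, c("predictor", "ci_lo", "ci_hi")],
                            by = "predictor")
    p <- p + ggplot2::geom_errorbarh(
      data = cdf,
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi,
                   y = .data$predictor),
      inherit.aes = FALSE, height = 0.25
    )
  }
  p
}

#' Plot an empirical semivariogram
#'
#' @param object A `pheno_semivariogram` from [empirical_semivariogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_semivariogram <- function(object, ...) {
  df <- object[object$n_pairs > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "distance (km)", y = "semivariance",
                  size = "pairs")
}

#' Plot the heat-requirement spread by aridity bin
#'
#' @param iqr_table Tibble from [gddreq_iqr_by_alpha()].
#' @return A ggplot object.
#' @export
plot_gddreq_iqr <- function(iqr_table) {
  df <- iqr_table[iqr_table$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha_mid,
                                   y = .data$iqr_gddreq)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = expression(alpha[E]),
                  y = "IQR of site heat requirement (°C-days)",
                  size = "sites")
}

#' Plot chilling versus heat requirement coloured by preseason radiation
#'
#' @param swp_table Tibble from [ncd_gddreq_swp_table()].
#' @return A ggplot object.
#' @export
plot_ncd_gddreq <- function(swp_table) {
  ggplot2::ggplot(swp_table,
                  ggplot2::aes(x = .data$ncd, y = .data$gddreq,
                               colour = .data$swp_above_median)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c23b22", `FALSE` = "#3b6bc2"),
      labels = c(`TRUE` = "above median SWP", `FALSE` = "below median SWP")
    ) +
    ggplot2::labs(x = "chilling days (NCD)",
                  y = "heat requirement (°C-days)", colour = NULL)
}
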