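#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default: the
#' thermal-time constants (GDD threshold 5 degC from 1 January; chilling band
#' 0-5 degC from 1 November), the seasonal windows (growing season days
#' 180-250; 90-day preseason), the retention filters (more than 5 years per
#' site; LU window days 80-152), the drought stratification threshold
#' (long-term alpha_e < 0.9), and the statistical settings (elastic-net
#' mixing 0.5 with 10-fold CV and the 1-SE rule; VIF threshold 4; candidate
#' spatial structures; bootstrap size; root seed).
#'
#' @param years Analysis year range.
#' @param gdd_threshold GDD base temperature (degC).
#' @param t0 GDD accumulation start day of year.
#' @param chill_band Chilling band (degC).
#' @param growing_window Growing-season day-of-year bounds, inclusive.
#' @param preseason_days Preseason window length (days).
#' @param lu_window Retained LU day-of-year window, inclusive.
#' @param min_years Minimum years per retained site.
#' @param drought_threshold Sites with long-term `alpha_e` below this are
#'   drought-prone.
#' @param en_alpha Elastic-net mixing parameter.
#' @param en_folds Cross-validation folds.
#' @param en_rule `"1se"` or `"min"` penalty rule.
#' @param vif_threshold Stepwise VIF removal threshold.
#' @param structures Candidate spatial correlation families.
#' @param n_boot Bootstrap replicates for importance CIs (0 disables the
#'   bootstrap).
#' @param min_sites Minimum sites for a (response, stratum, group) cell to be
#'   analysed.
#' @param seed Root seed; all randomness in the run flows from it.
#' @return List of class `pheno_config`.
#' @export
run_config <- function(years = 1970:2016,
                       gdd_threshold = 5, t0 = 1L, chill_band = c(0, 5),
                       growing_window = c(180L, 250L), preseason_days = 90L,
                       lu_window = c(80L, 152L), min_years = 6L,
                       drought_threshold = 0.9,
                       en_alpha = 0.5, en_folds = 10, en_rule = "1se",
                       vif_threshold = 4,
                       structures = c("independent", "exponential",
                                      "spherical", "gaussian",
                                      "rational_quadratic", "linear"),
                       n_boot = 0, min_sites = 30L, seed = 1L) {
  structure(
    list(years = years, gdd_threshold = gdd_threshold, t0 = t0,
         chill_band = chill_band, growing_window = growing_window,
         preseason_days = preseason_days, lu_window = lu_window,
         min_years = min_years, drought_threshold = drought_threshold,
         en_alpha = en_alpha, en_folds = en_folds, en_rule = en_rule,
         vif_threshold = vif_threshold,
         structures = match.arg(structures, .structure_families,
                                several.ok = TRUE),
         n_boot = n_boot, min_sites = min_sites, seed = as.integer(seed)),
    class = "pheno_config"
  )
}

#' Run the four-step importance analysis on one design
#'
#' Applies the statistical engine to an assembled design matrix: (1) pairwise
#' collinearity screen (diagnostic), (2) elastic-net predictor selection,
#' (3) stepwise VIF reduction, (4) spatially correlated GLS over the
#' candidate structure families with AIC selection, followed by the LMG
#' R-squared decomposition and (optionally) bootstrap confidence intervals.
#'
#' @param design A `pheno_design` from [build_design_matrix()].
#' @param config A [run_config()].
#' @return List of class `pheno_fit_result`: `design`, `screen`, `selected`
#'   (elastic-net table), `reduced` (post-VIF predictor names), `vif_log`,
#'   `fits` (per-family AIC tibble), `model` (`pheno_gls`), `importance`
#'   (`pheno_importance`), `ci` (or NULL), `status`.
#' @export
fit_importance <- function(design, config = run_config()) {
  stopifnot(inherits(design, "pheno_design"))
  screen <- correlation_screen(design$x)
  sel <- elastic_net_select(design$x, design$y, alpha = config$en_alpha,
                            nfolds = config$en_folds, seed = config$seed,
                            rule = config$en_rule)
  if (nrow(sel) == 0) {
    return(structure(list(design = design, screen = screen, selected = sel,
                          reduced = character(), vif_log = NULL, fits = NULL,
                          model = NULL, importance = NULL, ci = NULL,
                          status = "empty_selection"),
                     class = "pheno_fit_result"))
  }
  x_sel <- design$x[, sel$predictor, drop = FALSE]
  if (ncol(x_sel) >= 2) {
    x_red <- step_vif(x_sel, design$y, threshold = config$vif_threshold)
  } else {
    x_red <- x_sel
    attr(x_red, "removals") <- NULL
  }
  fits <- lapply(config$structures, function(fam) {
    gls_fit(x_red, design$y, design$coords, structure_family = fam)
  })
  fit_tbl <- tibble::tibble(
    family = vapply(fits, function(f) f$family, character(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  model <- select_structure(fits)
  imp <- relative_importance(model)
  ci <- NULL
  if (config$n_boot >= 100) {
    ci <- bootstrap_importance_ci(model, n_boot = config$n_boot,
                                  seed = config$seed + 17L)
  }
  structure(
    list(design = design, screen = screen, selected = sel,
         reduced = names(x_red), vif_log = attr(x_red, "removals"),
         fits = fit_tbl, model = model, importance = imp, ci = ci,
         status = "ok"),
    class = "pheno_fit_result"
  )
}

#' @export
print.pheno_fit_result <- function(x, ...) {
  cat("<pheno_fit_result>", x$design$response, "status:", x$status, "\n")
  if (!is.null(x$importance)) print(x$importance)
  invisible(x)
}

#' Run the end-to-end spatial-phenology analysis
#'
#' Orchestrates the full pipeline for a synthetic scenario or prepared
#' tables: lapse-corrects temperature, computes site phenology summaries and
#' climate normals, partitions sites into drought-prone
#' (`alpha_e < drought_threshold`) and wet strata, and runs the four-step
#' importance analysis for both responses (median LU; median heat
#' requirement) in every (stratum, group) cell with enough sites, per species
#' and pooled. Cells that fail are recorded with a reason and the remaining
#' cells proceed.
#'
#' @param data A [phenology_scenario()] (the study is generated), a
#'   `pheno_study`, or a list with elements `sites`, `observations`, and
#'   `climate` (a `pheno_climate` or a list with `daily` and `soil`).
#' @param config A [run_config()].
#' @param responses Responses to analyse.
#' @param strata Site strata to analyse.
#' @param by_species Also analyse each species separately (in addition to the
#'   pooled run).
#' @return List of class `pheno_analysis`: `results` (tibble with one row per
#'   analysed cell: `response`, `stratum`, `group`, `n_sites`, `status`,
#'   `r2`, `structure`, `aic`, and a `fit` list-column of
#'   `pheno_fit_result`), `summaries`, `normals`, `sites`, `config`.
#' @export
run_analysis <- function(data, config = run_config(),
                         responses = c("median_lu", "median_gddreq"),
                         strata = c("all", "drought", "wet"),
                         by_species = FALSE) {
  if (inherits(data, "phenology_scenario")) data <- simulate_phenology_study(data)
  sites <- data$sites
  observations <- data$observations
  climate <- data$climate
  daily <- correct_temperature_sites(climate$daily, sites)

  summaries <- summarize_sites(observations, daily, t0 = config$t0,
                               threshold = config$gdd_threshold,
                               lu_window = config$lu_window,
                               min_years = config$min_years,
                               chill_band = config$chill_band)
  normals <- climate_normals(daily, sites,
                             summaries[, c("s_id", "median_lu")],
                             soil_moisture = climate$soil,
                             years = intersect(config$years,
                                               unique(observations$year)),
                             growing_window = config$growing_window,
                             preseason_days = config$preseason_days)

  drought_ids <- normals$s_id[!is.na(normals$alpha_e) &
                                normals$alpha_e < config$drought_threshold]
  stratum_ids <- list(
    all = normals$s_id[!is.na(normals$alpha_e)],
    drought = drought_ids,
    wet = setdiff(normals$s_id[!is.na(normals$alpha_e)], drought_ids)
  )
  groups <- "pooled"
  if (by_species) groups <- c(unique(summaries$species), groups)

  cells <- expand.grid(response = responses, stratum = strata,
                       group = groups, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    keep <- summaries$s_id %in% stratum_ids[[cell$stratum]]
    if (cell$group != "pooled") keep <- keep & summaries$species == cell$group
    sm <- summaries[keep, ]
    row <- tibble::tibble(
      response = cell$response, stratum = cell$stratum, group = cell$group,
      n_sites = nrow(sm), status = NA_character_, r2 = NA_real_,
      structure = NA_character_, aic = NA_real_, fit = list(NULL)
    )
    if (nrow(sm) < config$min_sites) {
      row$status <- "too_few_sites"
      message("skipping ", cell$response, "/", cell$stratum, "/", cell$group,
              ": ", nrow(sm), " sites < ", config$min_sites)
      rows[[i]] <- row
      next
    }
    res <- tryCatch({
      design <- build_design_matrix(sm, normals, sites,
                                    response = cell$response)
      fit_importance(design, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- paste0("failed: ", conditionMessage(res))
      message("cell ", cell$response, "/", cell$stratum, "/", cell$group,
              " failed: ", conditionMessage(res))
    } else {
      row$status <- res$status
      row$fit <- list(res)
      if (!is.null(res$importance)) {
        row$r2 <- attr(res$importance, "r2")
        row$structure <- attr(res$importance, "family")
        row$aic <- attr(res$importance, "aic")
      }
    }
    rows[[i]] <- row
  }
  structure(
    list(results = dplyr::bind_rows(rows), summaries = summaries,
         normals = normals, sites = sites, config = config),
    class = "pheno_analysis"
  )
}

#' @export
print.pheno_analysis <- function(x, ...) {
  cat("<pheno_analysis>\n")
  print(x$results[, c("response", "stratum", "group", "n_sites", "status",
                      "r2", "structure")])
  invisible(x)
}

#' Heat-requirement spread by aridity bin
#'
#' Bins sites by long-term growing-season evapotranspiration ratio and
#' returns the interquartile range of the median heat requirement per bin —
#' the diagnostic of whether drought compresses the spatial variance of the
#' heat requirement.
#'
#' @param summaries Tibble from [summarize_sites()].
#' @param normals Tibble from [climate_normals()].
#' @param bin_width Bin width on the `alpha_e` axis.
#' @return Tibble (`alpha_lo`, `alpha_hi`, `alpha_mid`, `iqr_gddreq`, `n`);
#'   empty bins have `n = 0` and NA IQR.
#' @export
gddreq_iqr_by_alpha <- function(summaries, normals, bin_width = 0.05) {
  df <- dplyr::inner_join(summaries, normals, by = "s_id")
  df <- df[!is.na(df$alpha_e), ]
  lo <- floor(min(df$alpha_e) / bin_width) * bin_width
  brk <- seq(lo, max(df$alpha_e) + bin_width, by = bin_width)
  bin <- cut(df$alpha_e, brk, include.lowest = TRUE, labels = FALSE)
  n_bins <- length(brk) - 1
  out <- tibble::tibble(
    alpha_lo = brk[-length(brk)],
    alpha_hi = brk[-1],
    alpha_mid = (brk[-1] + brk[-length(brk)]) / 2,
    iqr_gddreq = as.numeric(tapply(df$median_gddreq,
                                   factor(bin, levels = seq_len(n_bins)),
                                   stats::IQR)),
    n = tabulate(bin, nbins = n_bins)
  )
  if (sum(out$n > 0) < 2) abort_validation("need at least 2 populated bins")
  out
}

#' Chilling versus heat requirement, stratified by preseason radiation
#'
#' Per-site table of median chilling days, median heat requirement and
#' preseason shortwave radiation, with a flag for sites whose SWP exceeds
#' the across-site median — the diagnostic of how background radiation
#' modulates the chilling/forcing relationship.
#'
#' @param summaries Tibble from [summarize_sites()].
#' @param normals Tibble from [climate_normals()].
#' @return Tibble (`s_id`, `ncd`, `gddreq`, `swp`, `swp_above_median`) with
#'   the SWP median as attribute `"swp_median"`.
#' @export
ncd_gddreq_swp_table <- function(summaries, normals) {
  df <- dplyr::inner_join(summaries, normals, by = "s_id")
  med <- stats::median(df$SWP, na.rm = TRUE)
  out <- tibble::tibble(
    s_id = df$s_id,
    ncd = df$median_ncd,
    gddreq = df$median_gddreq,
    swp = df$SWP,
    swp_above_median = df$SWP > med
  )
  attr(out, "swp_median") <- med
  out
}

#' Observed variability summary per species
#'
#' Intra-site (mean across sites of the within-site, across-year standard
#' deviation) and inter-site (standard deviation across sites of the site
#' medians) variability of LU and of the heat requirement, with site counts
#' and drought-prone site counts per species.
#'
#' @param observations Raw LU observation tibble (`s_id`, `species`, `year`,
#'   `day`).
#' @param summaries Tibble from [summarize_sites()].
#' @param normals Optional tibble from [climate_normals()] (needed for
#'   drought-prone counts).
#' @param lu_window LU filter window applied to the raw observations before
#'   computing intra-site spread.
#' @param drought_threshold `alpha_e` below which a site is drought-prone.
#' @return Tibble per species: `species`, `intra_site_lu_sd`,
#'   `inter_site_lu_sd`, `intra_site_gddreq_sd`, `inter_site_gddreq_sd`,
#'   `n_sites`, `n_drought`.
#' @export
table1_summary <- function(observations, summaries, normals = NULL,
                           lu_window = c(80L, 152L),
                           drought_threshold = 0.9) {
  obs <- observations
  if (!"species" %in% names(obs)) obs$species <- "all"
  obs <- obs[obs$day >= lu_window[1] & obs$day <= lu_window[2], ]
  obs <- obs[obs$s_id %in% summaries$s_id, ]
  intra <- obs |>
    dplyr::group_by(.data$species, .data$s_id) |>
    dplyr::summarise(sd_lu_obs = stats::sd(.data$day), .groups = "drop")
  drought_ids <- character()
  if (!is.null(normals)) {
    drought_ids <- normals$s_id[!is.na(normals$alpha_e) &
                                  normals$alpha_e < drought_threshold]
  }
  per_site <- dplyr::left_join(
    summaries, intra[, c("s_id", "species", "sd_lu_obs")],
    by = c("s_id", "species")
  )
  per_site |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      intra_site_lu_sd = mean(.data$sd_lu_obs, na.rm = TRUE),
      inter_site_lu_sd = if (dplyr::n() > 1)
        stats::sd(.data$median_lu) else NA_real_,
      intra_site_gddreq_sd = mean(.data$sd_gddreq, na.rm = TRUE),
      inter_site_gddreq_sd = if (dplyr::n() > 1)
        stats::sd(.data$median_gddreq) else NA_real_,
      n_sites = dplyr::n(),
      n_drought = sum(.data$s_id %in% drought_ids),
      .groups = "drop"
    )
}
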