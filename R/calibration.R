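#' Ordinary least squares fit of a season date on PYAAT
#'
#' Fits `DOY = m * PYAAT + b` by OLS across pooled station-years, with
#' classical 95% confidence intervals and the two-sided t-test p-value for
#' the slope.
#'
#' @param pyaat Predictor (K).
#' @param doy Response: observed first or last pollen day of year.
#' @param which Label only: `"start"` or `"end"`.
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `slope_ci95`, `intercept_ci95`, `p_value`, `n`, `r_squared`, `which`.
#' @export
fit_phenology_regression <- function(pyaat, doy, which = c("start", "end")) {
  which <- match.arg(which)
  new_regression_fit(pyaat, doy, which = which)
}

#' OLS fit of log annual pollen count on PYAAT
#'
#' Fits `ln(annual_count) = m_prod * PYAAT + b_prod`. A positive slope means
#' pollen production increases with warming.
#'
#' @param pyaat Predictor (K).
#' @param annual_count Observed annual total counts; all must be positive.
#' @return A `regression_fit` (slope = `m_prod`, intercept = `b_prod`) with
#'   a `direction` field (`"production increases with warming"` or
#'   `"production decreases with warming"`).
#' @export
fit_production_regression <- function(pyaat, annual_count) {
  bad <- which(!(is.finite(annual_count) & annual_count > 0))
  if (length(bad))
    stop("annual counts must be positive; offending row(s): ",
         paste(bad, collapse = ", "))
  fit <- new_regression_fit(pyaat, log(annual_count), which = "production")
  fit$direction <- if (fit$slope > 0) "production increases with warming"
                   else "production decreases with warming"
  fit
}

new_regression_fit <- function(x, y, which) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 observations to fit")
  if (stats::sd(x) == 0) stop("degenerate predictor: all PYAAT values equal")
  fit <- stats::lm(y ~ x)
  # interpolating fits are legitimate here (noise-free synthetic data);
  # silence R's perfect-fit caveat but keep any other warning
  quiet_perfect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  ci <- quiet_perfect(stats::confint(fit, level = 0.95))
  sm <- quiet_perfect(summary(fit))
  p <- if (nrow(sm$coefficients) < 2L || is.na(sm$coefficients[2L, 4L])) NA_real_
       else sm$coefficients[2L, 4L]
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_ci95 = unname(ci[2L, ]),
                 intercept_ci95 = unname(ci[1L, ]),
                 p_value = p, n = length(x),
                 r_squared = sm$r.squared, which = which),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit:%s> slope %.4g [%.4g, %.4g], intercept %.4g, p = %.3g, n = %d, R2 = %.3f\n",
              x$which, x$slope, x$slope_ci95[1], x$slope_ci95[2],
              x$intercept, x$p_value, x$n, x$r_squared))
  invisible(x)
}

#' Production normalization constant
#'
#' `P_norm = exp(m_prod * T_ref + b_prod)`: the predicted annual count at
#' the reference historical mean temperature, so the production scale at
#' that temperature cancels to exactly `P_annual`. The reference is the
#' domain historical mean PYAAT, except for the range-restricted Alnus,
#' which uses the Pacific Northwest regional mean.
#'
#' @param fit A production `regression_fit`.
#' @param reference_temperature Reference PYAAT (K).
#' @return `P_norm` (count units).
#' @export
compute_pnorm <- function(fit, reference_temperature) {
  if (!is.finite(fit$slope) || !is.finite(fit$intercept))
    stop("fit coefficients must be finite")
  exp(fit$slope * reference_temperature + fit$intercept)
}

#' Significance summary across taxa
#'
#' Flags, per taxon, whether the production-PYAAT relationship is
#' statistically significant at level `alpha` and counts the significant
#' relationships.
#'
#' @param fits Named list of `regression_fit` (one per taxon).
#' @param alpha Significance level, 0.05 by default.
#' @return List with `table` (taxon, p_value, slope, significant) and
#'   `n_significant` out of `n_taxa`.
#' @export
significance_summary <- function(fits, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tab <- data.frame(taxon = names(fits),
                    slope = vapply(fits, function(f) f$slope, 0),
                    p_value = vapply(fits, function(f) f$p_value, 0),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$p_value < alpha
  list(table = tab, n_significant = sum(tab$significant),
       n_taxa = nrow(tab), alpha = alpha)
}

#' Calibrate the full taxon parameter table from observations
#'
#' Pools station-years per taxon and fits the three regressions (season
#' start, season end, log production), then computes `P_norm` at the
#' reference temperature (PNW reference for taxa flagged `"PNW-mean"`).
#' `P_annual` and `a` are not identifiable from count observations and are
#' carried over from `literature` (a parameter table supplying `P_annual`,
#' `a`, `pft` and `T_ref_region` per taxon).
#'
#' @param observations Observation table (see
#'   [generate_pollen_observations()]).
#' @param literature Parameter table supplying the non-regression columns.
#' @param t_ref_us,t_ref_pnw Reference PYAAT (K) for `P_norm`.
#' @return List: `params` (calibrated parameter table in the standard
#'   dialect), `fits` (per taxon: start/end/production `regression_fit`),
#'   `diagnostics` (tidy data.frame of slopes, CIs, p-values, R2, n).
#' @export
calibrate_taxa <- function(observations, literature,
                           t_ref_us = 285, t_ref_pnw = 283) {
  taxa <- unique(observations$taxon)
  fits <- list(); rows <- list(); diag <- list()
  for (tx in taxa) {
    ob <- observations[observations$taxon == tx, ]
    fs <- fit_phenology_regression(ob$pyaat, ob$sdoy, "start")
    fe <- fit_phenology_regression(ob$pyaat, ob$edoy, "end")
    fp <- fit_production_regression(ob$pyaat, ob$annual_count)
    fits[[tx]] <- list(start = fs, end = fe, production = fp)
    lit <- literature[literature$taxon == tx, ]
    if (nrow(lit) != 1L) stop(sprintf("no literature row for taxon %s", tx))
    t_ref <- if (identical(lit$T_ref_region, "PNW-mean")) t_ref_pnw else t_ref_us
    rows[[tx]] <- data.frame(
      taxon = tx, pft = lit$pft,
      m_sDOY = fs$slope, b_sDOY = fs$intercept,
      m_eDOY = fe$slope, b_eDOY = fe$intercept,
      m_prod = fp$slope, b_prod = fp$intercept,
      P_annual = lit$P_annual,
      P_norm = compute_pnorm(fp, t_ref),
      a = lit$a, T_ref_region = lit$T_ref_region,
      stringsAsFactors = FALSE)
    diag[[tx]] <- data.frame(
      taxon = tx,
      which = c("start", "end", "production"),
      slope = c(fs$slope, fe$slope, fp$slope),
      slope_lo = c(fs$slope_ci95[1], fe$slope_ci95[1], fp$slope_ci95[1]),
      slope_hi = c(fs$slope_ci95[2], fe$slope_ci95[2], fp$slope_ci95[2]),
      intercept = c(fs$intercept, fe$intercept, fp$intercept),
      p_value = c(fs$p_value, fe$p_value, fp$p_value),
      r_squared = c(fs$r_squared, fe$r_squared, fp$r_squared),
      n = c(fs$n, fe$n, fp$n),
      stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  validate_params(params)
  list(params = params, fits = fits,
       diagnostics = do.call(rbind, c(diag, list(make.row.names = FALSE))))
}
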