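#' Previous-year annual average temperature (PYAAT)
#'
#' Per-cell arithmetic mean of the 365 daily temperatures of the year before
#' `year`. Pollen grains form in the year before flowering, so PYAAT is the
#' sole climatic predictor of both phenology and production.
#'
#' @param climate A `climate_grid`.
#' @param year Calendar year whose PYAAT is requested; `year - 1` must be
#'   fully present in the climate.
#' @return Numeric matrix (lat x lon) in K.
#' @export
compute_pyaat <- function(climate, year) {
  stopifnot(inherits(climate, "climate_grid"))
  if (!(year - 1L) %in% climate$years)
    stop(sprintf("cannot compute PYAAT for %d: previous year %d missing from climate",
                 year, year - 1L))
  idx <- year_time_index(climate, year - 1L)
  g <- climate$grid
  block <- matrix(climate$temperature[idx, , , drop = FALSE], 365L, n_cells(g))
  matrix(colMeans(block), g$n_lat, g$n_lon)
}

#' Pollen season start and end dates from PYAAT
#'
#' The season start and end days of year are linear in PYAAT:
#' `sDOY = m_sDOY * PYAAT + b_sDOY`, `eDOY = m_eDOY * PYAAT + b_eDOY`.
#' Dates are kept real-valued; rounding is for display only, so small
#' temperature differences are not quantized away.
#'
#' @param params One row of a taxon parameter table.
#' @param pyaat PYAAT in K; scalar, vector or matrix.
#' @param check If `TRUE` (default) a degenerate season (`eDOY <= sDOY`
#'   anywhere) is an error; gridded callers use `check = FALSE` and mask
#'   degenerate cells instead.
#' @return List with `sdoy` and `edoy`, each shaped like `pyaat`.
#' @export
phenology_dates <- function(params, pyaat, check = TRUE) {
  sdoy <- params$m_sDOY * pyaat + params$b_sDOY
  edoy <- params$m_eDOY * pyaat + params$b_eDOY
  if (check && any(edoy <= sdoy))
    stop(sprintf("degenerate season for taxon %s: eDOY <= sDOY at some PYAAT",
                 params$taxon %||% "?"))
  list(sdoy = sdoy, edoy = edoy)
}

#' Gaussian seasonal emission weights
#'
#' The daily phenology factor is a Gaussian in day of year,
#' `gamma_phen(t) = exp(-(t - mu)^2 / (2 sigma^2))`, with mean
#' `mu = (sDOY + eDOY) / 2` and width `sigma = (eDOY - sDOY) / a`. With the
#' default width divisor `a = 3`, the weight at both season boundaries is
#' `exp(-a^2/8) = exp(-1.125)`. The Gaussian is evaluated on all 365 days of
#' the no-leap year (no truncation outside the season window, no wraparound);
#' tails beyond the year edges are clipped by that evaluation range.
#'
#' @param sdoy,edoy Season start/end day of year (real-valued);
#'   `edoy > sdoy` required.
#' @param a Width divisor (> 0), 3 by default.
#' @return An object of class `phenology_state`: `sdoy`, `edoy`, `mu`,
#'   `sigma` and the length-365 weight vector `gamma`.
#' @examples
#' ph <- gaussian_phenology(80, 140)
#' ph$gamma[110]          # 1 at the season mean
#' @export
gaussian_phenology <- function(sdoy, edoy, a = 3) {
  if (a <= 0) stop("width divisor a must be > 0")
  if (edoy <= sdoy) stop("degenerate season: eDOY must exceed sDOY")
  mu <- (sdoy + edoy) / 2
  sigma <- (edoy - sdoy) / a
  if (sigma <= 0) stop("sigma must be > 0")
  t <- seq_len(365L)
  structure(list(sdoy = sdoy, edoy = edoy, mu = mu, sigma = sigma,
                 gamma = exp(-(t - mu)^2 / (2 * sigma^2))),
            class = "phenology_state")
}

#' Evaluate the seasonal weight at arbitrary (real) days
#'
#' @param phen A [gaussian_phenology()] state.
#' @param t Day of year, real-valued.
#' @return `exp(-(t - mu)^2 / (2 sigma^2))`.
#' @export
phenology_weight <- function(phen, t) {
  exp(-(t - phen$mu)^2 / (2 * phen$sigma^2))
}

#' Temperature-dependent annual production scale
#'
#' Scales the literature annual production to the simulated climate:
#' `S = exp(m_prod * PYAAT + b_prod) / P_norm * P_annual` (grains m-2 yr-1).
#' `P_norm` is the predicted count at the reference historical temperature,
#' so at that temperature `S` equals `P_annual` exactly.
#'
#' @param params One row of a taxon parameter table.
#' @param pyaat PYAAT in K; scalar, vector or matrix.
#' @return Production scale shaped like `pyaat`, strictly positive.
#' @export
production_scale <- function(params, pyaat) {
  expo <- params$m_prod * pyaat + params$b_prod
  if (any(!is.finite(expo)))
    stop("non-finite production exponent (check m_prod, b_prod, PYAAT)")
  exp(expo) / params$P_norm * params$P_annual
}

#' Daily emission amplitude from the annual production scale
#'
#' Converts the annual production `S` into the daily amplitude
#' `pf_annual = S / sum_t gamma_phen(t)` so that the precipitation-free
#' annual emission sum equals `A * S * gamma_CO2` exactly: phenology shifts
#' redistribute emission within the year but leave the integrated total
#' unchanged. Because the normalizing sum runs over days 1..365, seasons
#' clipped at the year edges remain conservative.
#'
#' @param S Annual production scale (grains m-2 yr-1).
#' @param phen A [gaussian_phenology()] state.
#' @return Daily amplitude `pf_annual` (grains m-2 d-1).
#' @export
daily_amplitude <- function(S, phen) {
  total <- sum(phen$gamma)
  if (total <= 0) stop("sum of seasonal weights must be positive")
  S / total
}

#' Precipitation scavenging switch
#'
#' Days whose precipitation strictly exceeds 5 mm d-1 lose all emission
#' (weight 0); all other days are unaffected (weight 1). Equality at the
#' threshold keeps the day.
#'
#' @param pr Precipitation (mm d-1), any shape; must be non-negative.
#' @param threshold Cutoff intensity (mm d-1).
#' @return 0/1 weights shaped like `pr`.
#' @export
precipitation_factor <- function(pr, threshold = 5) {
  if (any(pr < 0)) stop("precipitation must be non-negative")
  ifelse(pr > threshold, 0, 1)
}

#' CO2 fertilization factor
#'
#' Production multiplier for the CO2 sensitivity run: 1 with CO2 effects
#' off, 2 under the doubled-production assumption for end-of-century CO2.
#'
#' @param mode `"off"` or `"doubled"`.
#' @return 1 or 2.
#' @export
co2_factor <- function(mode) {
  switch(match.arg(mode, c("off", "doubled")), off = 1, doubled = 2)
}
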