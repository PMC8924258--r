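#' Simulate daily pollen emission for one taxon
#'
#' Runs the emission model over the grid for the requested years. For each
#' cell and year: PYAAT from the previous year's daily temperature, season
#' dates from the phenology regressions, the Gaussian seasonal weights, the
#' production scale, and the daily amplitude; the daily emission flux is
#' `E_pol = A * pf_annual * gamma_phen * gamma_precip * gamma_CO2`
#' (grains m-2 d-1) with `A` the taxon's land-cover fraction. Cells with a
#' degenerate season (`eDOY <= sDOY`) are masked (`NA`), counted and
#' reported via a message rather than aborting the run.
#'
#' @param params One row of a taxon parameter table.
#' @param climate A `climate_grid`.
#' @param landcover A `landcover_map` containing the taxon.
#' @param co2_mode `"off"` or `"doubled"`.
#' @param years Years to simulate; defaults to all climate years after the
#'   first. Every simulated year needs its predecessor in the climate.
#' @param quiet Suppress the masked-cell message.
#' @return An object of class `emission_field`: `e_pol` array
#'   (time, lat, lon) over `365 * length(years)` days, plus provenance
#'   (`taxon`, `years`, `grid`, `co2_mode`, `scenario`, `member`) and the
#'   masked-cell count `n_masked`.
#' @examples
#' g <- grid_spec(4, 5)
#' cl <- generate_climate(g, scenario_config("hist", years = 2000:2002), seed = 1)
#' lc <- generate_landcover(g, "Quercus", seed = 1, fill = 0.5)
#' pars <- generate_taxon_params(1)
#' ef <- simulate_taxon(pars[pars$taxon == "Quercus", ], cl, lc)
#' dim(ef$e_pol)
#' @export
simulate_taxon <- function(params, climate, landcover,
                           co2_mode = c("off", "doubled"), years = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(climate, "climate_grid"), inherits(landcover, "landcover_map"))
  if (nrow(params) != 1L) stop("params must be a single taxon row")
  co2_mode <- match.arg(co2_mode)
  g <- climate$grid
  if (g$n_lat != landcover$grid$n_lat || g$n_lon != landcover$grid$n_lon)
    stop("climate and land cover are on different grids")
  if (is.null(years)) years <- climate$years[-1L]
  if (!all((years - 1L) %in% climate$years))
    stop("every simulated year needs its preceding year in the climate")

  A <- landcover_fraction(landcover, params$taxon)
  nc <- n_cells(g)
  gco2 <- co2_factor(co2_mode)
  tvec <- seq_len(365L)
  e_pol <- array(0, dim = c(365L * length(years), g$n_lat, g$n_lon))
  n_masked <- 0L

  for (iy in seq_along(years)) {
    py <- compute_pyaat(climate, years[iy])
    ph <- phenology_dates(params, py, check = FALSE)
    sdoy <- as.vector(ph$sdoy); edoy <- as.vector(ph$edoy)
    bad <- !(edoy > sdoy)
    n_masked <- n_masked + sum(bad)
    mu <- (sdoy + edoy) / 2
    sigma <- (edoy - sdoy) / params$a
    sigma[bad] <- NA_real_

    # 365 x ncell seasonal weights; year-edge tails are clipped by the
    # evaluation range and the normalization uses the clipped sum.
    G <- exp(-sweep(outer(tvec, mu, "-")^2, 2L, 2 * sigma^2, "/"))
    S <- production_scale(params, as.vector(py))
    pf <- S / colSums(G)

    pr <- matrix(climate$precipitation[year_time_index(climate, years[iy]), , ,
                                       drop = FALSE], 365L, nc)
    gp <- precipitation_factor(pr)
    amp <- as.vector(A) * pf * gco2
    block <- G * rep(amp, each = 365L) * gp
    block[, bad] <- NA_real_
    block[, as.vector(A) == 0 & !bad] <- 0
    e_pol[(iy - 1L) * 365L + tvec, , ] <- array(block, dim = c(365L, g$n_lat, g$n_lon))
  }

  if (n_masked > 0L && !quiet)
    message(sprintf("simulate_taxon(%s): %d cell-year(s) masked (degenerate season)",
                    params$taxon, n_masked))
  structure(list(e_pol = e_pol, taxon = params$taxon, years = years, grid = g,
                 co2_mode = co2_mode, scenario = climate$scenario,
                 member = climate$member, n_masked = n_masked,
                 units = "grains m-2 d-1"),
            class = "emission_field")
}

#' @export
print.emission_field <- function(x, ...) {
  cat(sprintf("<emission_field> %s (%s, member %d, co2 %s): years %d-%d, %d x %d cells\n",
              x$taxon, x$scenario, x$member, x$co2_mode, min(x$years),
              max(x$years), x$grid$n_lat, x$grid$n_lon))
  invisible(x)
}

#' Simulate all taxa of a parameter table
#'
#' @inheritParams simulate_taxon
#' @param params Full taxon parameter table.
#' @return Named list of `emission_field`, one per taxon.
#' @export
simulate_all <- function(params, climate, landcover,
                         co2_mode = c("off", "doubled"), years = NULL,
                         quiet = TRUE) {
  co2_mode <- match.arg(co2_mode)
  out <- lapply(seq_len(nrow(params)), function(i)
    simulate_taxon(params[i, ], climate, landcover, co2_mode, years, quiet))
  names(out) <- params$taxon
  out
}
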