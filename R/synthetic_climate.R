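#' Generate synthetic gridded daily climate for one scenario member
#'
#' Builds daily near-surface temperature (K) and precipitation (mm d-1) on a
#' 365-day no-leap calendar. Temperature is a latitudinal mean gradient plus
#' a sinusoidal seasonal cycle, the scenario warming offset, a deterministic
#' per-member offset, an interannual year offset, and daily white noise.
#' Precipitation is a two-state wet/dry occurrence process with gamma
#' distributed (right-skewed) wet-day intensities.
#'
#' All stochastic terms are seeded from `seed` and the member index only, so
#' two scenarios that differ only in `warming_offset` share identical noise:
#' their per-cell annual means differ by exactly the offset difference.
#'
#' @param grid A [grid_spec()].
#' @param scenario A [scenario_config()]; must span at least two years so the
#'   previous-year annual average temperature (PYAAT) exists for every
#'   simulated year after the first.
#' @param member_index Ensemble member (1-based, `<= scenario$n_members`).
#' @param seed Integer seed; identical seed and configuration reproduce
#'   bit-identical fields.
#' @param mean_T Domain annual-mean temperature (K) at the grid's
#'   mid-latitude.
#' @param lat_gradient Change of annual-mean temperature per degree latitude
#'   (K per degree; negative = cooler poleward).
#' @param seasonal_amplitude Half peak-to-trough amplitude of the seasonal
#'   cycle (K); the cycle peaks near day 197 (mid-July).
#' @param noise_sd Daily white-noise standard deviation (K).
#' @param interannual_sd Standard deviation of the per-year mean offset (K).
#' @param wet_prob Probability any day is wet (0-1).
#' @param wet_mean_intensity Mean precipitation on wet days (mm d-1).
#' @param wet_shape Gamma shape of wet-day intensities (< 1 is right-skewed).
#' @return An object of class `climate_grid`: daily `temperature` and
#'   `precipitation` arrays with dimensions (time, lat, lon), the `years`
#'   covered, the grid, and a `"noleap"` calendar.
#' @examples
#' g <- grid_spec(4, 5)
#' sc <- scenario_config("hist", years = 2000:2002)
#' cl <- generate_climate(g, sc, seed = 1)
#' dim(cl$temperature)
#' @export
generate_climate <- function(grid, scenario, member_index = 1L, seed,
                             mean_T = 285, lat_gradient = -0.45,
                             seasonal_amplitude = 12,
                             noise_sd = 2, interannual_sd = 0.3,
                             wet_prob = 0.3, wet_mean_intensity = 4,
                             wet_shape = 0.7) {
  stopifnot(inherits(grid, "grid_spec"), inherits(scenario, "scenario_config"))
  member_index <- as.integer(member_index)
  if (member_index < 1L || member_index > scenario$n_members)
    stop("member_index out of range for this scenario")
  years <- scenario$years
  if (length(years) < 2L)
    stop("scenario must span at least 2 years: PYAAT cannot be formed from a single year")

  n_years <- length(years)
  n_time <- 365L * n_years
  nc <- n_cells(grid)

  # annual-mean surface: linear in latitude, constant in longitude
  lat_mid <- mean(grid$lat_bounds)
  base_mean <- mean_T + lat_gradient * (grid$lat - lat_mid)      # length n_lat
  doy <- seq_len(365L)
  seasonal <- -seasonal_amplitude * cos(2 * pi * (doy - 15) / 365) # peak ~ DOY 197

  offs <- member_offsets(scenario$n_members, scenario$member_spread)[member_index]

  # noise independent of the warming offset (shared across scenarios at equal seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 1009, member_index), kind = "Mersenne-Twister")

  year_offsets <- if (interannual_sd > 0) stats::rnorm(n_years, 0, interannual_sd)
                  else numeric(n_years)

  temp <- array(0, dim = c(n_time, grid$n_lat, grid$n_lon))
  clim_day <- outer(seasonal, base_mean, "+")                    # 365 x n_lat
  for (iy in seq_len(n_years)) {
    idx <- (iy - 1L) * 365L + doy
    block <- clim_day + scenario$warming_offset + offs + year_offsets[iy]
    temp[idx, , ] <- array(rep(block, grid$n_lon), dim = c(365L, grid$n_lat, grid$n_lon))
  }
  if (noise_sd > 0)
    temp <- temp + array(stats::rnorm(n_time * nc, 0, noise_sd), dim = dim(temp))

  wet <- stats::runif(n_time * nc) < wet_prob
  inten <- stats::rgamma(n_time * nc, shape = wet_shape,
                         scale = wet_mean_intensity / wet_shape)
  precip <- array(ifelse(wet, inten, 0), dim = dim(temp))

  structure(list(temperature = temp, precipitation = precip,
                 years = years, grid = grid, calendar = "noleap",
                 scenario = scenario$name, member = member_index,
                 co2_mode = scenario$co2_mode,
                 units = c(temperature = "K", precipitation = "mm d-1")),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s member %d: years %d-%d, %d x %d cells, calendar %s\n",
              x$scenario, x$member, min(x$years), max(x$years),
              x$grid$n_lat, x$grid$n_lon, x$calendar))
  invisible(x)
}

# Derive an independent RNG stream seed (kept below 2^31) from a user seed
# and a per-generator multiplier.
derive_seed <- function(seed, k, offset = 0L) {
  as.integer(((as.numeric(seed) %% 1000003) * k + offset) %% 2147483647)
}

# Save/restore .Random.seed so generators do not disturb the caller's RNG
# stream (generator determinism comes from the explicit seed argument).
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Time indices (rows of the daily arrays) belonging to one calendar year.
year_time_index <- function(climate, year) {
  iy <- match(year, climate$years)
  if (is.na(iy)) stop(sprintf("year %d not present in climate (years %d-%d)",
                              year, min(climate$years), max(climate$years)))
  (iy - 1L) * 365L + seq_len(365L)
}
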