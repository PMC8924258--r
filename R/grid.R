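#' Regular latitude-longitude grid specification
#'
#' Defines a regular cell-centered grid over a latitude/longitude box.
#' Longitudes are stored in degrees east, so the western hemisphere uses
#' negative values (e.g. 100 degrees W is -100).
#'
#' @param n_lat,n_lon Number of grid cells in latitude and longitude.
#' @param lat_bounds Length-2 numeric, south then north edge (degrees N).
#' @param lon_bounds Length-2 numeric, west then east edge (degrees E,
#'   negative west of Greenwich).
#' @return An object of class `grid_spec` with cell-center coordinate
#'   vectors `lat` and `lon`.
#' @examples
#' g <- grid_spec(20, 30, c(25, 48), c(-125, -70))
#' range(g$lat)
#' @export
grid_spec <- function(n_lat = 20L, n_lon = 30L,
                      lat_bounds = c(25, 48), lon_bounds = c(-125, -70)) {
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  if (n_lat < 1L || n_lon < 1L) stop("n_lat and n_lon must be >= 1")
  if (length(lat_bounds) != 2L || lat_bounds[1] >= lat_bounds[2])
    stop("lat_bounds must be ordered south -> north")
  if (length(lon_bounds) != 2L || lon_bounds[1] >= lon_bounds[2])
    stop("lon_bounds must be ordered west -> east")
  dlat <- diff(lat_bounds) / n_lat
  dlon <- diff(lon_bounds) / n_lon
  structure(list(
    n_lat = n_lat, n_lon = n_lon,
    lat_bounds = as.numeric(lat_bounds), lon_bounds = as.numeric(lon_bounds),
    lat = lat_bounds[1] + dlat * (seq_len(n_lat) - 0.5),
    lon = lon_bounds[1] + dlon * (seq_len(n_lon) - 0.5)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g] N, lon [%g, %g] E\n",
              x$n_lat, x$n_lon, x$lat_bounds[1], x$lat_bounds[2],
              x$lon_bounds[1], x$lon_bounds[2]))
  invisible(x)
}

n_cells <- function(grid) grid$n_lat * grid$n_lon

#' Climate scenario configuration
#'
#' Describes one emissions scenario for the synthetic climate generator:
#' a bulk warming offset applied on top of the historical climatology, the
#' simulated year range, whether the CO2 fertilization factor doubles pollen
#' production, and the ensemble size.
#'
#' @param name Scenario label (e.g. `"historical"`, `"moderate"`, `"high"`).
#' @param warming_offset Warming applied uniformly to daily temperature (K).
#' @param years Integer vector of consecutive calendar years to generate.
#'   At least two are required because phenology for a given year is driven
#'   by the previous-year annual average temperature (PYAAT).
#' @param co2_mode `"off"` or `"doubled"` (production multiplier 1 or 2).
#' @param n_members Ensemble size (>= 1).
#' @param member_spread Half-width (K) of the deterministic per-member
#'   temperature offset ladder spanning `[-member_spread, member_spread]`.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config("high", warming_offset = 4.5, years = 2081:2100)
#' @export
scenario_config <- function(name, warming_offset = 0, years,
                            co2_mode = c("off", "doubled"),
                            n_members = 1L, member_spread = 0) {
  co2_mode <- match.arg(co2_mode)
  years <- as.integer(years)
  if (length(years) < 1L) stop("years must be non-empty")
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  n_members <- as.integer(n_members)
  if (n_members < 1L) stop("n_members must be >= 1")
  if (member_spread < 0) stop("member_spread must be >= 0")
  structure(list(name = as.character(name),
                 warming_offset = as.numeric(warming_offset),
                 years = years, co2_mode = co2_mode,
                 n_members = n_members,
                 member_spread = as.numeric(member_spread)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: +%g K, years %d-%d, co2 %s, %d member(s)\n",
              x$name, x$warming_offset, min(x$years), max(x$years),
              x$co2_mode, x$n_members))
  invisible(x)
}

# Evenly spaced member temperature offsets in [-spread, spread]; a single
# member sits at 0 so the ensemble mean is unbiased.
member_offsets <- function(n_members, member_spread) {
  if (n_members == 1L) return(0)
  member_spread * seq(-1, 1, length.out = n_members)
}
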