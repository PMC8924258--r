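#' Generate station-level pseudo-observations of pollen seasons and counts
#'
#' Emulates a network of counting stations: for each station, taxon and year
#' (every year after the first, so PYAAT exists), the observed season start
#' and end days are the generating linear-in-PYAAT truth plus Gaussian noise,
#' and the observed annual total count is the log-linear production truth
#' plus Gaussian noise on the log scale. Station PYAAT is computed from the
#' supplied climate at the station's grid cell.
#'
#' @param truth Taxon parameter table holding the generating coefficients
#'   (see [generate_taxon_params()]).
#' @param climate A [generate_climate()] output covering at least 4 years.
#' @param n_stations Number of stations (>= 3), placed at distinct random
#'   grid cells.
#' @param noise List with `doy_sd` (days) and `logcount_sd` (natural-log
#'   units); zero gives observations exactly on the generating lines.
#' @param seed Integer seed.
#' @param stations Optional data.frame with columns `lat`, `lon` overriding
#'   random placement; positions outside the grid are an error.
#' @return A `data.frame` with columns `station`, `taxon`, `year`, `sdoy`,
#'   `edoy`, `annual_count`, `pyaat` and
#'   `n_stations * (n_years - 1) * n_taxa` rows.
#' @examples
#' g <- grid_spec(6, 8)
#' cl <- generate_climate(g, scenario_config("hist", years = 2000:2004),
#'                        seed = 2, noise_sd = 0)
#' obs <- generate_pollen_observations(generate_taxon_params(1), cl,
#'                                     n_stations = 3,
#'                                     noise = list(doy_sd = 0, logcount_sd = 0),
#'                                     seed = 3)
#' nrow(obs)
#' @export
generate_pollen_observations <- function(truth, climate, n_stations = 5L,
                                         noise = list(doy_sd = 5, logcount_sd = 0.3),
                                         seed, stations = NULL) {
  stopifnot(inherits(climate, "climate_grid"))
  validate_params(truth)
  n_stations <- as.integer(n_stations)
  if (n_stations < 3L) stop("n_stations must be >= 3")
  if (length(climate$years) < 4L)
    stop("climate must cover at least 3 years beyond the first")
  grid <- climate$grid

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 4001), kind = "Mersenne-Twister")

  if (is.null(stations)) {
    cells <- sample.int(n_cells(grid), n_stations)
    st_lat <- ((cells - 1L) %% grid$n_lat) + 1L
    st_lon <- ((cells - 1L) %/% grid$n_lat) + 1L
  } else {
    if (nrow(stations) != n_stations)
      stop("stations must have n_stations rows")
    st_lat <- findInterval(stations$lat, seq(grid$lat_bounds[1], grid$lat_bounds[2],
                                             length.out = grid$n_lat + 1L),
                           rightmost.closed = TRUE)
    st_lon <- findInterval(stations$lon, seq(grid$lon_bounds[1], grid$lon_bounds[2],
                                             length.out = grid$n_lon + 1L),
                           rightmost.closed = TRUE)
    if (any(st_lat < 1L | st_lat > grid$n_lat | st_lon < 1L | st_lon > grid$n_lon))
      stop("station position outside the climate grid")
  }

  obs_years <- climate$years[-1L]
  # station PYAAT per observation year
  pyaat_st <- matrix(0, n_stations, length(obs_years))
  for (iy in seq_along(obs_years)) {
    py <- compute_pyaat(climate, obs_years[iy])
    pyaat_st[, iy] <- py[cbind(st_lat, st_lon)]
  }

  grid_df <- expand.grid(station = seq_len(n_stations),
                         year_i = seq_along(obs_years),
                         taxon_i = seq_len(nrow(truth)))
  n <- nrow(grid_df)
  tr <- truth[grid_df$taxon_i, ]
  py <- pyaat_st[cbind(grid_df$station, grid_df$year_i)]
  doy_sd <- noise$doy_sd %||% 0
  log_sd <- noise$logcount_sd %||% 0
  sdoy <- tr$m_sDOY * py + tr$b_sDOY + stats::rnorm(n, 0, doy_sd)
  edoy <- tr$m_eDOY * py + tr$b_eDOY + stats::rnorm(n, 0, doy_sd)
  count <- exp(tr$m_prod * py + tr$b_prod + stats::rnorm(n, 0, log_sd))

  data.frame(station = grid_df$station,
             taxon = tr$taxon,
             year = obs_years[grid_df$year_i],
             sdoy = sdoy, edoy = edoy,
             annual_count = count, pyaat = py,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
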