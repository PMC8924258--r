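#' @section Text grid format:
#' Gridded fields are serialized as a plain-text container: line 1 is a JSON
#' header with the dimensions, coordinates, units and calendar; the rest is
#' a comma-separated numeric matrix (one row per leading-dimension index,
#' cells in column-major lat-fastest order). The round trip is lossless at
#' full double precision.
#' @keywords internal
#' @name pollensim-io
NULL

GRID_FORMAT_VERSION <- "pollensim-grid-1"

write_grid_file <- function(path, header, blocks) {
  header$format <- GRID_FORMAT_VERSION
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  close(con); on.exit()
  mat <- do.call(cbind, blocks)
  # 17 significant digits: exact double round trip through text
  txt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  txt[is.na(mat)] <- "NA"
  data.table::fwrite(data.table::as.data.table(txt), path, append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_grid_file <- function(path) {
  header <- jsonlite::fromJSON(readLines(path, n = 1L))
  if (!identical(header$format, GRID_FORMAT_VERSION))
    stop("not a recognized grid file: ", path)
  mat <- as.matrix(data.table::fread(path, skip = 1L, header = FALSE))
  dimnames(mat) <- NULL
  list(header = header, matrix = mat)
}

#' Write / read a climate grid
#'
#' Serializes daily temperature and precipitation with their coordinates,
#' units (`"K"`, `"mm d-1"`) and the `"noleap"` calendar to the package's
#' text grid format. Reading validates the units and calendar and restores
#' bit-identical arrays.
#'
#' @param climate A `climate_grid`.
#' @param path File path.
#' @return `write_climate` returns the path invisibly; `read_climate`
#'   returns the `climate_grid`.
#' @export
write_climate <- function(climate, path) {
  stopifnot(inherits(climate, "climate_grid"))
  g <- climate$grid
  nt <- dim(climate$temperature)[1L]
  header <- list(
    kind = "climate", n_time = nt, n_lat = g$n_lat, n_lon = g$n_lon,
    lat_bounds = g$lat_bounds, lon_bounds = g$lon_bounds,
    years = climate$years, calendar = climate$calendar,
    scenario = climate$scenario, member = climate$member,
    co2_mode = climate$co2_mode,
    units = list(temperature = "K", precipitation = "mm d-1"))
  write_grid_file(path, header,
                  list(matrix(climate$temperature, nt, n_cells(g)),
                       matrix(climate$precipitation, nt, n_cells(g))))
}

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  r <- read_grid_file(path)
  h <- r$header
  if (!identical(h$kind, "climate")) stop("file does not hold a climate grid")
  if (!identical(h$calendar, "noleap"))
    stop(sprintf("unsupported calendar '%s': the model requires 'noleap'", h$calendar))
  if (!identical(h$units$temperature, "K"))
    stop(sprintf("temperature units '%s' not accepted (need 'K')", h$units$temperature))
  if (!identical(h$units$precipitation, "mm d-1"))
    stop(sprintf("precipitation units '%s' not accepted (need 'mm d-1')",
                 h$units$precipitation))
  g <- grid_spec(h$n_lat, h$n_lon, h$lat_bounds, h$lon_bounds)
  nc <- h$n_lat * h$n_lon
  structure(list(
    temperature = array(r$matrix[, seq_len(nc)], c(h$n_time, h$n_lat, h$n_lon)),
    precipitation = array(r$matrix[, nc + seq_len(nc)], c(h$n_time, h$n_lat, h$n_lon)),
    years = as.integer(h$years), grid = g, calendar = h$calendar,
    scenario = h$scenario, member = h$member, co2_mode = h$co2_mode,
    units = c(temperature = "K", precipitation = "mm d-1")),
    class = "climate_grid")
}

#' Write / read a land-cover map
#'
#' @param landcover A `landcover_map`.
#' @param path File path.
#' @return `write_landcover` returns the path invisibly; `read_landcover`
#'   the `landcover_map`.
#' @export
write_landcover <- function(landcover, path) {
  stopifnot(inherits(landcover, "landcover_map"))
  g <- landcover$grid
  nt <- length(landcover$taxa)
  header <- list(kind = "landcover", n_taxa = nt, taxa = landcover$taxa,
                 n_lat = g$n_lat, n_lon = g$n_lon,
                 lat_bounds = g$lat_bounds, lon_bounds = g$lon_bounds,
                 units = "1")
  write_grid_file(path, header,
                  list(matrix(landcover$fraction, nt, n_cells(g))))
}

#' @rdname write_landcover
#' @export
read_landcover <- function(path) {
  r <- read_grid_file(path)
  h <- r$header
  if (!identical(h$kind, "landcover")) stop("file does not hold a land-cover map")
  if (!identical(h$units, "1"))
    stop(sprintf("land-cover units '%s' not accepted (need dimensionless '1')", h$units))
  g <- grid_spec(h$n_lat, h$n_lon, h$lat_bounds, h$lon_bounds)
  frac <- array(r$matrix, c(h$n_taxa, h$n_lat, h$n_lon),
                dimnames = list(taxon = h$taxa, NULL, NULL))
  structure(list(fraction = frac, taxa = h$taxa, grid = g, units = "1"),
            class = "landcover_map")
}

#' Write / read an emission field
#'
#' @param field An `emission_field`.
#' @param path File path.
#' @return `write_emission` returns the path invisibly; `read_emission`
#'   the `emission_field`.
#' @export
write_emission <- function(field, path) {
  stopifnot(inherits(field, "emission_field"))
  g <- field$grid
  nt <- dim(field$e_pol)[1L]
  header <- list(kind = "emission", taxon = field$taxon, n_time = nt,
                 n_lat = g$n_lat, n_lon = g$n_lon,
                 lat_bounds = g$lat_bounds, lon_bounds = g$lon_bounds,
                 years = field$years, scenario = field$scenario,
                 member = field$member, co2_mode = field$co2_mode,
                 n_masked = field$n_masked, units = "grains m-2 d-1")
  write_grid_file(path, header, list(matrix(field$e_pol, nt, n_cells(g))))
}

#' @rdname write_emission
#' @export
read_emission <- function(path) {
  r <- read_grid_file(path)
  h <- r$header
  if (!identical(h$kind, "emission")) stop("file does not hold an emission field")
  g <- grid_spec(h$n_lat, h$n_lon, h$lat_bounds, h$lon_bounds)
  structure(list(e_pol = array(r$matrix, c(h$n_time, h$n_lat, h$n_lon)),
                 taxon = h$taxon, years = as.integer(h$years), grid = g,
                 co2_mode = h$co2_mode, scenario = h$scenario,
                 member = h$member, n_masked = h$n_masked, units = h$units),
            class = "emission_field")
}

#' Write / read a taxon parameter table
#'
#' CSV dialect with header `taxon, pft, m_sDOY, b_sDOY, m_eDOY, b_eDOY,
#' m_prod, b_prod, P_annual, P_norm, a, T_ref_region`. Reading validates
#' the type invariants (positive `P_annual`, `P_norm`, `a`); unknown extra
#' columns are preserved with a warning.
#'
#' @param params Parameter table.
#' @param path File path.
#' @return `write_params` returns the path invisibly; `read_params` the
#'   validated data.frame.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  data.table::fwrite(params, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  missing <- setdiff(setdiff(param_columns(), c("pft", "T_ref_region")), names(tab))
  if (length(missing))
    stop("parameter CSV is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), param_columns())
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  validate_params(tab)
  tab
}

#' Write / read a pollen observation table
#'
#' CSV dialect with header `station, taxon, year, sdoy, edoy, annual_count,
#' pyaat`.
#'
#' @param observations Observation table.
#' @param path File path.
#' @return `write_observations` returns the path invisibly;
#'   `read_observations` the data.frame.
#' @export
write_observations <- function(observations, path) {
  need <- c("station", "taxon", "year", "sdoy", "edoy", "annual_count", "pyaat")
  missing <- setdiff(need, names(observations))
  if (length(missing))
    stop("observation table is missing column(s): ", paste(missing, collapse = ", "))
  data.table::fwrite(observations, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  need <- c("station", "taxon", "year", "sdoy", "edoy", "annual_count", "pyaat")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("observation CSV is missing column(s): ", paste(missing, collapse = ", "))
  tab
}
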