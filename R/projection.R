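#' Period-mean season metrics per cell
#'
#' For each year in the period, computes per-cell (sDOY, eDOY) from the
#' phenology regressions and PYAAT, then averages over the period's years.
#' Metrics are computed per year and then averaged, matching the 20-year
#' period-mean convention of the scenario analysis.
#'
#' @param params One row of a taxon parameter table.
#' @param climate A `climate_grid`.
#' @param years Years in the period (each needs its predecessor).
#' @param period Label (`"historical"` or `"future"`).
#' @return An object of class `season_metrics`: matrices `sdoy`, `edoy`,
#'   `duration` (lat x lon), the taxon, period and grid. Degenerate
#'   cell-years are `NA` and propagate through the mean.
#' @export
season_metrics <- function(params, climate, years, period = "historical") {
  if (nrow(params) != 1L) stop("params must be a single taxon row")
  if (!all((years - 1L) %in% climate$years))
    stop("every period year needs its preceding year in the climate")
  g <- climate$grid
  acc_s <- matrix(0, g$n_lat, g$n_lon); acc_e <- acc_s
  for (y in years) {
    ph <- phenology_dates(params, compute_pyaat(climate, y), check = FALSE)
    ph$sdoy[ph$edoy <= ph$sdoy] <- NA_real_
    ph$edoy[is.na(ph$sdoy)] <- NA_real_
    acc_s <- acc_s + ph$sdoy; acc_e <- acc_e + ph$edoy
  }
  sdoy <- acc_s / length(years); edoy <- acc_e / length(years)
  structure(list(taxon = params$taxon, period = period, grid = g,
                 sdoy = sdoy, edoy = edoy, duration = edoy - sdoy),
            class = "season_metrics")
}

#' Classify the warming response of a pollen season
#'
#' Compares historical and future season metrics and assigns one of three
#' regimes: Category 1, both dates shift earlier with the start shifting
#' faster, lengthening the season; Category 2, both dates shift earlier at
#' the same rate (duration unchanged within `tol`); Category 3, both dates
#' shift later with the end shifting faster (later, longer late-season
#' flowering). Anything else is `"unclassified"`.
#'
#' @param hist,fut Season start/end summaries: either `season_metrics`
#'   aggregates reduced to scalars, or any lists with scalar `sdoy` and
#'   `edoy` (e.g. regional means).
#' @param tol Duration-change tolerance (days) separating Category 2 from
#'   Category 1; default 2 d at region scale.
#' @return `"1"`, `"2"`, `"3"` or `"unclassified"`.
#' @export
classify_category <- function(hist, fut, tol = 2) {
  ds <- fut$sdoy - hist$sdoy
  de <- fut$edoy - hist$edoy
  dd <- de - ds
  if (ds < 0 && de < 0 && dd > tol) "1"
  else if (ds < 0 && de < 0 && abs(dd) <= tol) "2"
  else if (ds > 0 && de > 0 && dd > tol) "3"
  else "unclassified"
}

#' Maximum of the period-mean daily emission curve
#'
#' Builds the day-of-year climatology (mean across the period's years for
#' each DOY) per cell and takes its maximum over DOY. This is the maximum of
#' the period-average emission curve, not the mean of per-year maxima.
#'
#' @param field An `emission_field`.
#' @param years Subset of the field's years (default all).
#' @return Matrix (lat x lon) of maximum daily emission (grains m-2 d-1).
#' @export
emission_max <- function(field, years = NULL) {
  clim <- doy_climatology(field, years)
  g <- field$grid
  matrix(apply(clim, 2L, max), g$n_lat, g$n_lon)
}

#' Period-mean annual emission total
#'
#' Per-year daily sum per cell, averaged over the period's years.
#'
#' @inheritParams emission_max
#' @return Matrix (lat x lon) of annual emission (grains m-2 yr-1).
#' @export
emission_annual <- function(field, years = NULL) {
  clim <- doy_climatology(field, years)
  g <- field$grid
  matrix(colSums(clim), g$n_lat, g$n_lon)
}

# 365 x ncell day-of-year climatology (mean over the period's years).
doy_climatology <- function(field, years = NULL) {
  if (is.null(years)) years <- field$years
  iy <- match(years, field$years)
  if (anyNA(iy)) stop("requested years not present in the emission field")
  nc <- n_cells(field$grid)
  acc <- matrix(0, 365L, nc)
  for (i in iy) {
    idx <- (i - 1L) * 365L + seq_len(365L)
    acc <- acc + matrix(field$e_pol[idx, , , drop = FALSE], 365L, nc)
  }
  acc / length(iy)
}

#' Percent change between two values
#'
#' `100 * (fut - hist) / hist`; a zero baseline with nonzero future value is
#' undefined and returned as `NA` (flagged with a warning).
#'
#' @param hist,fut Baseline and future values (scalars, vectors, matrices).
#' @return Percent change, same shape.
#' @export
percent_change <- function(hist, fut) {
  out <- 100 * (fut - hist) / hist
  undef <- hist == 0 & fut != 0
  if (any(undef, na.rm = TRUE)) {
    warning("percent change undefined where the baseline is zero; reported as NA")
    out[undef] <- NA_real_
  }
  out[hist == 0 & fut == 0] <- 0
  out
}

#' Built-in analysis region boxes
#'
#' Five fixed subregions tiling 25-48 deg N, 70-125 deg W without overlap:
#' Northeast (NE), Southeast (SE), Mountain (MT), California (CA) and
#' Pacific Northwest (PNW); CA and PNW split at 40 deg N. Longitudes are
#' degrees east (negative for west).
#'
#' The table ships as an editable CSV under the package's `extdata/`; pass
#' `path` to use a custom set of boxes.
#'
#' @param path Optional CSV with columns `name`, `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` overriding the packaged table.
#' @return data.frame with those five columns.
#' @export
region_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "regions.csv", package = "pollensim")
  tab <- as.data.frame(data.table::fread(path))
  need <- c("name", "lat_min", "lat_max", "lon_min", "lon_max")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("region table is missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Area-weighted regional average of a gridded field
#'
#' Cosine-latitude-weighted mean over unmasked cells whose centers fall in
#' the region box (cells on the shared edge between two boxes belong to the
#' box whose minimum edge they sit on). Equal weighting is available as an
#' option.
#'
#' @param values Matrix (lat x lon).
#' @param grid The `grid_spec` the values live on.
#' @param region Region name from [region_definitions()], or a one-row
#'   data.frame with the same columns, or `"domain"` for the whole grid.
#' @param landmask Optional logical/0-1 matrix; only `TRUE`/nonzero cells
#'   contribute.
#' @param weighting `"coslat"` (default) or `"equal"`.
#' @return Scalar regional mean.
#' @export
regional_average <- function(values, grid, region = "domain", landmask = NULL,
                             weighting = c("coslat", "equal")) {
  weighting <- match.arg(weighting)
  if (is.character(region)) {
    if (region == "domain") {
      box <- data.frame(lat_min = -90, lat_max = 90, lon_min = -360, lon_max = 360)
    } else {
      defs <- region_definitions()
      box <- defs[defs$name == region, ]
      if (nrow(box) != 1L) stop(sprintf("unknown region '%s'", region))
    }
  } else box <- region
  in_lat <- grid$lat >= box$lat_min & grid$lat < box$lat_max |
    (box$lat_max >= grid$lat_bounds[2] & grid$lat == grid$lat[grid$n_lat] &
       grid$lat <= box$lat_max)
  in_lon <- grid$lon >= box$lon_min & grid$lon < box$lon_max |
    (box$lon_max >= grid$lon_bounds[2] & grid$lon == grid$lon[grid$n_lon] &
       grid$lon <= box$lon_max)
  sel <- outer(in_lat, in_lon, "&")
  if (!any(sel)) stop("region box does not intersect the grid")
  w <- if (weighting == "coslat")
    outer(cos(grid$lat * pi / 180), rep(1, grid$n_lon)) else (sel * 0 + 1)
  keep <- sel & is.finite(values)
  if (!is.null(landmask)) keep <- keep & (landmask != 0)
  if (!any(keep)) stop("no unmasked cells in the region box")
  sum(values[keep] * w[keep]) / sum(w[keep])
}

#' Ensemble summary statistics
#'
#' Evenly weighted multi-member summary: unweighted mean, minimum, maximum
#' and sample standard deviation across ensemble members.
#'
#' @param per_member_values Numeric vector, one value per member.
#' @return List `mean`, `min`, `max`, `std`, `n_members`.
#' @export
ensemble_stats <- function(per_member_values) {
  x <- per_member_values
  if (length(x) < 1L) stop("need at least one ensemble member")
  list(mean = mean(x), min = min(x), max = max(x),
       std = if (length(x) > 1L) stats::sd(x) else 0,
       n_members = length(x))
}

#' Aggregate taxon emission fields to plant functional types
#'
#' Sums member-taxon daily emissions per PFT: DBL (nine deciduous tree
#' genera), ENL (Cupressaceae + Pinaceae), GRA (C3 + C4 Poaceae), RAG
#' (Ambrosia). The sum over PFTs equals the sum over taxa at every cell and
#' day.
#'
#' @param taxon_fields Named list of `emission_field` (names = taxa).
#' @param mapping Named character vector taxon -> PFT (see
#'   [pft_mapping()]); must cover every field.
#' @return Named list of `emission_field`, one per PFT present.
#' @export
aggregate_pft <- function(taxon_fields, mapping = pft_mapping()) {
  taxa <- names(taxon_fields)
  unmapped <- setdiff(taxa, names(mapping))
  if (length(unmapped))
    stop("taxa without a PFT mapping: ", paste(unmapped, collapse = ", "))
  pfts <- unique(unname(mapping[taxa]))
  out <- list()
  for (p in pfts) {
    members <- taxa[mapping[taxa] == p]
    f <- taxon_fields[[members[1L]]]
    acc <- f$e_pol
    for (m in members[-1L]) acc <- acc + taxon_fields[[m]]$e_pol
    out[[p]] <- structure(list(e_pol = acc, taxon = p, years = f$years,
                               grid = f$grid, co2_mode = f$co2_mode,
                               scenario = f$scenario, member = f$member,
                               n_masked = sum(vapply(taxon_fields[members],
                                                     function(z) z$n_masked, 0L)),
                               units = f$units),
                          class = "emission_field")
  }
  out
}

#' Land-cover change sensitivity of maximum emission
#'
#' Runs the simulation with two land-cover maps under identical climate and
#' reports the percent change of the regional-average maximum daily
#' emission per PFT and region. Isolates the land-cover effect from climate
#' and CO2.
#'
#' @param params Taxon parameter table.
#' @param climate A `climate_grid`.
#' @param lc_a,lc_b Baseline and alternative `landcover_map` on the same
#'   grid.
#' @param co2_mode `"off"` or `"doubled"`.
#' @param years Years to simulate (default all but the first).
#' @param regions Region names to report (default the five boxes).
#' @return data.frame (pft, region, emax_a, emax_b, pct_change).
#' @export
landcover_sensitivity <- function(params, climate, lc_a, lc_b,
                                  co2_mode = c("off", "doubled"), years = NULL,
                                  regions = region_definitions()$name) {
  co2_mode <- match.arg(co2_mode)
  if (!identical(dim(lc_a$fraction)[2:3], dim(lc_b$fraction)[2:3]))
    stop("the two land-cover maps are on different grids")
  fa <- aggregate_pft(simulate_all(params, climate, lc_a, co2_mode, years),
                      pft_mapping(params))
  fb <- aggregate_pft(simulate_all(params, climate, lc_b, co2_mode, years),
                      pft_mapping(params))
  rows <- list()
  for (p in names(fa)) {
    ea <- emission_max(fa[[p]]); eb <- emission_max(fb[[p]])
    for (r in regions) {
      va <- regional_average(ea, climate$grid, r)
      vb <- regional_average(eb, climate$grid, r)
      rows[[paste(p, r)]] <- data.frame(pft = p, region = r, emax_a = va,
                                        emax_b = vb,
                                        pct_change = percent_change(va, vb),
                                        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Intra-PFT phenology overlap diagnostic
#'
#' For each taxon pair within one PFT, computes the overlap integral of the
#' regional-mean day-of-year emission climatologies,
#' `sum_t min(curve_i(t), curve_j(t))`, for the historical and future
#' periods, and labels the pair "convergence" if the overlap increases
#' under the future climate and "divergence" if it decreases. Also reports
#' the change in the summed-PFT maximum daily emission.
#'
#' @param hist_fields,fut_fields Named lists of `emission_field` for the
#'   same >= 2 taxa under the two periods.
#' @param grid The shared `grid_spec`.
#' @param region Region name or `"domain"`.
#' @return List: `pairs` data.frame (taxon_i, taxon_j, overlap_hist,
#'   overlap_fut, change, label) and `pft_emax` (historical, future,
#'   pct_change of the summed field's regional E_pol,max).
#' @export
overlap_diagnostic <- function(hist_fields, fut_fields, grid, region = "domain") {
  taxa <- names(hist_fields)
  if (length(taxa) < 2L) stop("need at least two taxa")
  if (!setequal(taxa, names(fut_fields)))
    stop("historical and future field lists must cover the same taxa")
  curve <- function(field) {
    clim <- doy_climatology(field)
    vapply(seq_len(365L), function(t)
      regional_average(matrix(clim[t, ], grid$n_lat, grid$n_lon), grid, region),
      0)
  }
  ch <- lapply(hist_fields, curve)
  cf <- lapply(fut_fields[taxa], curve)
  rows <- list()
  for (i in seq_along(taxa)[-length(taxa)]) for (j in (i + 1L):length(taxa)) {
    oh <- sum(pmin(ch[[i]], ch[[j]]))
    of <- sum(pmin(cf[[i]], cf[[j]]))
    rows[[paste(i, j)]] <- data.frame(
      taxon_i = taxa[i], taxon_j = taxa[j],
      overlap_hist = oh, overlap_fut = of, change = of - oh,
      label = if (of > oh) "convergence" else if (of < oh) "divergence" else "unchanged",
      stringsAsFactors = FALSE)
  }
  sum_curve_max <- function(curves) max(Reduce(`+`, curves))
  eh <- sum_curve_max(ch); ef <- sum_curve_max(cf)
  list(pairs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pft_emax = data.frame(historical = eh, future = ef,
                             pct_change = percent_change(eh, ef)))
}
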