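#' Default run configuration
#'
#' Desk-scale defaults: a 20 x 30 cell grid over 25-48 N / 125-70 W, a
#' historical baseline and two warming scenarios (+2 K and +4.5 K, the
#' moderate/high emissions-pathway analogs), 3-member ensembles, the 15
#' default taxa, 5 observation stations, and a small Morris screen.
#'
#' @param seed Master seed recorded in the configuration.
#' @return A nested list understood by [run_pipeline()]; serializable with
#'   [write_run_config()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    grid = list(n_lat = 20L, n_lon = 30L, lat_bounds = c(25, 48),
                lon_bounds = c(-125, -70)),
    scenarios = list(
      list(name = "historical", warming_offset = 0, years = c(1995L, 2014L),
           co2_mode = "off"),
      list(name = "moderate", warming_offset = 2, years = c(2081L, 2100L),
           co2_mode = "off"),
      list(name = "high", warming_offset = 4.5, years = c(2081L, 2100L),
           co2_mode = "off")),
    n_members = 3L, member_spread = 0.5,
    climate = list(noise_sd = 2, interannual_sd = 0.3, wet_prob = 0.3,
                   wet_mean_intensity = 4),
    observations = list(n_stations = 5L, doy_sd = 5, logcount_sd = 0.3),
    references = list(t_ref_us = 285, t_ref_pnw = 283),
    morris = list(p = 20L, levels = 4L, taxa = "Quercus",
                  p_annual_spread = 0.5),
    category_tolerance = 2,
    regional_weighting = "coslat"
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param config Configuration list.
#' @param path YAML file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   the validated configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_run_config(config)
}

validate_run_config <- function(config) {
  for (nm in c("seed", "grid", "scenarios"))
    if (is.null(config[[nm]])) stop("run config is missing field: ", nm)
  hist <- vapply(config$scenarios, function(s) s$name == "historical", TRUE)
  if (sum(hist) != 1L) stop("run config must declare exactly one historical scenario")
  config
}

config_grid <- function(config) {
  do.call(grid_spec, config$grid)
}

config_scenario <- function(config, name) {
  sc <- Filter(function(s) s$name == name, config$scenarios)
  if (length(sc) != 1L) stop(sprintf("scenario '%s' not in config", name))
  sc <- sc[[1L]]
  co2 <- sc$co2_mode %||% "off"
  # YAML 1.1 readers turn a bare `off` into FALSE; accept both spellings
  if (is.logical(co2)) co2 <- if (co2) "doubled" else "off"
  scenario_config(sc$name, sc$warming_offset, sc$years[1L]:sc$years[2L],
                  co2, config$n_members %||% 1L,
                  config$member_spread %||% 0)
}

config_hash <- function(config) {
  # order-stable structural fingerprint recorded in every output
  sprintf("%08x", sum(utf8ToInt(yaml::as.yaml(config)) *
                        (seq_along(utf8ToInt(yaml::as.yaml(config))) %% 97L)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes the requested steps against a configuration and writes all
#' artifacts under `outdir`: `generate` (synthetic climate per scenario and
#' member, land cover, truth parameters, pseudo-observations), `calibrate`
#' (fitted parameter and diagnostics CSVs), `simulate` (emission fields per
#' scenario, first member), `project` (season, category, emission and
#' regional/ensemble summary CSVs), `sensitivity` (Morris design, outputs
#' and indices CSVs) and `report` (headline diagnostics CSV). Outputs are
#' reproducible from (config, seed) alone; the config hash and seed are
#' recorded in a run log.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param outdir Output directory (created if needed).
#' @param steps Subset of
#'   `c("generate", "calibrate", "simulate", "project", "sensitivity",
#'   "report")`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed objects and written paths.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = tempdir(),
                         steps = c("generate", "calibrate", "simulate",
                                   "project", "sensitivity", "report"),
                         quiet = TRUE) {
  steps <- match.arg(steps, several.ok = TRUE)
  # later steps consume earlier steps' in-memory results
  chain <- c("generate", "calibrate", "simulate", "project", "sensitivity",
             "report")
  steps <- chain[seq_len(max(match(steps, chain)))]
  validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  grid <- config_grid(config)
  res <- list(paths = character())
  logline <- c(sprintf("seed: %d", seed),
               sprintf("config_hash: %s", config_hash(config)))

  params <- generate_taxon_params(seed,
                                  t_ref_us = config$references$t_ref_us,
                                  t_ref_pnw = config$references$t_ref_pnw)
  landcover <- generate_landcover(grid, params$taxon, seed)
  scen_names <- vapply(config$scenarios, `[[`, "", "name")
  climates <- list()

  if ("generate" %in% steps) {
    say("generating synthetic inputs")
    for (nm in scen_names) {
      sc <- config_scenario(config, nm)
      climates[[nm]] <- lapply(seq_len(sc$n_members), function(m)
        do.call(generate_climate,
                c(list(grid = grid, scenario = sc, member_index = m, seed = seed),
                  config$climate)))
      write_climate(climates[[nm]][[1L]],
                    file.path(outdir, sprintf("climate_%s_m1.txt", nm)))
    }
    write_landcover(landcover, file.path(outdir, "landcover.txt"))
    write_params(params, file.path(outdir, "params_truth.csv"))
    obs <- generate_pollen_observations(
      params, climates[["historical"]][[1L]],
      n_stations = config$observations$n_stations,
      noise = list(doy_sd = config$observations$doy_sd,
                   logcount_sd = config$observations$logcount_sd),
      seed = seed + 1L)
    write_observations(obs, file.path(outdir, "observations.csv"))
    res$params <- params; res$landcover <- landcover
    res$climates <- climates; res$observations <- obs
  }

  if ("calibrate" %in% steps) {
    say("calibrating regressions from observations")
    cal <- calibrate_taxa(res$observations, params,
                          t_ref_us = config$references$t_ref_us,
                          t_ref_pnw = config$references$t_ref_pnw)
    write_params(cal$params, file.path(outdir, "params_fitted.csv"))
    data.table::fwrite(cal$diagnostics, file.path(outdir, "fit_diagnostics.csv"))
    res$calibration <- cal
  }

  if ("simulate" %in% steps) {
    say("simulating emissions")
    res$fields <- list()
    for (nm in scen_names) {
      cl <- res$climates[[nm]][[1L]]
      res$fields[[nm]] <- simulate_all(params, cl, landcover,
                                       co2_mode = cl$co2_mode)
    }
  }

  if ("project" %in% steps) {
    say("computing projection diagnostics")
    hist_cl <- res$climates[["historical"]]
    fut_names <- setdiff(scen_names, "historical")
    tol <- config$category_tolerance %||% 2
    sum_rows <- list(); cat_rows <- list()
    for (fn in fut_names) {
      fut_cl <- res$climates[[fn]]
      for (i in seq_len(nrow(params))) {
        pr <- params[i, ]
        per_member <- vapply(seq_along(hist_cl), function(m) {
          h <- season_metrics(pr, hist_cl[[m]], hist_cl[[m]]$years[-1L], "historical")
          f <- season_metrics(pr, fut_cl[[m]], fut_cl[[m]]$years[-1L], "future")
          c(hs = regional_average(h$sdoy, grid, "domain"),
            he = regional_average(h$edoy, grid, "domain"),
            fs = regional_average(f$sdoy, grid, "domain"),
            fe = regional_average(f$edoy, grid, "domain"))
        }, c(hs = 0, he = 0, fs = 0, fe = 0))
        ens <- rowMeans(per_member)
        cat_rows[[paste(fn, pr$taxon)]] <- data.frame(
          scenario = fn, taxon = pr$taxon,
          d_sdoy = ens["fs"] - ens["hs"], d_edoy = ens["fe"] - ens["he"],
          d_duration = (ens["fe"] - ens["fs"]) - (ens["he"] - ens["hs"]),
          category = classify_category(list(sdoy = ens["hs"], edoy = ens["he"]),
                                       list(sdoy = ens["fs"], edoy = ens["fe"]),
                                       tol = tol),
          stringsAsFactors = FALSE)
      }
      for (tx in c("Quercus", "Ambrosia")) {
        pr <- params[params$taxon == tx, ]
        eh <- emission_max(res$fields[["historical"]][[tx]])
        ef <- emission_max(res$fields[[fn]][[tx]])
        ah <- emission_annual(res$fields[["historical"]][[tx]])
        af <- emission_annual(res$fields[[fn]][[tx]])
        for (rg in region_definitions()$name) {
          sum_rows[[paste(fn, tx, rg)]] <- data.frame(
            scenario = fn, taxon = tx, region = rg,
            emax_hist = regional_average(eh, grid, rg),
            emax_fut = regional_average(ef, grid, rg),
            eann_hist = regional_average(ah, grid, rg),
            eann_fut = regional_average(af, grid, rg),
            stringsAsFactors = FALSE)
        }
      }
    }
    res$categories <- do.call(rbind, c(cat_rows, list(make.row.names = FALSE)))
    res$regional <- do.call(rbind, c(sum_rows, list(make.row.names = FALSE)))
    res$regional$emax_pct <- percent_change(res$regional$emax_hist,
                                            res$regional$emax_fut)
    res$regional$eann_pct <- percent_change(res$regional$eann_hist,
                                            res$regional$eann_fut)
    data.table::fwrite(res$categories, file.path(outdir, "season_categories.csv"))
    data.table::fwrite(res$regional, file.path(outdir, "regional_summary.csv"))
  }

  if ("sensitivity" %in% steps) {
    say("running Morris screen")
    cal <- res$calibration
    mres <- list()
    for (tx in config$morris$taxa) {
      pr <- params[params$taxon == tx, ]
      spread <- config$morris$p_annual_spread %||% 0.5
      rng <- build_ranges(pr, cal$fits[[tx]],
                          literature_bounds = pr$P_annual * c(1 - spread, 1 + spread),
                          t_ref = config$references$t_ref_us)
      small_grid <- grid_spec(6L, 8L, config$grid$lat_bounds, config$grid$lon_bounds)
      sc <- config_scenario(config, "historical")
      sc1 <- scenario_config("morris", 0, sc$years[1:2], "off")
      cl1 <- do.call(generate_climate,
                     c(list(grid = small_grid, scenario = sc1, member_index = 1L,
                            seed = seed), config$climate))
      lc1 <- generate_landcover(small_grid, params$taxon, seed)
      mres[[tx]] <- morris_screen(rng, pr, cl1, lc1, p = config$morris$p,
                                  levels = config$morris$levels, seed = seed)
      data.table::fwrite(cbind(taxon = tx, as.data.frame(mres[[tx]])),
                         file.path(outdir, sprintf("morris_%s.csv", tx)))
    }
    res$morris <- mres
    data.table::fwrite(rank_report(mres), file.path(outdir, "morris_ranks.csv"))
  }

  if ("report" %in% steps) {
    say("writing headline report")
    head_rows <- data.frame(
      quantity = c("n_taxa", "n_category1", "n_category2", "n_category3",
                   "n_significant_production"),
      value = c(nrow(params),
                if (!is.null(res$categories))
                  vapply(c("1", "2", "3"), function(k)
                    sum(res$categories$category == k &
                          res$categories$scenario == res$categories$scenario[1L]), 0)
                else rep(NA_real_, 3),
                if (!is.null(res$calibration))
                  significance_summary(lapply(res$calibration$fits,
                                              `[[`, "production"))$n_significant
                else NA_real_),
      stringsAsFactors = FALSE)
    data.table::fwrite(head_rows, file.path(outdir, "report.csv"))
    res$report <- head_rows
  }

  writeLines(logline, file.path(outdir, "run_log.txt"))
  invisible(res)
}
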