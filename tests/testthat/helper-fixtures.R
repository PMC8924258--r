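# Shared desk-scale fixtures, built in code at test time.

small_grid <- function(n_lat = 6L, n_lon = 8L)
  grid_spec(n_lat, n_lon, c(25, 48), c(-125, -70))

# noise-free climate: deterministic gradient + seasonal cycle (+ offset)
quiet_climate <- function(years = 2000:2002, warming = 0, seed = 11,
                          grid = small_grid(), wet_prob = 0, ...) {
  generate_climate(grid,
                   scenario_config("t", warming_offset = warming, years = years),
                   seed = seed, noise_sd = 0, interannual_sd = 0,
                   wet_prob = wet_prob, ...)
}

noisy_climate <- function(years = 2000:2004, warming = 0, seed = 11,
                          grid = small_grid(), ...) {
  generate_climate(grid,
                   scenario_config("t", warming_offset = warming, years = years),
                   seed = seed, ...)
}

default_params <- function(seed = 1) generate_taxon_params(seed)

one_taxon <- function(taxon = "Quercus", seed = 1) {
  p <- default_params(seed)
  p[p$taxon == taxon, ]
}

uniform_landcover <- function(grid = small_grid(), taxa = "Quercus", fill = 0.5)
  generate_landcover(grid, taxa, seed = 1, fill = fill)

# canonical order of the nine screened parameters
morris_parameter_names_for_test <- function()
  c("P_annual", "m_sDOY", "b_sDOY", "m_eDOY", "b_eDOY",
    "m_prod", "b_prod", "P_norm", "a")
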