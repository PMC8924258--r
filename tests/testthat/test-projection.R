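test_that("season metrics average per-year dates and respond linearly to warming", {
  g <- small_grid()
  cl0 <- quiet_climate(years = 2000:2003, grid = g)
  p <- one_taxon("Quercus")
  sm <- season_metrics(p, cl0, 2001:2003)
  # constant climate across years: metrics equal single-year values
  one <- season_metrics(p, cl0, 2001)
  expect_equal(sm$sdoy, one$sdoy, tolerance = 1e-10)
  expect_equal(sm$duration, sm$edoy - sm$sdoy)

  cl4 <- quiet_climate(years = 2000:2003, warming = 4, grid = g)
  sm4 <- season_metrics(p, cl4, 2001:2003)
  expect_equal(sm4$sdoy - sm$sdoy,
               matrix(p$m_sDOY * 4, g$n_lat, g$n_lon), tolerance = 1e-9)
})

test_that("category classification follows the sign and tolerance rules", {
  mk <- function(s, e) list(sdoy = s, edoy = e)
  h <- mk(100, 160)
  expect_identical(classify_category(h, mk(80, 155)), "1")    # (-20, -5)
  expect_identical(classify_category(h, mk(90, 150)), "2")    # (-10, -10)
  expect_identical(classify_category(h, mk(105, 175)), "3")   # (+5, +15)
  expect_identical(classify_category(h, mk(95, 175)), "unclassified")
  # tolerance boundary: |delta duration| <= tol stays Category 2
  expect_identical(classify_category(h, mk(90, 151.5), tol = 2), "2")
  expect_identical(classify_category(h, mk(90, 153), tol = 2), "1")
})

test_that("scenario shifts scale exactly with the warming ratio", {
  g <- small_grid()
  cl0 <- quiet_climate(years = 2000:2002, grid = g, seed = 13)
  cl2 <- quiet_climate(years = 2000:2002, warming = 2, grid = g, seed = 13)
  cl45 <- quiet_climate(years = 2000:2002, warming = 4.5, grid = g, seed = 13)
  p <- one_taxon("Alnus")
  s0 <- season_metrics(p, cl0, 2001:2002)
  s2 <- season_metrics(p, cl2, 2001:2002)
  s45 <- season_metrics(p, cl45, 2001:2002)
  expect_equal((s45$sdoy - s0$sdoy) / (s2$sdoy - s0$sdoy),
               matrix(2.25, g$n_lat, g$n_lon), tolerance = 1e-9)
  expect_equal((s45$duration - s0$duration) / (s2$duration - s0$duration),
               matrix(2.25, g$n_lat, g$n_lon), tolerance = 1e-9)
})

test_that("emission maxima and annual totals follow their definitions", {
  g <- small_grid()
  cl <- quiet_climate(years = 2000:2001, grid = g)
  p <- one_taxon("Quercus")
  lc <- uniform_landcover(g, "Quercus", fill = 0.5)
  ef <- simulate_taxon(p, cl, lc, years = 2001)
  emax <- emission_max(ef)
  eann <- emission_annual(ef)
  # single year: max and sum of that year's series
  nc <- prod(dim(emax))
  daily <- matrix(ef$e_pol, 365, nc)
  expect_equal(as.vector(emax), apply(daily, 2, max))
  expect_equal(as.vector(eann), colSums(daily))
  # homogeneity
  ef2 <- ef; ef2$e_pol <- 2 * ef$e_pol
  expect_equal(emission_max(ef2), 2 * emax)
  expect_equal(emission_annual(ef2), 2 * eann)
  # precip-free: annual total equals A * S
  expect_equal(eann, 0.5 * production_scale(p, compute_pyaat(cl, 2001)),
               tolerance = 1e-9)
  # all-wet year removes everything
  wet <- cl; wet$precipitation[] <- 10
  efw <- simulate_taxon(p, wet, lc, years = 2001)
  expect_true(all(emission_annual(efw) == 0))
})

test_that("longer seasons lower the climatological daily maximum at fixed production", {
  g <- small_grid()
  cl <- quiet_climate(years = 2000:2001, grid = g)
  lc <- uniform_landcover(g, "Quercus", fill = 0.5)
  p_short <- one_taxon("Quercus"); p_long <- p_short
  # stretch the season symmetrically without touching production
  p_long$b_sDOY <- p_long$b_sDOY - 20
  p_long$b_eDOY <- p_long$b_eDOY + 20
  m_short <- emission_max(simulate_taxon(p_short, cl, lc, years = 2001))
  m_long <- emission_max(simulate_taxon(p_long, cl, lc, years = 2001))
  expect_true(all(m_long < m_short))
})

test_that("percent change handles signs and the zero baseline", {
  expect_equal(percent_change(10, 14), 40)
  expect_equal(percent_change(10, 6.5), -35)
  expect_equal(percent_change(7, 7), 0)
  expect_warning(out <- percent_change(0, 3), "undefined")
  expect_true(is.na(out))
  expect_equal(suppressWarnings(percent_change(c(0, 10), c(0, 20))), c(0, 100))
})

test_that("region boxes tile the analysis domain without overlap", {
  g <- grid_spec(23, 55, c(25, 48), c(-125, -70))
  defs <- region_definitions()
  counts <- matrix(0L, g$n_lat, g$n_lon)
  for (i in seq_len(nrow(defs))) {
    in_lat <- g$lat >= defs$lat_min[i] & g$lat < defs$lat_max[i]
    in_lon <- g$lon >= defs$lon_min[i] & g$lon < defs$lon_max[i]
    counts <- counts + outer(in_lat, in_lon)
  }
  expect_true(all(counts == 1L))
  # point membership per the box definitions
  expect_true(40 >= 38 && 40 < 48 && -80 >= -100)       # (40N, 80W) in NE
  ne <- defs[defs$name == "NE", ]
  se <- defs[defs$name == "SE", ]
  expect_true(40 >= ne$lat_min && 40 < ne$lat_max && -80 >= ne$lon_min)
  expect_true(30 >= se$lat_min && 30 < se$lat_max && -80 >= se$lon_min)
})

test_that("regional averages are exact on uniform fields and respect weighting", {
  g <- small_grid()
  vals <- matrix(7.5, g$n_lat, g$n_lon)
  for (r in c(region_definitions()$name, "domain"))
    expect_equal(regional_average(vals, g, r), 7.5)
  # cosine weighting favors southern rows
  grad <- matrix(rep(seq_len(g$n_lat), g$n_lon), g$n_lat, g$n_lon)
  expect_lt(regional_average(grad, g, "domain", weighting = "coslat"),
            regional_average(grad, g, "domain", weighting = "equal"))
  expect_error(regional_average(vals, grid_spec(4, 4, c(0, 10), c(0, 10)), "NE"),
               "intersect")
})

test_that("ensemble statistics summarize members evenly", {
  s <- ensemble_stats(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$min, 1); expect_equal(s$max, 3)
  expect_equal(s$std, 1); expect_equal(s$n_members, 3L)
  same <- ensemble_stats(rep(4.2, 5))
  expect_equal(same$min, same$mean)
  expect_equal(same$max, same$mean)
  expect_equal(same$std, 0)
  expect_equal(ensemble_stats(rnorm(15))$n_members, 15L)
  expect_error(ensemble_stats(numeric(0)), "at least one")
})

test_that("PFT aggregation conserves total emission", {
  g <- small_grid()
  cl <- noisy_climate(grid = g, years = 2000:2001, seed = 17)
  pars <- default_params()
  sub <- pars[pars$taxon %in% c("Cupressaceae", "Pinaceae", "Quercus", "Ambrosia"), ]
  lc <- generate_landcover(g, sub$taxon, seed = 2)
  fields <- simulate_all(sub, cl, lc)
  pfts <- aggregate_pft(fields, pft_mapping(sub))
  expect_setequal(names(pfts), c("ENL", "DBL", "RAG"))
  expect_equal(pfts$ENL$e_pol,
               fields$Cupressaceae$e_pol + fields$Pinaceae$e_pol)
  total_taxa <- Reduce(`+`, lapply(fields, `[[`, "e_pol"))
  total_pft <- Reduce(`+`, lapply(pfts, `[[`, "e_pol"))
  expect_equal(total_pft, total_taxa, tolerance = 1e-12)
  expect_error(aggregate_pft(fields, c(Quercus = "DBL")), "without a PFT")
})

test_that("land-cover differencing isolates the cover effect", {
  g <- small_grid()
  cl <- quiet_climate(grid = g, years = 2000:2001)
  pars <- default_params()
  sub <- pars[pars$taxon %in% c("Quercus", "Ambrosia"), ]
  lc_a <- generate_landcover(g, sub$taxon, seed = 5)
  # identical maps: 0% everywhere
  same <- landcover_sensitivity(sub, cl, lc_a, lc_a, years = 2001)
  expect_true(all(abs(same$pct_change) < 1e-9))
  # scaling cover by 1.2 scales maxima by 1.2 (linear in A)
  lc_b <- lc_a; lc_b$fraction <- 1.2 * lc_a$fraction
  up <- landcover_sensitivity(sub, cl, lc_a, lc_b, years = 2001)
  expect_equal(up$pct_change, rep(20, nrow(up)), tolerance = 1e-9)
  # zeroing a PFT's cover removes it entirely
  lc_c <- lc_a; lc_c$fraction["Ambrosia", , ] <- 0
  gone <- landcover_sensitivity(sub, cl, lc_a, lc_c, years = 2001)
  expect_equal(gone$pct_change[gone$pft == "RAG"], rep(-100, 5))
})

test_that("phenology overlap labels convergence and divergence", {
  g <- small_grid()
  lc <- uniform_landcover(g, c("A", "B"), fill = 0.4)
  pars0 <- default_params()
  mk_pars <- function(taxon, s0, e0, m_s, m_e) {
    p <- pars0[pars0$taxon == "Quercus", ]
    p$taxon <- taxon
    p$m_sDOY <- m_s; p$m_eDOY <- m_e
    p$b_sDOY <- s0 - m_s * 285; p$b_eDOY <- e0 - m_e * 285
    p
  }
  cl0 <- quiet_climate(grid = g, years = 2000:2001)
  cl4 <- quiet_climate(grid = g, years = 2000:2001, warming = 4)
  # seasons whose means approach under warming
  pa <- mk_pars("A", 80, 140, 0, 0)       # fixed season
  pb <- mk_pars("B", 200, 260, -5, -5)    # shifts 20 d earlier under +4 K
  hist_f <- list(A = simulate_taxon(pa, cl0, lc, years = 2001),
                 B = simulate_taxon(pb, cl0, lc, years = 2001))
  fut_f <- list(A = simulate_taxon(pa, cl4, lc, years = 2001),
                B = simulate_taxon(pb, cl4, lc, years = 2001))
  od <- overlap_diagnostic(hist_f, fut_f, g, "domain")
  expect_identical(od$pairs$label, "convergence")
  expect_gt(od$pairs$overlap_fut, od$pairs$overlap_hist)
  # identical curves overlap by their full annual sum
  od2 <- overlap_diagnostic(list(A = hist_f$A, B = hist_f$A),
                            list(A = hist_f$A, B = hist_f$A), g, "domain")
  curve_sum <- od2$pairs$overlap_hist
  expect_gt(curve_sum, 0)
  expect_equal(od2$pairs$overlap_fut, curve_sum)
})
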