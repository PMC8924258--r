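test_that("PYAAT is the previous-year mean: constant, symmetric and linear cases", {
  g <- small_grid(2, 2)
  mk <- function(temps) {
    sc <- scenario_config("t", years = 2000:2001)
    cl <- quiet_climate(years = 2000:2001, grid = g)
    cl$temperature[seq_len(365), , ] <- temps
    cl
  }
  expect_equal(compute_pyaat(mk(283.15), 2001),
               matrix(283.15, 2, 2), tolerance = 1e-12)
  sinu <- 285 + 10 * sin(2 * pi * (1:365) / 365)
  expect_equal(compute_pyaat(mk(array(sinu, c(365, 2, 2))), 2001),
               matrix(285, 2, 2), tolerance = 1e-10)
  cl <- quiet_climate(years = 2000:2001, grid = g)
  base <- compute_pyaat(cl, 2001)
  cl$temperature[seq_len(365), , ] <- cl$temperature[seq_len(365), , ] + 4
  expect_equal(compute_pyaat(cl, 2001), base + 4, tolerance = 1e-12)
  expect_error(compute_pyaat(cl, 2000), "previous year")
})

test_that("phenology dates are linear in PYAAT", {
  p <- data.frame(taxon = "x", m_sDOY = -2.5, b_sDOY = 790,
                  m_eDOY = -1, b_eDOY = 450)
  expect_equal(phenology_dates(p, 284)$sdoy, 80)
  expect_equal(phenology_dates(p, 288)$sdoy, 70)
  p0 <- data.frame(taxon = "x", m_sDOY = 0, b_sDOY = 80,
                   m_eDOY = 0, b_eDOY = 140)
  expect_equal(phenology_dates(p0, 250)$sdoy, 80)
  expect_equal(phenology_dates(p0, 300)$sdoy, 80)
  pbad <- data.frame(taxon = "x", m_sDOY = 0, b_sDOY = 200,
                     m_eDOY = 0, b_eDOY = 100)
  expect_error(phenology_dates(pbad, 285), "degenerate")
})

test_that("the Gaussian season peaks at the mean and hits exp(-a^2/8) at the boundaries", {
  ph <- gaussian_phenology(80, 140, a = 3)
  expect_equal(ph$mu, 110)
  expect_equal(ph$sigma, 20)
  expect_equal(ph$gamma[110], 1)
  expect_equal(ph$gamma[80], exp(-9 / 8), tolerance = 1e-12)
  expect_equal(ph$gamma[140], exp(-9 / 8), tolerance = 1e-12)
  expect_equal(ph$gamma[90], exp(-0.5), tolerance = 1e-12)
  expect_true(all(ph$gamma <= 1))
  # boundary value holds for arbitrary seasons and widths
  for (case in list(c(30, 90, 3), c(100.5, 260.25, 2.4), c(200, 310, 3.2))) {
    ph <- gaussian_phenology(case[1], case[2], case[3])
    expect_equal(phenology_weight(ph, case[1]), exp(-case[3]^2 / 8),
                 tolerance = 1e-12)
    expect_equal(phenology_weight(ph, case[2]), exp(-case[3]^2 / 8),
                 tolerance = 1e-12)
  }
  expect_error(gaussian_phenology(140, 80), "degenerate")
  expect_error(gaussian_phenology(80, 140, a = 0), "a must be")
})

test_that("production scale follows the normalized exponential in PYAAT", {
  p <- data.frame(taxon = "x", m_prod = 0, b_prod = log(500),
                  P_norm = 500, P_annual = 2e5)
  expect_equal(production_scale(p, 270), 2e5)
  expect_equal(production_scale(p, 300), 2e5)
  # at the reference temperature the regression cancels to exactly P_annual
  p2 <- data.frame(taxon = "x", m_prod = 0.1, b_prod = -20,
                   P_norm = exp(0.1 * 284 - 20), P_annual = 1e5)
  expect_equal(production_scale(p2, 284), 1e5, tolerance = 1e-12)
  expect_equal(production_scale(p2, 288), 1e5 * exp(0.4), tolerance = 1e-12)
  # negative slope: strictly decreasing in PYAAT
  p3 <- transform(p2, m_prod = -0.1, P_norm = exp(-0.1 * 284 - 20))
  vals <- production_scale(p3, c(280, 284, 288))
  expect_true(all(diff(vals) < 0))
})

test_that("daily amplitude conserves the annual production total", {
  ph <- gaussian_phenology(80, 140)
  pf <- daily_amplitude(2e5, ph)
  expect_equal(sum(pf * ph$gamma), 2e5, tolerance = 1e-12)
  # flat hypothetical season: amplitude is S/365
  flat <- structure(list(gamma = rep(1, 365)), class = "phenology_state")
  expect_equal(daily_amplitude(1, flat), 1 / 365)
  # interior seasons: sum of weights approaches sigma * sqrt(2*pi)
  for (sig in c(10, 15, 20)) {
    ph <- gaussian_phenology(180 - 1.5 * sig, 180 + 1.5 * sig, a = 3)
    expect_equal(ph$sigma, sig)
    expect_equal(sum(ph$gamma), sig * sqrt(2 * pi), tolerance = 0.01)
  }
})

test_that("precipitation switch is strict at 5 mm per day", {
  expect_equal(precipitation_factor(0), 1)
  expect_equal(precipitation_factor(5.0), 1)
  expect_equal(precipitation_factor(10), 0)
  expect_equal(precipitation_factor(c(0, 4.99, 5, 5.01, 12)),
               c(1, 1, 1, 0, 0))
  expect_error(precipitation_factor(-1), "non-negative")
})

test_that("the CO2 factor is 1 off and exactly 2 doubled", {
  expect_identical(co2_factor("off"), 1)
  expect_identical(co2_factor("doubled"), 2)
  expect_error(co2_factor("triple"))
})

test_that("simulated emission obeys the multiplicative structure", {
  g <- small_grid()
  cl <- quiet_climate(grid = g)
  p <- one_taxon("Quercus")

  # zero land cover -> all-zero field
  lc0 <- uniform_landcover(g, "Quercus", fill = 0)
  ef0 <- simulate_taxon(p, cl, lc0)
  expect_true(all(ef0$e_pol == 0))

  # precip-free: per-cell annual sum equals A * S
  lc <- uniform_landcover(g, "Quercus", fill = 0.5)
  ef <- simulate_taxon(p, cl, lc, years = 2001)
  S <- production_scale(p, compute_pyaat(cl, 2001))
  annual <- apply(ef$e_pol, c(2, 3), sum)
  expect_equal(annual, 0.5 * S, tolerance = 1e-9)

  # point product check: A=0.5, pf=2e4, gamma=0.5 -> 5e3
  ph <- gaussian_phenology(80, 140)
  t_half <- ph$mu - ph$sigma * sqrt(2 * log(2))  # gamma = 0.5 there
  expect_equal(0.5 * 2e4 * phenology_weight(ph, t_half) * 1 * 1, 5e3,
               tolerance = 1e-9)
})

test_that("wet days remove exactly the emissions of days above threshold", {
  g <- small_grid()
  cl <- noisy_climate(grid = g, years = 2000:2001, seed = 21)
  p <- one_taxon("Quercus")
  lc <- uniform_landcover(g, "Quercus", fill = 0.5)
  ef <- simulate_taxon(p, cl, lc, years = 2001)
  pr <- cl$precipitation[365 + seq_len(365), , ]
  # every day has positive seasonal weight (full-year Gaussian), so
  # zero-emission days are exactly the wet days
  zero_days <- ef$e_pol == 0
  expect_equal(sum(zero_days), sum(pr > 5))
  expect_true(all(pr[zero_days] > 5))
})

test_that("CO2 doubling scales the whole field by exactly 2", {
  g <- small_grid()
  cl <- noisy_climate(grid = g, years = 2000:2001, seed = 31)
  p <- one_taxon("Ambrosia")
  lc <- uniform_landcover(g, "Ambrosia", fill = 0.4)
  off <- simulate_taxon(p, cl, lc, co2_mode = "off")
  dbl <- simulate_taxon(p, cl, lc, co2_mode = "doubled")
  expect_identical(dbl$e_pol, 2 * off$e_pol)
})

test_that("lengthening the season flattens the emission curve", {
  # same production, longer duration -> strictly lower daily maximum
  S <- 1e5
  short <- gaussian_phenology(100, 150)
  long <- gaussian_phenology(90, 170)
  peak <- function(ph) max(daily_amplitude(S, ph) * ph$gamma)
  expect_lt(peak(long), peak(short))
})

test_that("degenerate cells are masked and counted, not fatal", {
  g <- small_grid()
  cl <- quiet_climate(grid = g)
  p <- one_taxon("Quercus")
  p$m_eDOY <- p$m_sDOY          # same slopes ...
  p$b_eDOY <- p$b_sDOY - 1      # ... end strictly before start everywhere
  lc <- uniform_landcover(g, "Quercus", fill = 0.5)
  expect_message(ef <- simulate_taxon(p, cl, lc, years = 2001), "masked")
  expect_equal(ef$n_masked, 48L)  # every cell of the 6 x 8 grid
  expect_true(all(is.na(ef$e_pol)))
})
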