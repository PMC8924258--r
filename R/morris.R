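#' Parameter ranges for the elementary-effects screen
#'
#' Builds the uncertainty ranges of the nine screened parameters for one
#' taxon: the four phenology and two production regression coefficients use
#' their 95% confidence bounds; `P_annual` uses supplied literature bounds;
#' `P_norm` bounds are the minimum and maximum of
#' `exp(m_prod * T_ref + b_prod)` over the four (m_prod, b_prod) CI
#' corners; the Gaussian width divisor `a` spans plus/minus 0.2 around 3.
#'
#' @param params One row of a taxon parameter table (supplies `a` and the
#'   reference region).
#' @param fits List with `start`, `end`, `production` `regression_fit`s for
#'   the taxon (see [calibrate_taxa()]).
#' @param literature_bounds Length-2 numeric, low/high for `P_annual`.
#' @param t_ref Reference temperature (K) for the `P_norm` corners.
#' @param a_halfwidth Half-width of the `a` range (default 0.2).
#' @return An object of class `parameter_ranges`: data.frame (name, low,
#'   high) with the nine parameters in canonical order.
#' @export
build_ranges <- function(params, fits, literature_bounds, t_ref = 285,
                         a_halfwidth = 0.2) {
  for (nm in c("start", "end", "production"))
    if (is.null(fits[[nm]])) stop(sprintf("missing '%s' regression fit", nm))
  corners <- expand.grid(m = fits$production$slope_ci95,
                         b = fits$production$intercept_ci95)
  pnorm_vals <- exp(corners$m * t_ref + corners$b)
  tab <- data.frame(
    name = morris_parameter_names(),
    low = c(literature_bounds[1],
            fits$start$slope_ci95[1], fits$start$intercept_ci95[1],
            fits$end$slope_ci95[1], fits$end$intercept_ci95[1],
            fits$production$slope_ci95[1], fits$production$intercept_ci95[1],
            min(pnorm_vals), params$a - a_halfwidth),
    high = c(literature_bounds[2],
             fits$start$slope_ci95[2], fits$start$intercept_ci95[2],
             fits$end$slope_ci95[2], fits$end$intercept_ci95[2],
             fits$production$slope_ci95[2], fits$production$intercept_ci95[2],
             max(pnorm_vals), params$a + a_halfwidth),
    stringsAsFactors = FALSE
  )
  parameter_ranges(tab)
}

#' Construct a parameter-ranges object
#'
#' @param tab data.frame with columns `name`, `low`, `high`; `low < high`
#'   required for every row.
#' @return The validated `parameter_ranges` object.
#' @export
parameter_ranges <- function(tab) {
  stopifnot(all(c("name", "low", "high") %in% names(tab)))
  bad <- which(!(tab$low < tab$high))
  if (length(bad))
    stop("low must be strictly below high for parameter(s): ",
         paste(tab$name[bad], collapse = ", "))
  structure(tab, class = c("parameter_ranges", "data.frame"))
}

#' Morris one-at-a-time trajectory design
#'
#' Samples `p` random trajectories on a `levels`-level grid of the unit
#' hypercube with step `delta = levels / (2 * (levels - 1))`, scaled to the
#' physical ranges. Each trajectory has `k + 1` points; consecutive points
#' differ in exactly one coordinate by `delta` (on the unit scale), each
#' coordinate moving exactly once per trajectory in random order and random
#' direction. The design has `N = p * (k + 1)` rows.
#'
#' @param ranges A [parameter_ranges()] (k rows).
#' @param p Number of trajectories (>= 1); the standard screen uses
#'   `p = 100`, giving 1000 runs for k = 9.
#' @param levels Number of grid levels (even, >= 4); default 4.
#' @param seed Integer seed; identical seed reproduces the design.
#' @return Numeric matrix `N x k` (columns named by parameter) with
#'   attributes `trajectory` (row -> trajectory id), `unit` (the design on
#'   the unit scale) and `delta`.
#' @export
morris_sample <- function(ranges, p, levels = 4L, seed = 1L) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  p <- as.integer(p); levels <- as.integer(levels)
  if (p < 1L) stop("p must be >= 1")
  if (levels < 4L || levels %% 2L != 0L)
    stop("levels must be an even integer >= 4")
  k <- nrow(ranges)
  delta <- levels / (2 * (levels - 1))
  grid_vals <- seq(0, 1, length.out = levels)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 5003), kind = "Mersenne-Twister")

  unit <- matrix(0, p * (k + 1L), k)
  traj_id <- rep(seq_len(p), each = k + 1L)
  for (tr in seq_len(p)) {
    dir <- sample(c(-1, 1), k, replace = TRUE)
    base <- vapply(seq_len(k), function(j) {
      ok <- grid_vals[grid_vals + dir[j] * delta >= -1e-12 &
                      grid_vals + dir[j] * delta <= 1 + 1e-12]
      ok[sample.int(length(ok), 1L)]
    }, 0)
    order_j <- sample.int(k)
    pts <- matrix(base, k + 1L, k, byrow = TRUE)
    x <- base
    for (step in seq_len(k)) {
      j <- order_j[step]
      x[j] <- min(max(x[j] + dir[j] * delta, 0), 1)
      pts[step + 1L, ] <- x
    }
    unit[(tr - 1L) * (k + 1L) + seq_len(k + 1L), ] <- pts
  }
  design <- sweep(sweep(unit, 2L, ranges$high - ranges$low, "*"),
                  2L, ranges$low, "+")
  colnames(design) <- ranges$name
  attr(design, "trajectory") <- traj_id
  attr(design, "unit") <- unit
  attr(design, "delta") <- delta
  design
}

#' Evaluate the emission model over a Morris design
#'
#' For each design row, overwrites the taxon's nine parameters with the
#' row's values, simulates a single year, and returns the domain-average
#' (cosine-latitude-weighted) maximum daily pollen emission. Rows whose
#' parameters produce an entirely degenerate season are returned as `NA`
#' and counted.
#'
#' @param design Matrix from [morris_sample()] with the nine canonical
#'   parameter columns.
#' @param base_params The taxon's parameter row (non-screened fields, taxon
#'   identity and PFT are kept).
#' @param climate A `climate_grid` covering the simulated year and its
#'   predecessor.
#' @param landcover A `landcover_map` containing the taxon.
#' @param year Year to simulate (default: second climate year).
#' @param co2_mode `"off"` or `"doubled"`.
#' @return Numeric vector of length `nrow(design)`; attribute `n_failed`
#'   counts degenerate rows.
#' @export
run_model_over_design <- function(design, base_params, climate, landcover,
                                  year = NULL, co2_mode = "off") {
  if (is.null(year)) year <- climate$years[2L]
  nms <- morris_parameter_names()
  if (!all(nms %in% colnames(design)))
    stop("design must contain the nine canonical parameter columns")
  out <- rep(NA_real_, nrow(design))
  n_failed <- 0L
  for (i in seq_len(nrow(design))) {
    pr <- base_params
    pr[nms] <- as.list(design[i, nms])
    ef <- simulate_taxon(pr, climate, landcover, co2_mode, years = year,
                         quiet = TRUE)
    em <- emission_max(ef)
    if (all(!is.finite(em))) { n_failed <- n_failed + 1L; next }
    out[i] <- regional_average(em, climate$grid, "domain")
  }
  if (n_failed > 0L)
    message(sprintf("run_model_over_design: %d design row(s) degenerate (NA output)",
                    n_failed))
  attr(out, "n_failed") <- n_failed
  out
}

#' Elementary effects from a trajectory design
#'
#' For each trajectory and each parameter's single move, the elementary
#' effect is the output change divided by the signed unit-scale step,
#' `EE = (f_after - f_before) / delta_signed`, so a linear model
#' `f = sum c_j x_j` on unit ranges yields `EE_j = c_j` for every
#' trajectory regardless of move direction. Moves touching a missing output
#' give a missing effect, excluded from the statistics.
#'
#' @param design Matrix from [morris_sample()].
#' @param outputs Numeric vector aligned with the design rows.
#' @param ranges The [parameter_ranges()] used to build the design.
#' @return Matrix `p x k` of elementary effects (columns named by
#'   parameter), possibly containing `NA`.
#' @export
elementary_effects <- function(design, outputs, ranges) {
  if (length(outputs) != nrow(design))
    stop("outputs must align with the design rows")
  unit <- attr(design, "unit")
  traj <- attr(design, "trajectory")
  if (is.null(unit) || is.null(traj))
    stop("design must carry its 'unit' and 'trajectory' attributes")
  k <- ncol(design)
  p <- length(unique(traj))
  ee <- matrix(NA_real_, p, k, dimnames = list(NULL, colnames(design)))
  n_dropped <- 0L
  for (tr in seq_len(p)) {
    rows <- which(traj == tr)
    for (s in seq_len(length(rows) - 1L)) {
      i0 <- rows[s]; i1 <- rows[s + 1L]
      dj <- unit[i1, ] - unit[i0, ]
      j <- which(abs(dj) > 1e-12)
      if (length(j) != 1L) stop("trajectory step must change exactly one coordinate")
      if (is.na(outputs[i0]) || is.na(outputs[i1])) { n_dropped <- n_dropped + 1L; next }
      ee[tr, j] <- (outputs[i1] - outputs[i0]) / dj[j]
    }
  }
  if (n_dropped > 0L)
    message(sprintf("elementary_effects: %d effect(s) dropped (missing outputs)",
                    n_dropped))
  ee
}

#' Morris screening indices
#'
#' Per parameter: `mu_star`, the mean absolute elementary effect (overall
#' influence), and `sigma`, the sample standard deviation of the effects
#' (nonlinearity and interaction). Ranks are descending by `mu_star`
#' (respectively `sigma`); ties are broken by the larger companion index,
#' then by parameter order.
#'
#' @param ee Elementary-effects matrix from [elementary_effects()].
#' @return An object of class `morris_result`: data.frame (parameter,
#'   mu_star, sigma, rank_mu_star, rank_sigma, n_effects), plus
#'   `n_trajectories` and `n_runs` attributes.
#' @export
morris_indices <- function(ee) {
  k <- ncol(ee)
  n_valid <- colSums(!is.na(ee))
  if (any(n_valid == 0L))
    stop("no valid elementary effects for parameter(s): ",
         paste(colnames(ee)[n_valid == 0L], collapse = ", "))
  mu_star <- colMeans(abs(ee), na.rm = TRUE)
  sigma <- apply(ee, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) stats::sd(x) else 0
  })
  rank_mu <- integer(k); rank_sg <- integer(k)
  rank_mu[order(-mu_star, -sigma, seq_len(k))] <- seq_len(k)
  rank_sg[order(-sigma, -mu_star, seq_len(k))] <- seq_len(k)
  res <- data.frame(parameter = colnames(ee), mu_star = unname(mu_star),
                    sigma = unname(sigma), rank_mu_star = rank_mu,
                    rank_sigma = rank_sg, n_effects = unname(n_valid),
                    stringsAsFactors = FALSE)
  structure(res, class = c("morris_result", "data.frame"),
            n_trajectories = nrow(ee), n_runs = nrow(ee) * (k + 1L))
}

#' Full Morris screen for one taxon
#'
#' Samples the design, evaluates the one-year emission model over it, and
#' computes the screening indices.
#'
#' @inheritParams run_model_over_design
#' @inheritParams morris_sample
#' @return A `morris_result` (see [morris_indices()]).
#' @export
morris_screen <- function(ranges, base_params, climate, landcover, p = 100L,
                          levels = 4L, seed = 1L, year = NULL,
                          co2_mode = "off") {
  design <- morris_sample(ranges, p, levels, seed)
  outputs <- run_model_over_design(design, base_params, climate, landcover,
                                   year, co2_mode)
  morris_indices(elementary_effects(design, outputs, ranges))
}

#' Top-ranked parameters per taxon
#'
#' Reports, per taxon, the four highest-ranked parameters by `mu_star` and
#' by `sigma` — the variables with the largest overall influence on the
#' simulated emission maximum.
#'
#' @param results Named list of `morris_result` (names = taxa).
#' @param top Number of parameters to report (default 4).
#' @return data.frame (taxon, criterion, rank, parameter, value).
#' @export
rank_report <- function(results, top = 4L) {
  rows <- list()
  for (tx in names(results)) {
    r <- results[[tx]]
    for (crit in c("mu_star", "sigma")) {
      rk <- if (crit == "mu_star") r$rank_mu_star else r$rank_sigma
      sel <- order(rk)[seq_len(min(top, nrow(r)))]
      rows[[paste(tx, crit)]] <- data.frame(
        taxon = tx, criterion = crit, rank = rk[sel],
        parameter = r$parameter[sel], value = r[[crit]][sel],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
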