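#' Generate synthetic per-taxon land-cover fraction maps
#'
#' Produces spatially smooth vegetated-area fractions per taxon by bilinear
#' interpolation of a coarse random surface, so that regional averages are
#' non-degenerate. Each taxon's fraction lies in `[0, 0.9/n_taxa]`, hence the
#' per-cell sum over taxa is at most 0.9 by construction.
#'
#' @param grid A [grid_spec()].
#' @param taxa Character vector of taxon labels (non-empty).
#' @param seed Integer seed; identical seed reproduces an identical map.
#' @param fill Optional single fraction in `[0, 1]`: every taxon gets this
#'   constant value everywhere (sum over taxa must still be <= 1).
#' @param coarse Coarse-surface resolution (cells per side) controlling the
#'   spatial smoothness scale; smaller is smoother.
#' @return An object of class `landcover_map` holding `fraction`, an array
#'   with dimensions (taxon, lat, lon), values in `[0, 1]`.
#' @examples
#' lc <- generate_landcover(grid_spec(4, 5), c("Quercus", "Betula"), seed = 1)
#' range(lc$fraction)
#' @export
generate_landcover <- function(grid, taxa, seed, fill = NULL, coarse = c(4L, 5L)) {
  stopifnot(inherits(grid, "grid_spec"))
  taxa <- as.character(taxa)
  if (length(taxa) < 1L) stop("taxa must be non-empty")
  nt <- length(taxa)
  frac <- array(0, dim = c(nt, grid$n_lat, grid$n_lon),
                dimnames = list(taxon = taxa, NULL, NULL))
  if (!is.null(fill)) {
    if (fill < 0 || fill > 1) stop("fill must be in [0, 1]")
    if (fill * nt > 1) stop("fill * n_taxa exceeds 1: cell fractions would not sum to <= 1")
    frac[] <- fill
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 2003), kind = "Mersenne-Twister")
    cap <- 0.9 / nt
    for (it in seq_len(nt)) {
      surf <- matrix(stats::runif(prod(coarse)), coarse[1], coarse[2])
      frac[it, , ] <- cap * bilinear_upsample(surf, grid$n_lat, grid$n_lon)
    }
  }
  structure(list(fraction = frac, taxa = taxa, grid = grid, units = "1"),
            class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  cat(sprintf("<landcover_map> %d taxa on %d x %d cells, mean fraction %.3f\n",
              length(x$taxa), x$grid$n_lat, x$grid$n_lon, mean(x$fraction)))
  invisible(x)
}

# Bilinear interpolation of a coarse matrix onto an n_lat x n_lon grid,
# coarse nodes placed at the fine grid's corners.
bilinear_upsample <- function(surf, n_lat, n_lon) {
  cr <- nrow(surf); cc <- ncol(surf)
  xi <- if (n_lat == 1L) 1 else seq(1, cr, length.out = n_lat)
  yj <- if (n_lon == 1L) 1 else seq(1, cc, length.out = n_lon)
  i0 <- pmin(floor(xi), cr - 1L); j0 <- pmin(floor(yj), cc - 1L)
  if (cr == 1L) i0[] <- 1L
  if (cc == 1L) j0[] <- 1L
  fx <- xi - i0; fy <- yj - j0
  out <- matrix(0, n_lat, n_lon)
  for (j in seq_len(n_lon)) {
    jl <- j0[j]; jr <- min(jl + 1L, cc)
    a <- surf[, jl] * (1 - fy[j]) + surf[, jr] * fy[j]
    il <- i0; ir <- pmin(il + 1L, cr)
    out[, j] <- a[il] * (1 - fx) + a[ir] * fx
  }
  out
}

# Fraction matrix (lat x lon) for one taxon, by name.
landcover_fraction <- function(landcover, taxon) {
  it <- match(taxon, landcover$taxa)
  if (is.na(it)) stop(sprintf("taxon '%s' not present in land-cover map", taxon))
  g <- landcover$grid
  matrix(landcover$fraction[it, , , drop = FALSE], g$n_lat, g$n_lon)
}
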