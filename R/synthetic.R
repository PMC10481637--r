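#' Default inter-category correlation target
#'
#' Correlation structure of the latent category factors used by
#' [sample_panel()]: seven determinant categories plus one health-condition
#' factor. The default magnitudes follow the reported pattern for this kind
#' of panel — a strong positive link between economic status (A.1) and
#' education (A.2), negative links of both with the demographic situation
#' (A.3), positive association of A.1/A.2 with health condition (B.1), and
#' weak links elsewhere.
#'
#' @return an 8 x 8 symmetric positive-definite correlation matrix with
#'   dimnames `A.1`…`A.7`, `B.1`.
#' @export
default_category_correlation <- function() {
  labs <- c(paste0("A.", 1:7), "B.1")
  r <- diag(8)
  dimnames(r) <- list(labs, labs)
  set_pair <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_pair("A.1", "A.2", 0.60)
  set_pair("A.1", "A.3", -0.45)
  set_pair("A.2", "A.3", -0.55)
  set_pair("A.1", "B.1", 0.55)
  set_pair("A.2", "B.1", 0.55)
  set_pair("A.3", "B.1", -0.15)
  set_pair("A.6", "B.1", 0.22)
  set_pair("A.1", "A.6", 0.20)
  set_pair("A.4", "A.5", 0.15)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(min(ev) > 1e-8)
  r
}

#' Configuration for the synthetic panel generator
#'
#' Defines the study conditions the generator emulates: 77 regions on a
#' rectangular lattice, 33 determinant indicators in seven categories plus
#' 24 health indicators, two periods, a target inter-category correlation
#' structure, a per-category temporal drift, and optional spatial
#' autocorrelation, hotspot plants and missingness.
#'
#' @param n_regions number of regions (default 77).
#' @param rows,cols lattice dimensions covering `n_regions` (default 7 x 11).
#' @param category_sizes named integer vector of indicators per category
#'   (default `A.1`–`A.5` with 5, `A.6`–`A.7` with 4 — 33 determinants —
#'   and `B.1` with 24).
#' @param correlation target correlation matrix of the latent category
#'   factors; default [default_category_correlation()]. Must be symmetric
#'   positive definite with one row per category.
#' @param loading loading of each indicator on its category factor
#'   (default 0.8); the rest is independent indicator noise.
#' @param minimize_fraction fraction of indicators of minimize direction
#'   (default 0.5).
#' @param drift named per-category latent mean shift from period 1 to period
#'   2, in factor sd units. Default: mild improvement (+0.2) for most
#'   determinant categories, deterioration for the demographic situation
#'   (A.3, -0.2) and road safety (A.6, -0.1), and a slight decline of health
#'   condition (B.1, -0.15) — the qualitative temporal story of this kind of
#'   panel.
#' @param innovation_sd sd of the period-2 innovation noise on the latent
#'   factors (default 0.3).
#' @param rho spatial autocorrelation coefficient in `[0, 0.9]` applied to
#'   the latent fields (default 0, no spatial structure).
#' @param hotspot optional list `list(block = region ids, shift_sd = )`
#'   planting a uniformly worse block (default `NULL`).
#' @param missing_rate fraction of cells set missing (default 0).
#' @param seed integer RNG seed (mandatory).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 77, rows = 7, cols = 11,
                             category_sizes = c(A.1 = 5, A.2 = 5, A.3 = 5,
                                                A.4 = 5, A.5 = 5, A.6 = 4,
                                                A.7 = 4, B.1 = 24),
                             correlation = default_category_correlation(),
                             loading = 0.8,
                             minimize_fraction = 0.5,
                             drift = c(A.1 = 0.2, A.2 = 0.2, A.3 = -0.2,
                                       A.4 = 0.2, A.5 = 0.1, A.6 = -0.1,
                                       A.7 = 0.2, B.1 = -0.15),
                             innovation_sd = 0.3,
                             rho = 0, hotspot = NULL, missing_rate = 0,
                             seed) {
  if (missing(seed)) stopf("a seed is mandatory for the synthetic generator")
  if (rows * cols < n_regions) stopf("lattice %dx%d cannot cover %d regions",
                                     rows, cols, n_regions)
  if (n_regions < 2) stopf("need at least 2 regions")
  cats <- names(category_sizes)
  if (is.null(cats) || any(category_sizes < 1)) {
    stopf("category_sizes must be a named vector of counts >= 1")
  }
  if (!all(cats %in% valid_categories())) {
    stopf("unknown category in category_sizes")
  }
  if (!identical(dim(correlation), c(length(cats), length(cats)))) {
    stopf("correlation must be %d x %d", length(cats), length(cats))
  }
  if (max(abs(correlation - t(correlation))) > 1e-12) {
    stopf("correlation matrix must be symmetric")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stopf("correlation target not positive definite")
  if (rho < 0 || rho > 0.9) stopf("rho must lie in [0, 0.9]")
  if (loading <= 0 || loading > 1) stopf("loading must lie in (0, 1]")
  drift_full <- stats::setNames(rep(0, length(cats)), cats)
  drift_full[names(drift)[names(drift) %in% cats]] <-
    drift[names(drift) %in% cats]
  structure(list(n_regions = n_regions, rows = rows, cols = cols,
                 category_sizes = category_sizes, correlation = correlation,
                 loading = loading, minimize_fraction = minimize_fraction,
                 drift = drift_full, innovation_sd = innovation_sd,
                 rho = rho, hotspot = hotspot, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Unit-square lattice geometry
#'
#' Generates `rows x cols` unit squares (row-major region ids `R001`, `R002`,
#' …), keeping the first `n_regions` when given.
#'
#' @param rows,cols positive lattice dimensions.
#' @param n_regions optional number of regions to keep (default all).
#' @return a [region_geometry_set()].
#' @export
make_lattice <- function(rows, cols, n_regions = rows * cols) {
  if (rows < 1 || cols < 1) stopf("lattice dimensions must be positive")
  if (n_regions > rows * cols) stopf("lattice too small for %d regions", n_regions)
  ids <- sprintf("R%03d", seq_len(n_regions))
  out <- stats::setNames(vector("list", n_regions), ids)
  k <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      k <- k + 1L
      if (k > n_regions) break
      x0 <- cc - 1; y0 <- r - 1
      ring <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                    c(x0, y0 + 1), c(x0, y0))
      out[[k]] <- list(list(ring))   # one part, one outer ring
    }
  }
  region_geometry_set(out)
}

# latent category factors -> spatial smoothing -> indicators
#' Sample a synthetic indicator panel
#'
#' Draws per-region latent category factors from a multivariate normal with
#' the configured correlation target, smooths them spatially when
#' `rho > 0`, derives each indicator as
#' `loading * factor + sqrt(1 - loading^2) * noise` on an indicator-specific
#' affine scale (so raw units are heterogeneous, as in real panels), flips
#' the sign of minimize-direction indicators, and builds period 2 as period
#' 1 plus the per-category drift and innovation noise. Both the latent
#' factors and the indicator-level noise persist across periods (period 2
#' adds innovations to period 1 rather than redrawing), so regions keep
#' their relative positions and systematic drifts are detectable against
#' the innovation noise, as in real administrative panels. Deterministic
#' under the configured seed (Mersenne-Twister).
#'
#' @param cfg a [synthetic_config()].
#' @return a list with elements `panel` ([indicator_panel()]), `criteria`
#'   ([criteria_spec()]), `geometry` ([region_geometry_set()]), and
#'   `latent` (the period-wise latent factor arrays, for diagnostics).
#' @export
sample_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_regions
  cats <- names(cfg$category_sizes)
  ncat <- length(cats)
  geoms <- make_lattice(cfg$rows, cfg$cols, n)
  ids <- names(geoms)

  f1 <- MASS::mvrnorm(n, mu = rep(0, ncat), Sigma = cfg$correlation)
  dimnames(f1) <- list(ids, cats)
  innov <- matrix(stats::rnorm(n * ncat, sd = cfg$innovation_sd), n, ncat)
  f2 <- f1 + matrix(cfg$drift, n, ncat, byrow = TRUE) + innov
  dimnames(f2) <- dimnames(f1)
  if (cfg$rho > 0) {
    w <- row_standardize(suppressWarnings(queen_contiguity(geoms)))
    f1 <- apply(f1, 2, smooth_field, w = w, rho = cfg$rho)
    f2 <- apply(f2, 2, smooth_field, w = w, rho = cfg$rho)
    dimnames(f1) <- dimnames(f2) <- list(ids, cats)
  }

  ind_cat <- rep(cats, times = cfg$category_sizes)
  nind <- length(ind_cat)
  ind_ids <- paste0(ind_cat, ".", unlist(lapply(cfg$category_sizes, seq_len),
                                         use.names = FALSE))
  direction <- ifelse(stats::runif(nind) < cfg$minimize_fraction,
                      "minimize", "maximize")
  scale <- stats::runif(nind, 0.5, 20)    # heterogeneous raw units
  offset <- stats::runif(nind, -10, 100)
  lam <- cfg$loading
  noise_sd <- sqrt(1 - lam^2)

  vals <- array(NA_real_, c(n, nind, 2),
                dimnames = list(ids, ind_ids, c("period1", "period2")))
  for (j in seq_len(nind)) {
    e1 <- stats::rnorm(n, sd = noise_sd)
    # indicator noise persists across periods (region effects) plus innovation
    e2 <- e1 + stats::rnorm(n, sd = cfg$innovation_sd)
    raw1 <- lam * f1[, ind_cat[j]] + e1
    raw2 <- lam * f2[, ind_cat[j]] + e2
    sgn <- if (direction[j] == "minimize") -1 else 1
    vals[, j, 1] <- offset[j] + scale[j] * sgn * raw1
    vals[, j, 2] <- offset[j] + scale[j] * sgn * raw2
  }
  panel <- indicator_panel(vals, ids, ind_ids, c("period1", "period2"))
  criteria <- criteria_spec(ind_ids, ind_cat, direction)

  if (!is.null(cfg$hotspot)) {
    panel <- plant_hotspot(panel, criteria, cfg$hotspot$block,
                           cfg$hotspot$shift_sd)
  }
  if (cfg$missing_rate > 0) {
    v <- panel$values
    drop <- which(stats::runif(length(v)) < cfg$missing_rate)
    v[drop] <- NA_real_
    panel <- indicator_panel(v, panel$region_ids, panel$indicator_ids,
                             panel$period_ids)
  }
  list(panel = panel, criteria = criteria, geometry = geoms,
       latent = list(period1 = f1, period2 = f2))
}

# iterated spatial moving average (1-rho) z + rho W z; isolates untouched
smooth_field <- function(z, w, rho, iter = 50, tol = 1e-8) {
  ids <- names(w$neighbors)
  names(z) <- ids
  for (s in seq_len(iter)) {
    lag <- spatial_lag(z, w)
    lag[is.na(lag)] <- z[is.na(lag)]
    znew <- (1 - rho) * z + rho * lag
    names(znew) <- ids
    if (max(abs(znew - z)) < tol) {
      z <- znew
      break
    }
    z <- znew
  }
  z
}

#' Spatially smooth the indicator fields of a panel
#'
#' Replaces each indicator's per-period field `z` by the iterated spatial
#' moving average `(1 - rho) z + rho W z` (row-standardized queen weights;
#' 50 iterations or convergence tolerance `1e-8`), raising its spatial
#' autocorrelation. `rho = 0` returns the panel unchanged; isolates are
#' excluded from smoothing with a warning.
#'
#' @param panel an [indicator_panel()].
#' @param geoms the matching [region_geometry_set()].
#' @param rho spatial autocorrelation coefficient in `[0, 1)`.
#' @param seed unused (the operation is deterministic); kept for interface
#'   symmetry with the other generator stages.
#' @return the smoothed [indicator_panel()].
#' @export
inject_spatial_structure <- function(panel, geoms, rho, seed = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  if (rho == 0) return(panel)
  w <- row_standardize(queen_contiguity(geoms))
  if (length(w$isolates)) {
    warnf("isolate region(s) excluded from spatial smoothing: %s",
          paste(w$isolates, collapse = ", "))
  }
  v <- panel$values
  for (j in seq_along(panel$indicator_ids)) {
    for (t in seq_along(panel$period_ids)) {
      v[, j, t] <- smooth_field(v[, j, t], w, rho)
    }
  }
  indicator_panel(v, panel$region_ids, panel$indicator_ids, panel$period_ids)
}

#' Plant a uniformly disadvantaged block of regions
#'
#' Shifts every indicator of the block regions by `shift_sd` times that
#' indicator's per-period standard deviation, with the sign chosen so the
#' block becomes uniformly worse on the composite indices (down for
#' maximize-type indicators, up for minimize-type ones).
#'
#' @param panel an [indicator_panel()].
#' @param criteria the matching [criteria_spec()] (provides directions).
#' @param block non-empty character vector of region ids.
#' @param shift_sd shift magnitude in per-indicator sd units; 0 is the
#'   identity.
#' @return the modified [indicator_panel()].
#' @export
plant_hotspot <- function(panel, criteria, block, shift_sd) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (length(block) == 0L) stopf("hotspot block must be non-empty")
  missing_b <- setdiff(block, panel$region_ids)
  if (length(missing_b)) stopf("block region(s) not in the panel: %s",
                               paste(missing_b, collapse = ", "))
  if (shift_sd == 0) return(panel)
  dir <- criteria$direction[match(panel$indicator_ids, criteria$indicator_id)]
  v <- panel$values
  for (j in seq_along(panel$indicator_ids)) {
    sgn <- if (dir[j] == "minimize") +1 else -1   # worse = more of a bad thing
    for (t in seq_along(panel$period_ids)) {
      s <- stats::sd(v[, j, t])
      v[block, j, t] <- v[block, j, t] + sgn * shift_sd * s
    }
  }
  indicator_panel(v, panel$region_ids, panel$indicator_ids, panel$period_ids)
}
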