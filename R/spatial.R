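#' Queen contiguity weights from region polygons
#'
#' Two regions are neighbors under the queen criterion when their boundaries
#' share at least one point (edge or corner contact). Shared points are
#' detected by matching polygon vertices after snapping coordinates to a
#' tolerance, the same convention contiguity builders use for administrative
#' polygons; boundaries that touch only between stored vertices are not
#' detected. Regions with no neighbor are flagged as isolates (empty weight
#' row) and excluded from LISA computations downstream.
#'
#' @param geoms a [region_geometry_set()].
#' @param snap coordinate snapping tolerance (default `1e-8`).
#' @return an object of class `spatial_weights`: list with `neighbors`
#'   (named list of neighbor id vectors), `weights` (matching numeric
#'   lists), `style` (`"binary"` or `"row"`), `isolates`.
#' @export
queen_contiguity <- function(geoms, snap = 1e-8) {
  stopifnot(inherits(geoms, "region_geometry_set"))
  ids <- names(geoms)
  vkey <- lapply(geoms, function(parts) {
    pts <- do.call(rbind, unlist(parts, recursive = FALSE))
    pts <- round(pts / snap) * snap
    unique(paste(sprintf("%.12g", pts[, 1]), sprintf("%.12g", pts[, 2]),
                 sep = "|"))
  })
  # invert: vertex key -> regions touching it
  touch <- split(rep(ids, lengths(vkey)), unlist(vkey, use.names = FALSE))
  nb <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (regs in touch) {
    if (length(regs) < 2L) next
    regs <- unique(regs)
    for (r in regs) nb[[r]] <- union(nb[[r]], setdiff(regs, r))
  }
  nb <- lapply(nb, sort)
  isolates <- ids[lengths(nb) == 0L]
  if (length(isolates)) {
    warnf("isolate region(s) with no neighbor: %s",
          paste(isolates, collapse = ", "))
  }
  structure(list(neighbors = nb,
                 weights = lapply(nb, function(x) rep(1, length(x))),
                 style = "binary", isolates = isolates),
            class = "spatial_weights")
}

#' Build spatial weights from an explicit neighbor list
#'
#' @param neighbors named list mapping each region id to its neighbor ids;
#'   adjacency must be symmetric.
#' @return a binary [queen_contiguity()]-style `spatial_weights` object.
#' @export
weights_from_neighbors <- function(neighbors) {
  ids <- names(neighbors)
  if (is.null(ids)) stopf("neighbors must be a named list")
  for (i in ids) {
    for (j in neighbors[[i]]) {
      if (identical(i, j)) stopf("self-neighbor: %s", i)
      if (!i %in% neighbors[[j]]) stopf("asymmetric adjacency: %s -> %s", i, j)
    }
  }
  nb <- lapply(neighbors, function(x) sort(as.character(x)))
  structure(list(neighbors = nb,
                 weights = lapply(nb, function(x) rep(1, length(x))),
                 style = "binary", isolates = ids[lengths(nb) == 0L]),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat(sprintf("Spatial weights (%s): %d regions, mean %.2f neighbors\n",
              x$style, length(k), mean(k)))
  if (length(x$isolates)) cat("  isolates:", paste(x$isolates, collapse = ", "), "\n")
  invisible(x)
}

#' Row-standardize spatial weights
#'
#' Each non-isolate region's weights are scaled to sum to 1; isolate rows
#' stay empty. Idempotent.
#'
#' @param w a `spatial_weights` object.
#' @return the row-standardized `spatial_weights`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  w$weights <- lapply(w$weights, function(ww) {
    if (length(ww) == 0L) ww else ww / sum(ww)
  })
  w$style <- "row"
  w
}

#' Local Moran's I
#'
#' Anselin's local Moran statistic per region:
#' `I_i = ((x_i - xbar) / m2) * sum_j w_ij (x_j - xbar)` with
#' `m2 = sum_k (x_k - xbar)^2 / n`. With row-standardized weights the
#' average of the `I_i` equals global Moran's I. Isolates get `NA`.
#'
#' @param values named numeric vector (names = region ids) or plain vector
#'   aligned with the weights.
#' @param w row-standardized `spatial_weights`.
#' @return named numeric vector of local Moran statistics.
#' @export
local_moran <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"))
  ids <- names(w$neighbors)
  if (!is.null(names(values))) {
    if (!all(ids %in% names(values))) stopf("values missing for some regions")
    values <- values[ids]
  } else if (length(values) != length(ids)) {
    stopf("values length does not match the weights")
  }
  if (anyNA(values)) stopf("missing values not allowed")
  if (stats::sd(values) == 0) stopf("local Moran undefined for a constant field")
  n <- length(values)
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  names(z) <- ids
  ii <- vapply(ids, function(i) {
    nbi <- w$neighbors[[i]]
    if (length(nbi) == 0L) return(NA_real_)
    (z[[i]] / m2) * sum(w$weights[[i]] * z[nbi])
  }, numeric(1))
  ii
}

# spatially lagged values (row-standardized weighted neighbor mean)
spatial_lag <- function(values, w) {
  ids <- names(w$neighbors)
  values <- if (!is.null(names(values))) values[ids] else values
  vapply(seq_along(ids), function(i) {
    nbi <- w$neighbors[[i]]
    if (length(nbi) == 0L) return(NA_real_)
    sum(w$weights[[i]] * values[match(nbi, ids)])
  }, numeric(1))
}

#' Global Moran's I
#'
#' @param values numeric field over the regions.
#' @param w row-standardized `spatial_weights`.
#' @return global Moran's I.
#' @export
global_moran <- function(values, w) {
  ids <- names(w$neighbors)
  keep <- lengths(w$neighbors) > 0L
  values <- if (!is.null(names(values))) values[ids] else values
  v <- values[keep]
  z <- v - mean(v)
  lag <- spatial_lag(stats::setNames(values, ids) - mean(v), w)[keep]
  sum(z * lag) / sum(z^2)
}

#' Conditional-permutation pseudo p-values for local Moran
#'
#' For each region the observed value is held fixed while the remaining
#' values are permuted across the other regions; the pseudo p-value is
#' `(1 + count of permuted local statistics at least as extreme in
#' magnitude as the observed one) / (n_permutations + 1)`. Because the
#' observed statistic is exchangeable with the permuted ones under the
#' null, this p-value is discrete-uniform and a test at level `alpha` has
#' null rejection rate `alpha` (up to the 1/(n_permutations + 1) grid).
#' Reproducible under a fixed seed.
#'
#' @param values numeric field over the regions.
#' @param w row-standardized `spatial_weights`.
#' @param n_permutations number of conditional permutations (default 999;
#'   fewer than 99 triggers a warning).
#' @param seed integer RNG seed (required for reproducibility).
#' @return named vector of pseudo p-values in `[1/(n_perm+1), 1]`; `NA` for
#'   isolates.
#' @export
permutation_pvalues <- function(values, w, n_permutations = 999, seed) {
  stopifnot(inherits(w, "spatial_weights"))
  if (missing(seed)) stopf("a seed is required for permutation inference")
  if (n_permutations < 99) warnf("fewer than 99 permutations gives coarse p-values")
  ids <- names(w$neighbors)
  values <- if (!is.null(names(values))) values[ids] else stats::setNames(values, ids)
  n <- length(values)
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  iobs <- local_moran(values, w)
  set.seed(as.integer(seed))
  p <- stats::setNames(rep(NA_real_, n), ids)
  for (i in seq_len(n)) {
    ki <- length(w$neighbors[[i]])
    if (ki == 0L) next
    zi <- z[i]
    pool <- z[-i]
    wi <- w$weights[[ids[i]]]
    # each permutation draws ki neighbor values without replacement
    perm_lag <- vapply(seq_len(n_permutations), function(s) {
      sum(wi * pool[sample.int(n - 1L, ki)])
    }, numeric(1))
    iperm <- (zi / m2) * perm_lag
    count <- sum(abs(iperm) >= abs(iobs[[i]]))
    p[i] <- (1 + count) / (n_permutations + 1)
  }
  p
}

#' Quadrant labels for local Moran results
#'
#' Significant regions are labelled by the sign pair (value above/below the
#' mean x spatial lag above/below the mean): `HH` and `LL` are spatial
#' clusters of similar values, `HL` and `LH` spatial outliers; all other
#' regions are `not-significant`.
#'
#' @param values numeric field.
#' @param lag spatial lag of `values`.
#' @param pvalues permutation pseudo p-values.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of labels.
#' @export
lisa_labels <- function(values, lag, pvalues, alpha = 0.05) {
  if (length(values) != length(lag) || length(values) != length(pvalues)) {
    stopf("values, lag and pvalues must be aligned")
  }
  zb <- values - mean(values)
  lb <- lag - mean(values)
  lab <- rep("not-significant", length(values))
  sig <- !is.na(pvalues) & pvalues < alpha
  lab[sig & zb >= 0 & lb >= 0] <- "HH"
  lab[sig & zb < 0 & lb < 0] <- "LL"
  lab[sig & zb >= 0 & lb < 0] <- "HL"
  lab[sig & zb < 0 & lb >= 0] <- "LH"
  lab
}

#' Local indicators of spatial association (LISA)
#'
#' Computes local Moran statistics, conditional-permutation pseudo p-values,
#' and HH/LL/HL/LH quadrant labels for a field over the regions.
#'
#' @param values named numeric field over the regions.
#' @param w `spatial_weights` (row-standardized automatically if binary).
#' @param n_permutations permutations for the pseudo p-values (default 999).
#' @param seed integer RNG seed.
#' @param alpha significance threshold for quadrant labels (default 0.05).
#' @return a data frame of class `lisa` with columns `region`, `value`,
#'   `Ii`, `lag`, `p`, `label`, and attributes `n_permutations`, `seed`,
#'   `alpha`.
#' @export
lisa <- function(values, w, n_permutations = 999, seed, alpha = 0.05) {
  if (w$style == "binary") w <- row_standardize(w)
  ids <- names(w$neighbors)
  values <- if (!is.null(names(values))) values[ids] else stats::setNames(values, ids)
  ii <- local_moran(values, w)
  lag <- spatial_lag(values, w)
  p <- permutation_pvalues(values, w, n_permutations, seed)
  lab <- lisa_labels(values, lag, p, alpha)
  lab[is.na(p)] <- "isolate"
  out <- data.frame(region = ids, value = unname(values), Ii = unname(ii),
                    lag = lag, p = unname(p), label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  class(out) <- c("lisa", "data.frame")
  out
}

#' @export
print.lisa <- function(x, ...) {
  cat(sprintf("LISA: %d regions, %d permutations, alpha = %g\n",
              nrow(x), attr(x, "n_permutations"), attr(x, "alpha")))
  print(table(label = x$label))
  invisible(x)
}

#' Fisher-Jenks natural breaks classification
#'
#' Exact optimal 1-D classification into `k` classes minimizing the total
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted values. Deterministic; equal values always share a class.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes (`>= 2`).
#' @return a list of class `jenks` with `breaks` (class boundaries,
#'   `k + 1` values from min to max: class `c` covers
#'   `(breaks[c], breaks[c+1]]`, the first class including its lower bound),
#'   `classes` (class index 1..k per input element), `k`, and `objective`
#'   (the minimized within-class SSD).
#' @export
jenks_breaks <- function(values, k) {
  if (anyNA(values)) stopf("missing values not allowed")
  if (k < 2) stopf("k must be >= 2")
  n <- length(values)
  if (length(unique(values)) < k) {
    stopf("need at least k = %d distinct values, got %d",
          k, length(unique(values)))
  }
  o <- order(values)
  x <- values[o]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  ssd <- function(i, j) {  # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # never split tied values: admissible class ends are positions where
  # x[j] < x[j+1] (plus n)
  cost <- matrix(Inf, k, n)     # cost[c, j]: best SSD of x[1..j] in c classes
  back <- matrix(0L, k, n)      # last class start position
  admissible_end <- c(x[-n] < x[-1], TRUE)
  for (j in which(admissible_end)) cost[1, j] <- ssd(1, j)
  back[1, ] <- 1L
  for (cl in 2:k) {
    for (j in which(admissible_end)) {
      if (j < cl) next
      starts <- which(admissible_end[seq_len(j - 1)]) + 1L
      if (length(starts) == 0L) next
      cand <- cost[cl - 1, starts - 1L] + vapply(starts, function(s) ssd(s, j),
                                                 numeric(1))
      b <- which.min(cand)
      cost[cl, j] <- cand[b]
      back[cl, j] <- starts[b]
    }
  }
  if (!is.finite(cost[k, n])) stopf("no admissible %d-class partition", k)
  # recover class boundaries
  bounds <- integer(k + 1)      # bounds[c] .. bounds[c+1]-1 is class c (sorted)
  bounds[k + 1] <- n + 1L
  j <- n
  for (cl in k:1) {
    bounds[cl] <- back[cl, j]
    j <- back[cl, j] - 1L
  }
  classes_sorted <- rep(seq_len(k), times = diff(bounds))
  classes <- integer(n)
  classes[o] <- classes_sorted
  breaks <- c(x[1], x[bounds[2:k] - 1L], x[n])
  structure(list(breaks = breaks, classes = classes, k = k,
                 objective = cost[k, n]),
            class = "jenks")
}

#' @export
print.jenks <- function(x, ...) {
  cat(sprintf("Fisher-Jenks classification: %d classes, objective %.6g\n",
              x$k, x$objective))
  cat("  breaks:", paste(signif(x$breaks, 6), collapse = " | "), "\n")
  print(table(class = x$classes))
  invisible(x)
}

#' Bivariate high/low classification of two indices
#'
#' Classifies each region on two indices with Fisher-Jenks natural breaks
#' (`kA`, `kB` classes) and derives the combined label: `high-high` when the
#' region is in the top class of both, `low-low` when in the bottom class of
#' both, `high-low` / `low-high` for the opposed extremes (A then B), and
#' `middle` otherwise.
#'
#' @param indexA,indexB aligned numeric vectors (e.g. a category index and
#'   the health-condition index).
#' @param kA,kB numbers of natural-breaks classes per axis (default 4).
#' @return a data frame of class `bivariate_class` with columns `classA`,
#'   `classB`, `label` (and `region` when the inputs are named).
#' @export
bivariate_classify <- function(indexA, indexB, kA = 4, kB = 4) {
  if (length(indexA) != length(indexB)) stopf("indexA and indexB must be aligned")
  ja <- jenks_breaks(indexA, kA)
  jb <- jenks_breaks(indexB, kB)
  a_hi <- ja$classes == kA; a_lo <- ja$classes == 1L
  b_hi <- jb$classes == kB; b_lo <- jb$classes == 1L
  label <- rep("middle", length(indexA))
  label[a_hi & b_hi] <- "high-high"
  label[a_lo & b_lo] <- "low-low"
  label[a_hi & b_lo] <- "high-low"
  label[a_lo & b_hi] <- "low-high"
  out <- data.frame(classA = ja$classes, classB = jb$classes, label = label,
                    stringsAsFactors = FALSE)
  if (!is.null(names(indexA))) out <- cbind(region = names(indexA), out,
                                            stringsAsFactors = FALSE)
  class(out) <- c("bivariate_class", "data.frame")
  out
}

#' Share table of bivariate classes across periods
#'
#' Percentage of regions per bivariate label and period (the `middle` class
#' included so each period row sums to 100%).
#'
#' @param classes_by_period named list of [bivariate_classify()] results,
#'   one per period.
#' @param n total number of regions (must match every class vector).
#' @return a numeric matrix of class `share_table` (periods x labels) of
#'   percentages at full precision; the print method rounds to 1 decimal.
#' @export
share_table <- function(classes_by_period, n) {
  labels <- c("high-high", "high-low", "low-low", "low-high", "middle")
  rows <- lapply(classes_by_period, function(cl) {
    if (nrow(cl) != n) stopf("class vector length %d does not match n = %d",
                             nrow(cl), n)
    100 * as.numeric(table(factor(cl$label, labels))) / n
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(classes_by_period), labels)
  structure(m, n = n, class = c("share_table", "matrix"))
}

#' @export
print.share_table <- function(x, ...) {
  cat(sprintf("Share of regions per bivariate class (%%; n = %d)\n", attr(x, "n")))
  y <- unclass(x)
  attr(y, "n") <- NULL
  print(round(y, 1))
  invisible(x)
}

#' Write spatial weights as a plain-text adjacency list
#'
#' One line per region: `region_id: neighbor1 neighbor2 ...`.
#'
#' @param w a `spatial_weights` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  lines <- vapply(names(w$neighbors), function(i) {
    paste0(i, ": ", paste(w$neighbors[[i]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
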