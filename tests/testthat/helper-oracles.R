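# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and the Lance-Williams recurrence, the
# Jenks DP and the convolution-based exact Wilcoxon p), so agreement is a
# genuine cross-check.

# tiny long-format panel builder
toy_panel <- function(df) indicator_panel(df)

# exhaustive Ward agglomeration: at each step compute the ESS increase of
# every candidate merge directly from the definition and take the minimum
# (lexicographic tie-break on cluster creation order)
ward_bruteforce <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  ess <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_cost)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# all ways to split sorted values into k contiguous classes; returns the
# minimal within-class SSD
jenks_bruteforce_objective <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (col in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, col], n)
    # reject partitions that split tied values
    ok <- all(vapply(2:(length(cuts) - 1), function(i) {
      x[cuts[i]] < x[cuts[i] + 1]
    }, logical(1)))
    if (!ok) next
    obj <- sum(vapply(seq_len(k), function(cl) {
      ssd(x[(cuts[cl] + 1):cuts[cl + 1]])
    }, numeric(1)))
    best <- min(best, obj)
  }
  best
}

# exact two-sided signed-rank p by direct enumeration over sign vectors
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_plus_obs <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  w_obs <- min(v_plus_obs, total - v_plus_obs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v <- as.vector(signs %*% r)
  mean(pmin(v, total - v) <= w_obs + 1e-9)
}

# 4-neighbor / 8-neighbor grid adjacency built by coordinate arithmetic,
# independent of the polygon-based builder
grid_queen_neighbors <- function(rows, cols) {
  ids <- sprintf("R%03d", seq_len(rows * cols))
  nb <- list()
  cell <- function(r, cc) (r - 1) * cols + cc
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      res <- character(0)
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; ccc <- cc + dc
          if (rr >= 1 && rr <= rows && ccc >= 1 && ccc <= cols) {
            res <- c(res, ids[cell(rr, ccc)])
          }
        }
      }
      nb[[ids[cell(r, cc)]]] <- sort(res)
    }
  }
  nb
}

# shoelace polygon area of a closed ring
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# adjusted Rand index between two labelings (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
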