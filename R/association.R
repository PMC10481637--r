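#' Pearson product-moment correlation
#'
#' Thin validated wrapper around the product-moment coefficient: requires
#' equal-length vectors of at least 3 observations and refuses constant
#' vectors, for which the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Correlation matrix of category indices
#'
#' Pairwise Pearson correlations of the category composite indices across
#' regions, for one period. With `include_b1 = TRUE` the health-condition
#' index `B.1` is included, so its column gives the category-vs-health
#' correlations.
#'
#' @param object a [wsa()] fit.
#' @param period period label; defaults to the first period.
#' @param include_b1 include the `B.1` index? Default `FALSE` (determinant
#'   categories only).
#' @return a symmetric correlation matrix of class `corr_matrix` with a
#'   `period` attribute.
#' @export
correlation_matrix <- function(object, period = NULL, include_b1 = FALSE) {
  stopifnot(inherits(object, "wsa_index"))
  period <- period %||% object$panel$period_ids[1]
  cats <- setdiff(dimnames(object$index)[[2]], "aggregate")
  if (!include_b1) cats <- setdiff(cats, "B.1")
  m <- object$index[, cats, period, drop = TRUE]
  const <- which(apply(m, 2, stats::sd) == 0)
  if (length(const)) {
    stopf("correlation undefined: constant index %s in period %s",
          colnames(m)[const[1]], period)
  }
  r <- stats::cor(m)
  diag(r) <- 1
  structure(r, period = period, class = c("corr_matrix", class(r)))
}

#' @export
print.corr_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix (period %s)\n", attr(x, "period")))
  y <- unclass(x)
  attr(y, "period") <- NULL
  print(round(y, digits))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests a location change between paired observations (the same regions at
#' two times). Differences `d = late - early` are taken, zeros dropped, the
#' absolute differences ranked (average ranks for ties), and
#' `W = min(V+, V-)` formed from the signed-rank sums. The exact two-sided
#' p-value enumerates all `2^n` sign assignments (used when
#' `n_effective <= 25` and there are no ties in `|d|`); otherwise a normal
#' approximation with tie-corrected variance and no continuity correction is
#' used.
#'
#' @param x_early,x_late paired numeric vectors of equal length.
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return a list of class `wilcoxon_sr` with `n_effective`, `statistic`
#'   (`W`), `v_plus`, `p_value`, `method`, and `degenerate` (all differences
#'   zero; then `p = 1` by convention).
#' @export
wilcoxon_signed_rank <- function(x_early, x_late,
                                 mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x_early) != length(x_late)) stopf("paired vectors of equal length required")
  if (anyNA(x_early) || anyNA(x_late)) stopf("missing values not allowed")
  d <- x_late - x_early
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_effective = 0L, statistic = 0, v_plus = 0,
                          p_value = 1, method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_sr"))
  }
  r <- rank(abs(d))
  v_plus <- sum(r[d > 0])
  v_minus <- n * (n + 1) / 2 - v_plus
  w <- min(v_plus, v_minus)
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = n <= 25L && !ties)
  if (use_exact && ties) {
    warnf("exact enumeration with tied |d|; p-value uses the tied ranks as observed")
  }
  if (use_exact) {
    p <- wilcoxon_exact_p(r, w)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(n_effective = n, statistic = w, v_plus = v_plus,
                 p_value = p, method = method, degenerate = FALSE),
            class = "wilcoxon_sr")
}

# exact two-sided p by full enumeration of the 2^n sign assignments:
# the fraction of assignments whose min(V+, V-) is <= the observed W
wilcoxon_exact_p <- function(ranks, w_obs) {
  n <- length(ranks)
  total <- n * (n + 1) / 2
  # distribution of V+ over all sign assignments via iterated convolution
  # on the half-rank grid (supports tied average ranks, which are .5 grids)
  grid <- 2L  # work in units of 1/2 so tied average ranks stay integral
  rr <- as.integer(round(ranks * grid))
  tot <- sum(rr)
  f <- numeric(tot + 1)  # f[v + 1] = count of assignments with grid*V+ = v
  f[1] <- 1
  for (ri in rr) {
    shifted <- numeric(tot + 1)
    shifted[(ri + 1):(tot + 1)] <- f[1:(tot + 1 - ri)]
    f <- f + shifted
  }
  vplus <- (0:tot) / grid
  wmin <- pmin(vplus, total - vplus)
  sum(f[wmin <= w_obs + 1e-9]) / 2^n
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat("Wilcoxon signed-rank test (paired)\n")
  cat(sprintf("  n_effective = %d, W = %g, V+ = %g\n",
              x$n_effective, x$statistic, x$v_plus))
  cat(sprintf("  p-value = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

#' Temporal change tests for every determinant
#'
#' Runs a paired Wilcoxon signed-rank test of change between two periods for
#' each indicator, on the raw (not normalized) values, and flags significant
#' changes at `alpha`. No multiple-testing adjustment is applied by default,
#' matching a raw per-test threshold; `adjust = "BH"` switches on a
#' Benjamini-Hochberg correction.
#'
#' @param panel an [indicator_panel()].
#' @param pair a [period_pair()]; defaults to (first, last) period.
#' @param alpha significance threshold (default 0.05).
#' @param mode passed to [wilcoxon_signed_rank()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a data frame of class `change_test` with columns `indicator`,
#'   `n_effective`, `W`, `p`, `significant`; indicators missing a period are
#'   excluded with a warning. The non-significant indicators are listed in
#'   the `non_significant` attribute.
#' @export
change_test_suite <- function(panel, pair = NULL, alpha = 0.05,
                              mode = "auto", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(panel, "indicator_panel"))
  if (is.null(pair)) {
    pair <- period_pair(panel$period_ids[1],
                        panel$period_ids[length(panel$period_ids)], panel)
  }
  rows <- lapply(panel$indicator_ids, function(ind) {
    e <- panel$values[, ind, pair$earlier]
    l <- panel$values[, ind, pair$later]
    if (anyNA(e) || anyNA(l)) {
      warnf("indicator %s missing values in a period; excluded from change tests", ind)
      return(NULL)
    }
    t <- wilcoxon_signed_rank(e, l, mode)
    data.frame(indicator = ind, n_effective = t$n_effective,
               W = t$statistic, p = t$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stopf("no testable indicators")
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p, "BH")
  pcol <- if (adjust == "BH") out$p_adjusted else out$p
  out$significant <- pcol < alpha
  rownames(out) <- NULL
  attr(out, "non_significant") <- out$indicator[!out$significant]
  attr(out, "alpha") <- alpha
  attr(out, "pair") <- pair
  class(out) <- c("change_test", "data.frame")
  out
}

#' @export
print.change_test <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("Paired Wilcoxon change tests, %s -> %s (alpha = %g)\n",
              pair$earlier, pair$later, attr(x, "alpha")))
  cat(sprintf("  %d of %d indicators changed significantly\n",
              sum(x$significant), nrow(x)))
  ns <- attr(x, "non_significant")
  if (length(ns)) cat("  not significant:", paste(ns, collapse = ", "), "\n")
  invisible(x)
}
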