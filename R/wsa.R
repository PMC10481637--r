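#' Ideal and basal criterion bounds
#'
#' For each indicator, the ideal value is the best observed value and the
#' basal value the worst, defining the min-max normalization range. With
#' `scope = "pooled"` (the default) the bounds pool observations across all
#' periods, so index levels are comparable over time; with
#' `scope = "per_period"` bounds are recomputed within each period.
#'
#' @param panel a validated [indicator_panel()].
#' @param scope `"pooled"` or `"per_period"`.
#' @return a data frame of class `criterion_bounds` with columns
#'   `indicator_id`, `period` (`NA` for pooled), `basal`, `ideal`,
#'   `degenerate`. Bounds are observed min/max; a constant indicator is
#'   flagged degenerate (and triggers a warning).
#' @export
compute_bounds <- function(panel, scope = c("pooled", "per_period")) {
  scope <- match.arg(scope)
  stopifnot(inherits(panel, "indicator_panel"))
  if (anyNA(panel$values)) {
    stopf("panel has missing values; run validate_panel() first")
  }
  if (scope == "pooled") {
    basal <- apply(panel$values, 2, min)
    ideal <- apply(panel$values, 2, max)
    out <- data.frame(indicator_id = panel$indicator_ids,
                      period = NA_character_,
                      basal = basal, ideal = ideal,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    out <- do.call(rbind, lapply(panel$period_ids, function(p) {
      m <- panel$values[, , p, drop = FALSE]
      data.frame(indicator_id = panel$indicator_ids, period = p,
                 basal = apply(m, 2, min), ideal = apply(m, 2, max),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  out$degenerate <- out$ideal == out$basal
  if (any(out$degenerate)) {
    warnf("degenerate bounds (constant indicator) for: %s",
          paste(unique(out$indicator_id[out$degenerate]), collapse = ", "))
  }
  class(out) <- c("criterion_bounds", "data.frame")
  out
}

#' Min-max normalize a criterion value
#'
#' Maps a raw criterion value onto the `[0, 1]` "higher is better" utility
#' scale: `(y - basal) / (ideal - basal)` for a maximize-type criterion,
#' `(ideal - y) / (ideal - basal)` for a minimize-type one. Degenerate bounds
#' (`ideal == basal`) yield the neutral value 0.5 with a warning, keeping the
#' criterion count stable rather than dropping the criterion.
#'
#' @param y numeric value(s) to normalize.
#' @param basal,ideal observed worst/best values of the criterion.
#' @param direction `"maximize"` or `"minimize"`.
#' @return normalized value(s) in `[0, 1]`.
#' @export
normalize_value <- function(y, basal, ideal, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (ideal < basal) stopf("ideal (%g) below basal (%g)", ideal, basal)
  if (ideal == basal) {
    warnf("degenerate bounds (basal == ideal == %g); returning neutral 0.5", basal)
    return(rep(0.5, length(y)))
  }
  if (any(y < basal | y > ideal)) {
    stopf("value %g outside [basal = %g, ideal = %g]; bounds must derive from the same panel",
          y[which(y < basal | y > ideal)[1]], basal, ideal)
  }
  r <- (y - basal) / (ideal - basal)
  # the minimize form (ideal - y)/(ideal - basal) is evaluated as 1 - r so
  # the direction-flip identity r -> 1 - r holds to the last bit
  if (direction == "maximize") r else 1 - r
}

# Normalized panel: rij in [0,1], all indicators oriented "higher is better".
normalize_panel <- function(panel, specs, scope = c("pooled", "per_period")) {
  scope <- match.arg(scope)
  check_criteria_cover(panel, specs)
  bounds <- suppressWarnings(compute_bounds(panel, scope))
  v <- panel$values
  out <- v
  dir <- specs$direction[match(panel$indicator_ids, specs$indicator_id)]
  for (j in seq_along(panel$indicator_ids)) {
    for (t in seq_along(panel$period_ids)) {
      b <- if (scope == "pooled") {
        bounds[bounds$indicator_id == panel$indicator_ids[j], ]
      } else {
        bounds[bounds$indicator_id == panel$indicator_ids[j] &
                 bounds$period == panel$period_ids[t], ]
      }
      if (b$degenerate) {
        out[, j, t] <- 0.5
      } else {
        out[, j, t] <- normalize_value(v[, j, t], b$basal, b$ideal, dir[j])
      }
    }
  }
  if (any(bounds$degenerate)) {
    warnf("degenerate bounds normalized to neutral 0.5 for: %s",
          paste(unique(bounds$indicator_id[bounds$degenerate]), collapse = ", "))
  }
  indicator_panel(out, panel$region_ids, panel$indicator_ids, panel$period_ids)
}

#' Weighted-sum utility of a normalized criterion vector
#'
#' The WSA utility `u(a) = sum_j v_j r_j` of one alternative over `k`
#' criteria, with weights summing to 1, so the utility stays on the `[0, 1]`
#' scale of the normalized values.
#'
#' @param r numeric vector of normalized criterion values in `[0, 1]`.
#' @param weights positive weights of the same length, summing to 1
#'   (tolerance `1e-9`); defaults to equal weights.
#' @return the utility, a number in `[0, 1]`.
#' @export
wsa_utility <- function(r, weights = NULL) {
  k <- length(r)
  weights <- weights %||% rep(1 / k, k)
  if (length(weights) != k) stopf("length mismatch: %d values, %d weights",
                                  k, length(weights))
  if (abs(sum(weights) - 1) > 1e-9) {
    stopf("weights must sum to 1 (got %.12g)", sum(weights))
  }
  if (any(weights <= 0)) stopf("weights must be positive")
  sum(weights * r)
}

#' Category composite index
#'
#' WSA utility of each region, per period, over the indicators of one
#' category with equal weights — phase 1 of the index construction.
#'
#' @param panel a validated [indicator_panel()].
#' @param specs a [criteria_spec()].
#' @param category one of `A.1`–`A.7`, `B.1`.
#' @param bounds_scope normalization scope, see [compute_bounds()].
#' @return a numeric matrix, regions x periods.
#' @export
category_index <- function(panel, specs, category,
                           bounds_scope = c("pooled", "per_period")) {
  bounds_scope <- match.arg(bounds_scope)
  ids <- specs$indicator_id[specs$category == category]
  ids <- intersect(panel$indicator_ids, ids)
  if (length(ids) == 0L) stopf("category %s has no indicators in the panel", category)
  np <- normalize_panel(panel, specs, bounds_scope)
  idx <- apply(np$values[, ids, , drop = FALSE], c(1, 3), mean)
  dimnames(idx) <- list(panel$region_ids, panel$period_ids)
  idx
}

#' Aggregate health-inequality index
#'
#' Phase 2: the WSA utility over all determinant indicators (categories
#' `A.1`–`A.7` together; `B.1` is excluded by construction). With
#' `mode = "all_determinants"` (default) every determinant gets the same
#' weight `1/k` over the full determinant set; with
#' `mode = "mean_of_categories"` the aggregate is the unweighted mean of the
#' seven category indices. The two coincide when all categories are the same
#' size.
#'
#' @inheritParams category_index
#' @param mode `"all_determinants"` or `"mean_of_categories"`.
#' @return a numeric matrix, regions x periods.
#' @export
aggregate_index <- function(panel, specs,
                            bounds_scope = c("pooled", "per_period"),
                            mode = c("all_determinants", "mean_of_categories")) {
  bounds_scope <- match.arg(bounds_scope)
  mode <- match.arg(mode)
  acats <- setdiff(intersect(valid_categories(), unique(specs$category)), "B.1")
  if (length(acats) == 0L) stopf("no determinant categories (A.x) in the criteria")
  if (mode == "all_determinants") {
    ids <- specs$indicator_id[specs$category %in% acats]
    ids <- intersect(panel$indicator_ids, ids)
    np <- normalize_panel(panel, specs, bounds_scope)
    idx <- apply(np$values[, ids, , drop = FALSE], c(1, 3), mean)
  } else {
    mats <- lapply(acats, function(cc) {
      suppressWarnings(category_index(panel, specs, cc, bounds_scope))
    })
    idx <- Reduce(`+`, mats) / length(mats)
  }
  dimnames(idx) <- list(panel$region_ids, panel$period_ids)
  idx
}

#' Fit the full set of WSA composite indices
#'
#' The central fitting function: for every region and period it computes the
#' composite index of each determinant category (`A.1`–`A.7`), the health
#' condition index (`B.1`), and the aggregate index over all determinants.
#' All indices live on the `[0, 1]` utility scale with higher values
#' indicating better outcomes.
#'
#' @param panel a validated [indicator_panel()].
#' @param specs a [criteria_spec()] covering every panel indicator.
#' @param bounds_scope `"pooled"` (default; index levels comparable across
#'   periods) or `"per_period"`.
#' @param aggregate_mode see [aggregate_index()].
#' @return an object of class `wsa_index`: a list with
#'   \item{index}{3-d array, regions x (categories, `B.1`, `aggregate`) x periods}
#'   \item{panel, specs}{the inputs}
#'   \item{bounds}{the [compute_bounds()] table used}
#'   \item{bounds_scope, aggregate_mode}{the configuration}
#' @examples
#' syn <- sample_panel(synthetic_config(n_regions = 20, seed = 1))
#' fit <- wsa(syn$panel, syn$criteria)
#' summary(fit)
#' @export
wsa <- function(panel, specs, bounds_scope = c("pooled", "per_period"),
                aggregate_mode = c("all_determinants", "mean_of_categories")) {
  bounds_scope <- match.arg(bounds_scope)
  aggregate_mode <- match.arg(aggregate_mode)
  panel <- validate_panel(panel, specs, policy = "error")
  cats <- intersect(valid_categories(), unique(specs$category))
  cols <- c(cats, "aggregate")
  idx <- array(NA_real_,
               c(length(panel$region_ids), length(cols), length(panel$period_ids)),
               dimnames = list(panel$region_ids, cols, panel$period_ids))
  for (cc in cats) {
    idx[, cc, ] <- suppressWarnings(category_index(panel, specs, cc, bounds_scope))
  }
  idx[, "aggregate", ] <- suppressWarnings(
    aggregate_index(panel, specs, bounds_scope, aggregate_mode))
  structure(list(index = idx, panel = panel, specs = specs,
                 bounds = suppressWarnings(compute_bounds(panel, bounds_scope)),
                 bounds_scope = bounds_scope, aggregate_mode = aggregate_mode),
            class = "wsa_index")
}

#' @export
print.wsa_index <- function(x, ...) {
  d <- dim(x$index)
  cat(sprintf("WSA composite indices: %d regions, %d indices (%s), %d period(s)\n",
              d[1], d[2], paste(dimnames(x$index)[[2]], collapse = ", "), d[3]))
  cat(sprintf("  bounds scope: %s; aggregate mode: %s\n",
              x$bounds_scope, x$aggregate_mode))
  invisible(x)
}

#' @export
coef.wsa_index <- function(object, period = NULL, ...) {
  p <- period %||% utils::tail(object$panel$period_ids, 1)
  object$index[, , p]
}

#' @export
as.data.frame.wsa_index <- function(x, ...) {
  d <- dimnames(x$index)
  out <- expand.grid(region = d[[1]], index = d[[2]], period = d[[3]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.vector(x$index)
  out
}

#' Summarize composite indices (descriptive statistics per period)
#'
#' Minimum, maximum, mean and median of each index per period — the standard
#' descriptive table for comparing index levels across periods.
#'
#' @param object a [wsa()] fit.
#' @param ... unused.
#' @return a data frame of class `summary.wsa_index` with one row per
#'   (index, period).
#' @export
summary.wsa_index <- function(object, ...) {
  d <- dimnames(object$index)
  rows <- expand.grid(index = d[[2]], period = d[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_of <- function(v) c(min = min(v), max = max(v),
                            mean = mean(v), median = stats::median(v))
  st <- t(mapply(function(i, p) stats_of(object$index[, i, p]),
                 rows$index, rows$period))
  out <- cbind(rows, as.data.frame(st))
  rownames(out) <- NULL
  class(out) <- c("summary.wsa_index", "data.frame")
  out
}

#' @export
print.summary.wsa_index <- function(x, digits = 2, ...) {
  cat("Composite index descriptive statistics by period\n")
  y <- x
  for (cn in c("min", "max", "mean", "median")) y[[cn]] <- round(y[[cn]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.wsa_index <- function(x, which = "aggregate", ...) {
  m <- x$index[, which, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 1, dimnames = list(NULL, x$panel$period_ids))
  graphics::boxplot(m, ylab = paste(which, "index"), xlab = "period", ...)
  invisible(x)
}

#' Period-to-period change of a composite index
#'
#' For each region, the difference `later - earlier` of the chosen index,
#' together with counts of declining (`delta < 0`), improving (`delta > 0`)
#' and tied (`delta == 0`, reported separately, never folded into the other
#' two) regions, and per-period mean/median levels with their differences.
#'
#' @param object a [wsa()] fit with at least two periods.
#' @param pair a [period_pair()]; defaults to (first period, last period).
#' @param which index name: a category label, `"B.1"`, or `"aggregate"`.
#' @return a list of class `index_change` with elements `delta` (named
#'   vector), `n_decline`, `n_improve`, `n_tie`, `levels` (mean/median per
#'   period and difference), `which`, `pair`.
#' @export
index_change <- function(object, pair = NULL, which = "aggregate") {
  stopifnot(inherits(object, "wsa_index"))
  periods <- object$panel$period_ids
  if (is.null(pair)) {
    if (length(periods) < 2L) stopf("need at least two periods")
    pair <- period_pair(periods[1], periods[length(periods)], object$panel)
  }
  if (!which %in% dimnames(object$index)[[2]]) {
    stopf("unknown index \"%s\"", which)
  }
  early <- object$index[, which, pair$earlier]
  late <- object$index[, which, pair$later]
  if (anyNA(early) || anyNA(late)) {
    stopf("region present in only one period for index %s", which)
  }
  delta <- late - early
  levels <- data.frame(
    period = c(pair$earlier, pair$later, "difference"),
    mean = c(mean(early), mean(late), mean(late) - mean(early)),
    median = c(stats::median(early), stats::median(late),
               stats::median(late) - stats::median(early)),
    stringsAsFactors = FALSE)
  structure(list(delta = delta,
                 n_decline = sum(delta < 0),
                 n_improve = sum(delta > 0),
                 n_tie = sum(delta == 0),
                 levels = levels, which = which, pair = pair),
            class = "index_change")
}

#' @export
print.index_change <- function(x, ...) {
  n <- length(x$delta)
  cat(sprintf("Change in %s index, %s -> %s (n = %d regions)\n",
              x$which, x$pair$earlier, x$pair$later, n))
  cat(sprintf("  decline: %d (%.0f%%)  improve: %d (%.0f%%)  tie: %d\n",
              x$n_decline, 100 * x$n_decline / n,
              x$n_improve, 100 * x$n_improve / n, x$n_tie))
  print.data.frame(transform(x$levels, mean = round(mean, 3),
                             median = round(median, 3)), row.names = FALSE)
  invisible(x)
}
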