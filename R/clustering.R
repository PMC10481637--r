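#' Squared Euclidean distance between two coordinate vectors
#'
#' @param a,b numeric vectors of equal dimension.
#' @return `sum((a - b)^2)`.
#' @export
squared_euclidean <- function(a, b) {
  if (length(a) != length(b)) stopf("dimension mismatch: %d vs %d",
                                    length(a), length(b))
  sum((a - b)^2)
}

#' Ward agglomerative linkage
#'
#' Hierarchical agglomeration that at each step merges the pair of clusters
#' whose union minimally increases the total within-cluster sum of squares
#' (Ward's criterion on squared Euclidean distances), implemented via the
#' Lance-Williams recurrence. The merge height recorded for each step is the
#' Ward cost increase itself (so two singletons `a`, `b` merge at
#' `||a - b||^2 / 2`). Ties are broken deterministically by the
#' lexicographically smallest pair of cluster indices, so runs are
#' bit-for-bit reproducible.
#'
#' @param x numeric matrix, one row per region (rownames used as labels), or
#'   a numeric vector for one-dimensional features.
#' @return an object of class `ward_tree` with `merge` / `height` / `labels`
#'   in [stats::hclust()] conventions plus the feature matrix in `$data`.
#'   Convert with [as.hclust()] for dendrogram plotting.
#' @export
ward_linkage <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stopf("need at least 2 regions to cluster")
  if (anyNA(x)) stopf("missing coordinates not allowed")
  labels <- rownames(x) %||% as.character(seq_len(n))
  # initial Ward costs: ||xi - xj||^2 / 2 for singleton pairs
  d <- as.matrix(stats::dist(x))^2 / 2
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1, n)
  # hclust id convention: -i for singleton i, step number for a merged cluster
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dm <- d[idx, idx, drop = FALSE]
    best <- which(dm == min(dm), arr.ind = TRUE)
    # lexicographically smallest (i, j) with i < j among tied minima
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    height[step] <- d[i, j]
    merge[step, ] <- sort_merge_pair(id[i], id[j])
    # Lance-Williams update for Ward on the cost matrix
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      dnew <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
      d[i, k] <- dnew
      d[k, i] <- dnew
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 data = x, method = "ward"),
            class = "ward_tree")
}

# merge-row convention: singletons (negative) before merged clusters,
# otherwise the smaller entry first; within-row order is cosmetic
sort_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(max(a, b), min(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("Ward linkage tree: %d regions, %d merges\n",
              length(x$labels), length(x$height)))
  cat(sprintf("  merge heights (Ward cost): %.4g .. %.4g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = tree_order(x$merge, length(x$labels)),
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "squared euclidean"),
            class = "hclust")
}

# leaf ordering by left-to-right traversal of the merge tree
tree_order <- function(merge, n) {
  res <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    l <- merge[s, 1]; r <- merge[s, 2]
    lv <- if (l < 0) -l else res[[l]]
    rv <- if (r < 0) -r else res[[r]]
    res[[s]] <- c(lv, rv)
  }
  res[[n - 1L]]
}

#' @export
plot.ward_tree <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' Removes the `k - 1` highest merges and relabels the resulting clusters
#' `1..k` by descending cluster mean of `order_by` (by default the row means
#' of the clustered features): when the features are composite indices on
#' the higher-is-better scale, cluster 1 is the best-off group (smallest
#' inequalities) and cluster `k` the most disadvantaged.
#'
#' @param tree a [ward_linkage()] tree.
#' @param k number of clusters (default 4).
#' @param order_by optional numeric vector (one value per region, e.g. the
#'   aggregate index) used to order cluster labels.
#' @return an integer vector of class `cluster_assignment`, named by region,
#'   with attribute `k`.
#' @export
cut_to_k <- function(tree, k = 4, order_by = NULL) {
  stopifnot(inherits(tree, "ward_tree"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stopf("k must be in [1, %d]", n)
  raw <- stats::cutree(stats::as.hclust(tree), k = k)
  score <- order_by %||% rowMeans(tree$data)
  if (length(score) != n) stopf("order_by must have one value per region")
  means <- tapply(score, raw, mean)
  relab <- order(order(-means))  # rank of each raw cluster by descending mean
  out <- relab[raw]
  names(out) <- tree$labels
  structure(out, k = k, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("Cluster assignment: %d regions in %d clusters\n", length(x), k))
  print(table(cluster = unclass(x)))
  invisible(x)
}

#' z-score standardization (population variant)
#'
#' `(x - mean(x)) / sd_pop(x)` with the population (1/n) standard deviation:
#' the region set is treated as the complete population, not a sample. A
#' positive z marks a value above the mean.
#'
#' @param values non-constant numeric vector.
#' @return vector of z-scores with mean 0 and population sd exactly 1.
#' @export
zscore <- function(values) {
  if (anyNA(values)) stopf("missing values not allowed")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stopf("z-scores undefined for a constant vector")
  (values - m) / s
}

#' Mean z-score profile of each cluster
#'
#' Standardizes each category index across all regions of one period
#' (population z-scores), then averages within clusters. The size-weighted
#' mean of cluster means is 0 for every category by construction, so
#' profiles read as above/below the national average.
#'
#' @param assignment a [cut_to_k()] assignment.
#' @param object a [wsa()] fit (or a plain numeric matrix of features,
#'   regions x variables).
#' @param period period label (used when `object` is a `wsa_index`);
#'   defaults to the first period.
#' @param categories index columns to profile; defaults to the determinant
#'   categories `A.1`–`A.7` present in the fit.
#' @return a numeric matrix of class `cluster_profile`, clusters x
#'   categories, of mean z-scores.
#' @export
cluster_profile <- function(assignment, object, period = NULL,
                            categories = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (inherits(object, "wsa_index")) {
    period <- period %||% object$panel$period_ids[1]
    categories <- categories %||%
      grep("^A\\.", dimnames(object$index)[[2]], value = TRUE)
    m <- object$index[, categories, period, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1, dimnames = list(names(assignment), categories))
  } else {
    m <- as.matrix(object)
  }
  if (!all(names(assignment) %in% rownames(m))) {
    stopf("region(s) in the assignment have no index values: %s",
          paste(setdiff(names(assignment), rownames(m)), collapse = ", "))
  }
  m <- m[names(assignment), , drop = FALSE]
  z <- apply(m, 2, zscore)
  k <- attr(assignment, "k")
  prof <- t(vapply(seq_len(k), function(cl) {
    colMeans(z[assignment == cl, , drop = FALSE])
  }, numeric(ncol(z))))
  dimnames(prof) <- list(paste0("cluster_", seq_len(k)), colnames(m))
  structure(prof, sizes = as.integer(table(factor(assignment, seq_len(k)))),
            class = c("cluster_profile", "matrix"))
}

#' @export
print.cluster_profile <- function(x, digits = 2, ...) {
  cat("Mean z-score per category within clusters\n")
  y <- unclass(x)
  attr(y, "sizes") <- NULL
  print(round(y, digits))
  cat("cluster sizes:", paste(attr(x, "sizes"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cluster_profile <- function(x, ...) {
  y <- unclass(x)
  attr(y, "sizes") <- NULL
  graphics::barplot(t(y), beside = TRUE, legend.text = colnames(y),
                    ylab = "mean z-score", ...)
  graphics::abline(h = 0)
  invisible(x)
}
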