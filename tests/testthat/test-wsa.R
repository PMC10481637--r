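# small helper: panel with one period from a region x indicator matrix
matrix_panel <- function(m, periods = "t1") {
  arr <- array(m, c(nrow(m), ncol(m), length(periods)),
               dimnames = list(rownames(m), colnames(m), periods))
  indicator_panel(arr, rownames(m), colnames(m), periods)
}

test_that("bounds are observed min/max, pooled or per period", {
  df <- expand.grid(region = c("a", "b", "c"), indicator = "i1",
                    period = c("t1", "t2"), stringsAsFactors = FALSE)
  df$value <- c(2, 5, 9, 12, 15, 19)
  panel <- indicator_panel(df)
  b <- compute_bounds(panel, "pooled")
  expect_equal(b$basal, 2)
  expect_equal(b$ideal, 19)
  bp <- compute_bounds(panel, "per_period")
  expect_equal(bp$basal, c(2, 12))
  expect_equal(bp$ideal, c(9, 19))
  expect_false(any(b$degenerate))
})

test_that("constant indicators are flagged degenerate and normalize to 0.5", {
  m <- cbind(i1 = c(4, 4, 4), i2 = 1:3)
  rownames(m) <- c("a", "b", "c")
  panel <- matrix_panel(m)
  expect_warning(b <- compute_bounds(panel), "degenerate")
  expect_true(b$degenerate[b$indicator_id == "i1"])
  sp <- criteria_spec(c("i1", "i2"), c("A.1", "A.1"), rep("maximize", 2))
  np <- suppressWarnings(normalize_panel(panel, sp))
  expect_equal(unname(np$values[, "i1", 1]), rep(0.5, 3))
  expect_warning(normalize_value(3, 4, 4), "degenerate")
})

test_that("normalization matches the min-max formulas at boundaries and interior", {
  expect_equal(normalize_value(5, 0, 10, "maximize"), 0.5)
  expect_equal(normalize_value(10, 0, 10, "maximize"), 1.0)
  expect_equal(normalize_value(10, 0, 10, "minimize"), 0.0)
  expect_equal(normalize_value(2, 0, 10, "minimize"), 0.8)
  expect_equal(normalize_value(0, 0, 10, "minimize"), 1.0)
  expect_error(normalize_value(11, 0, 10, "maximize"), "outside")
})

test_that("direction flip maps r to 1 - r exactly", {
  y <- runif(25, -3, 7)
  b <- range(y)
  rmax <- normalize_value(y, b[1], b[2], "maximize")
  rmin <- normalize_value(y, b[1], b[2], "minimize")
  expect_identical(rmin, 1 - rmax)
})

test_that("normalization is invariant to positive affine rescaling (pooled scope)", {
  set.seed(11)
  m <- cbind(i1 = rnorm(8), i2 = runif(8))
  rownames(m) <- paste0("r", 1:8)
  sp <- criteria_spec(c("i1", "i2"), c("A.1", "A.2"), c("maximize", "minimize"))
  np1 <- normalize_panel(matrix_panel(m), sp)
  m2 <- m
  m2[, "i1"] <- 3.7 * m[, "i1"] + 11  # positive affine map
  np2 <- normalize_panel(matrix_panel(m2), sp)
  expect_equal(np2$values, np1$values, tolerance = 1e-12)
})

test_that("the WSA utility is the weighted mean of normalized values", {
  expect_equal(wsa_utility(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(wsa_utility(rep(1, 5)), 1)
  expect_equal(wsa_utility(c(0.5, 0.1), c(0.8, 0.2)), 0.42)
  expect_error(wsa_utility(c(0.5, 0.5), c(0.6, 0.6)), "sum to 1")
  expect_error(wsa_utility(c(0.5, 0.5), c(1)), "length mismatch")
})

test_that("category indices match an independent spreadsheet-style evaluation", {
  # 3 regions x 2 maximize indicators, evaluated by hand:
  # i1 in {2, 4, 6}: r = 0, .5, 1 ; i2 in {10, 30, 20}: r = 0, 1, .5
  m <- cbind(i1 = c(2, 4, 6), i2 = c(10, 30, 20))
  rownames(m) <- c("a", "b", "c")
  sp <- criteria_spec(c("i1", "i2"), c("A.1", "A.1"), rep("maximize", 2))
  idx <- category_index(matrix_panel(m), sp, "A.1")
  expect_equal(unname(idx[, 1]), c(0, 0.75, 0.75))
})

test_that("a single-indicator category index equals the normalized indicator", {
  m <- cbind(i1 = c(1, 3, 2))
  rownames(m) <- c("a", "b", "c")
  sp <- criteria_spec("i1", "A.2", "maximize")
  idx <- category_index(matrix_panel(m), sp, "A.2")
  expect_equal(unname(idx[, 1]), c(0, 1, 0.5))
})

test_that("the region attaining every ideal scores exactly 1", {
  set.seed(4)
  syn <- sample_panel(synthetic_config(n_regions = 10, seed = 4))
  v <- syn$panel$values
  dirs <- syn$criteria$direction
  for (j in seq_along(syn$panel$indicator_ids)) {
    best <- if (dirs[j] == "maximize") max(v[, j, ]) else min(v[, j, ])
    v[1, j, ] <- best
  }
  panel <- indicator_panel(v, syn$panel$region_ids, syn$panel$indicator_ids,
                           syn$panel$period_ids)
  fit <- wsa(panel, syn$criteria)
  expect_equal(max(abs(fit$index[1, , ] - 1)), 0, tolerance = 1e-12)
  expect_true(all(fit$index >= 0 & fit$index <= 1 + 1e-12))
})

test_that("aggregate equals the equal-weight utility over all determinants", {
  syn <- sample_panel(synthetic_config(n_regions = 12, seed = 9))
  np <- normalize_panel(syn$panel, syn$criteria)
  det <- syn$criteria$indicator_id[syn$criteria$category != "B.1"]
  agg <- aggregate_index(syn$panel, syn$criteria)
  # oracle: plain wsa_utility over the concatenated normalized vector
  for (r in c(1, 5, 12)) {
    for (t in 1:2) {
      expect_equal(agg[r, t], wsa_utility(np$values[r, det, t]),
                   tolerance = 1e-12)
    }
  }
})

test_that("both aggregate modes agree for equal-sized categories", {
  syn <- sample_panel(synthetic_config(
    n_regions = 8, category_sizes = c(A.1 = 3, A.2 = 3, A.3 = 3, B.1 = 2),
    correlation = diag(4), seed = 2))
  a1 <- aggregate_index(syn$panel, syn$criteria, mode = "all_determinants")
  a2 <- aggregate_index(syn$panel, syn$criteria, mode = "mean_of_categories")
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("improving a maximize indicator never decreases any containing index", {
  syn <- sample_panel(synthetic_config(n_regions = 10, seed = 6))
  fit <- wsa(syn$panel, syn$criteria)
  maxi <- which(syn$criteria$direction == "maximize")[1]
  ind <- syn$criteria$indicator_id[maxi]
  v <- syn$panel$values
  # lift region 3 toward (not beyond) the pooled ideal of that indicator
  v[3, ind, ] <- pmin(v[3, ind, ] + diff(range(v[, ind, ])) / 4, max(v[, ind, ]))
  fit2 <- wsa(indicator_panel(v, syn$panel$region_ids, syn$panel$indicator_ids,
                              syn$panel$period_ids), syn$criteria)
  cat_of <- syn$criteria$category[maxi]
  expect_true(all(fit2$index[3, c(cat_of, "aggregate"), ] >=
                    fit$index[3, c(cat_of, "aggregate"), ] - 1e-12))
})

test_that("index_change counts declines, improvements and ties separately", {
  idx <- array(0.5, c(3, 2, 2),
               dimnames = list(c("a", "b", "c"), c("A.1", "aggregate"),
                               c("t1", "t2")))
  idx[, "aggregate", "t2"] <- c(0.4, 0.7, 0.8)
  df <- expand.grid(region = c("a", "b", "c"), indicator = "x",
                    period = c("t1", "t2"), stringsAsFactors = FALSE)
  df$value <- 1:6
  fake <- structure(list(index = idx, panel = indicator_panel(df)),
                    class = "wsa_index")
  ch <- index_change(fake, which = "aggregate")
  expect_equal(ch$n_decline, 1L)
  expect_equal(ch$n_improve, 2L)
  expect_equal(ch$n_tie, 0L)
  expect_equal(unname(ch$delta), c(-0.1, 0.2, 0.3))
  ch0 <- index_change(fake, which = "A.1")
  expect_equal(ch0$n_tie, 3L)
  expect_equal(ch0$n_decline + ch0$n_improve, 0L)
})
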