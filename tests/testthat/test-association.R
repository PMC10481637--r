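test_that("pearson matches hand-computed product-moment values", {
  expect_equal(pearson(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson(1:3, c(6, 4, 2)), -1)
  expect_equal(pearson(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson of an affine transform is the slope sign", {
  set.seed(21)
  x <- rnorm(30)
  expect_equal(pearson(x, 2.5 * x + 1), 1)
  expect_equal(pearson(x, -0.3 * x + 4), -1)
})

test_that("correlation matrix is symmetric with unit diagonal and order-invariant", {
  syn <- sample_panel(synthetic_config(n_regions = 30, seed = 5))
  fit <- wsa(syn$panel, syn$criteria)
  cm <- correlation_matrix(fit, "period1", include_b1 = TRUE)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, 8))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # permuting region order leaves the matrix unchanged
  perm <- sample(syn$panel$region_ids)
  v <- syn$panel$values[perm, , ]
  fit2 <- wsa(indicator_panel(v, perm, syn$panel$indicator_ids,
                              syn$panel$period_ids), syn$criteria)
  expect_equal(unclass(correlation_matrix(fit2, "period1", include_b1 = TRUE)),
               unclass(cm), tolerance = 1e-12)
})

test_that("two categories built from identical indicators correlate perfectly", {
  m <- cbind(i1 = c(1, 5, 3, 8), i2 = c(1, 5, 3, 8))
  rownames(m) <- paste0("r", 1:4)
  arr <- array(m, c(4, 2, 1), dimnames = list(rownames(m), colnames(m), "t1"))
  panel <- indicator_panel(arr)
  sp <- criteria_spec(c("i1", "i2"), c("A.1", "A.2"), rep("maximize", 2))
  fit <- wsa(panel, sp)
  cm <- correlation_matrix(fit, "t1")
  expect_equal(cm["A.1", "A.2"], 1)
})

test_that("correlation is invariant to an increasing affine transform of one category", {
  syn <- sample_panel(synthetic_config(n_regions = 25, seed = 8))
  fit <- wsa(syn$panel, syn$criteria)
  cm <- correlation_matrix(fit, "period1")
  fit2 <- fit
  fit2$index[, "A.1", ] <- 0.2 + 0.5 * fit2$index[, "A.1", ]
  cm2 <- correlation_matrix(fit2, "period1")
  expect_equal(unclass(cm2), unclass(cm), tolerance = 1e-12)
})

test_that("generator correlation targets are recovered at panel scale", {
  # target r = 0.6 between the A.1 and A.2 latent factors at n = 77.
  # the category indices attenuate it (indicator noise averaged over ~5
  # indicators per category), so the empirical index-level correlation is
  # expected in [0.35, 0.8]
  hits <- 0L
  for (s in 1:10) {
    syn <- sample_panel(synthetic_config(seed = 100 + s))
    fit <- wsa(syn$panel, syn$criteria)
    r <- correlation_matrix(fit, "period1")["A.1", "A.2"]
    hits <- hits + (r >= 0.35 && r <= 0.8)
  }
  expect_gte(hits, 9L)
})

test_that("exact signed-rank p equals full sign enumeration", {
  # spec case: three all-positive differences
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 7))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.25)
  expect_identical(res$method, "exact")
  # random untied instances, n <= 10
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, sd = 3), 6)
    d <- d[d != 0]
    if (length(d) < 2) next
    res <- wilcoxon_signed_rank(rep(0, length(d)), d, mode = "exact")
    expect_equal(res$p_value, wilcoxon_enumeration_p(d), tolerance = 1e-12)
  }
})

test_that("identical paired samples give the degenerate p = 1", {
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_effective, 0L)
})

test_that("normal approximation matches the classical tie-corrected z test", {
  set.seed(7)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.3)
  mine <- wilcoxon_signed_rank(x, y, mode = "normal_approx")
  ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # with ties (rounded data) the tie-corrected variance must still agree
  xr <- round(x, 1); yr <- round(y, 1)
  mine2 <- wilcoxon_signed_rank(xr, yr, mode = "normal_approx")
  ref2 <- suppressWarnings(wilcox.test(yr, xr, paired = TRUE,
                                       exact = FALSE, correct = FALSE))
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-10)
})

test_that("a shifted pair is reliably detected at n = 100", {
  # shift of one sd: essentially always significant
  hits <- 0L
  set.seed(13)
  for (s in 1:20) {
    x <- rnorm(100)
    y <- x + rnorm(100) + 1
    hits <- hits + (wilcoxon_signed_rank(x, y)$p_value < 0.05)
  }
  expect_gte(hits, 20L * 0.99)
})

test_that("change-test suite bookkeeping: one row per testable determinant", {
  syn <- sample_panel(synthetic_config(n_regions = 20, seed = 17))
  tests <- change_test_suite(syn$panel)
  expect_equal(nrow(tests), length(syn$panel$indicator_ids))
  expect_true(all(tests$p > 0 & tests$p <= 1))
  expect_true(all(tests$W >= 0))
  expect_true(all(tests$W <= tests$n_effective * (tests$n_effective + 1) / 2))
})

test_that("an indicator identical across periods is flagged non-significant", {
  df <- expand.grid(region = paste0("r", 1:6), indicator = c("i1", "i2"),
                    period = c("t1", "t2"), stringsAsFactors = FALSE)
  df$value <- seq_len(nrow(df))
  panel <- indicator_panel(df)
  panel$values[, "i1", "t2"] <- panel$values[, "i1", "t1"]
  tests <- change_test_suite(panel)
  expect_false(tests$significant[tests$indicator == "i1"])
  expect_true("i1" %in% attr(tests, "non_significant"))
})

test_that("a uniform positive shift across 77 regions is significant with W = 0", {
  set.seed(2)
  base <- runif(77, 50, 150)
  df <- data.frame(region = rep(paste0("r", 1:77), 2),
                   indicator = "i1",
                   period = rep(c("t1", "t2"), each = 77),
                   value = c(base, base * 1.10))
  tests <- change_test_suite(indicator_panel(df))
  expect_equal(tests$W, 0)
  expect_true(tests$significant)
})
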