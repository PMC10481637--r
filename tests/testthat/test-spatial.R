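test_that("queen contiguity on small grids matches known degrees", {
  w22 <- queen_contiguity(make_lattice(2, 2))
  expect_equal(unname(lengths(w22$neighbors)), rep(3L, 4))   # corner contact counts
  w13 <- queen_contiguity(make_lattice(1, 3))
  expect_equal(unname(lengths(w13$neighbors)), c(1L, 2L, 1L))
})

test_that("queen contiguity on a 10x10 grid equals the arithmetic neighbor oracle", {
  w <- queen_contiguity(make_lattice(10, 10))
  oracle <- grid_queen_neighbors(10, 10)
  expect_identical(w$neighbors[names(oracle)], oracle)
})

test_that("adjacency is symmetric on random-sized lattices", {
  set.seed(50)
  for (rep in 1:5) {
    r <- sample(2:6, 1); cc <- sample(2:6, 1)
    w <- queen_contiguity(make_lattice(r, cc))
    for (i in names(w$neighbors)) {
      for (j in w$neighbors[[i]]) {
        expect_true(i %in% w$neighbors[[j]])
      }
    }
  }
})

test_that("row standardization sums rows to 1 and is idempotent", {
  w <- queen_contiguity(make_lattice(3, 3))
  ws <- row_standardize(w)
  expect_true(all(abs(vapply(ws$weights, sum, numeric(1)) - 1) < 1e-12))
  expect_equal(ws$weights[["R005"]], rep(1 / 8, 8))
  expect_identical(row_standardize(ws)$weights, ws$weights)
})

test_that("explicit neighbor lists reject self-neighbors and asymmetry", {
  expect_error(weights_from_neighbors(list(a = "a")), "self-neighbor")
  expect_error(weights_from_neighbors(list(a = "b", b = character(0))),
               "asymmetric")
})

test_that("local Moran matches the hand-computed line-graph case", {
  w <- row_standardize(weights_from_neighbors(
    list(a = "b", b = c("a", "c"), c = "b")))
  ii <- local_moran(c(a = 1, b = 1, c = -2), w)
  expect_equal(unname(ii), c(0.5, -0.25, -1.0))
  # centered antisymmetric values on the symmetric line: all zeros
  ii0 <- local_moran(c(a = 1, b = 0, c = -1), w)
  expect_equal(unname(ii0[2]), 0)
  expect_equal(sum(ii0), 0, tolerance = 1e-12)
  expect_error(local_moran(c(a = 1, b = 1, c = 1), w), "constant")
})

test_that("mean local Moran equals global Moran's I on random lattices", {
  set.seed(60)
  for (rep in 1:5) {
    g <- make_lattice(sample(3:6, 1), sample(3:6, 1))
    w <- row_standardize(queen_contiguity(g))
    x <- setNames(rnorm(length(g)), names(g))
    ii <- local_moran(x, w)
    expect_equal(mean(ii), global_moran(x, w), tolerance = 1e-9)
  }
})

test_that("permutation p-values are deterministic under a fixed seed and bounded", {
  g <- make_lattice(5, 5)
  w <- row_standardize(queen_contiguity(g))
  x <- setNames(rnorm(25), names(g))
  p1 <- permutation_pvalues(x, w, 199, seed = 11)
  p2 <- permutation_pvalues(x, w, 199, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 200 & p1 <= 1))
  expect_warning(permutation_pvalues(x, w, 49, seed = 1), "99")
})

test_that("a high cell in a depressed neighborhood is an HL outlier", {
  g <- make_lattice(5, 5)
  w <- row_standardize(queen_contiguity(g))
  set.seed(81)
  x <- setNames(rnorm(25), names(g))
  center <- "R013"
  x[center] <- 6
  x[w$neighbors[[center]]] <- -2   # uniformly low ring around a high cell
  res <- lisa(x, w, n_permutations = 999, seed = 3)
  expect_equal(res$label[res$region == center], "HL")
})

test_that("no labels are significant at alpha = 0", {
  g <- make_lattice(4, 4)
  w <- row_standardize(queen_contiguity(g))
  x <- setNames(rnorm(16), names(g))
  res <- lisa(x, w, n_permutations = 99, seed = 5, alpha = 0)
  expect_true(all(res$label == "not-significant"))
})

test_that("Jenks breaks separate well-separated groups and handle boundary k", {
  jb <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_equal(jb$classes, c(1, 1, 1, 2, 2, 2))
  expect_equal(jb$objective, 4)   # 2 + 2
  v <- c(4, 8, 15, 16, 23, 42)
  js <- jenks_breaks(v, 6)
  expect_equal(sort(unique(js$classes)), 1:6)   # singleton classes
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("Jenks DP objective equals the all-partitions brute force (n <= 20, k <= 4)", {
  set.seed(70)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    v <- round(rnorm(n, 50, 20), 2)
    if (length(unique(v)) < k) next
    expect_equal(jenks_breaks(v, k)$objective,
                 jenks_bruteforce_objective(v, k), tolerance = 1e-9)
  }
})

test_that("tied values always share a Jenks class", {
  v <- c(1, 2, 2, 2, 3, 9, 9, 10)
  jb <- jenks_breaks(v, 3)
  expect_equal(length(unique(jb$classes[v == 2])), 1L)
  expect_equal(length(unique(jb$classes[v == 9])), 1L)
})

test_that("bivariate classification labels the extreme corners", {
  a <- c(r1 = 0, r2 = 3, r3 = 5, r4 = 8, r5 = 10, r6 = 2, r7 = 7, r8 = 9)
  b <- c(r1 = 10, r2 = 4, r3 = 5, r4 = 2, r5 = 10, r6 = 8, r7 = 5, r8 = 0)
  bc <- bivariate_classify(a, b, kA = 4, kB = 4)
  expect_equal(bc$label[bc$region == "r5"], "high-high")  # max of both
  expect_equal(bc$label[bc$region == "r1"], "low-high")   # min A, max B
  expect_equal(bc$label[bc$region == "r8"], "high-low")
  expect_true(all(bc$label %in% c("high-high", "high-low", "low-low",
                                  "low-high", "middle")))
})

test_that("bivariate extreme-class counts match a constructed bimodal fixture", {
  # both axes exactly bimodal: with k = 2 the Jenks split falls in the gap,
  # so the four corner labels partition the regions by the quadrant of
  # (a > 5, b > 5), hand-tallied here
  a <- c(1.0, 1.1, 1.2, 1.3, 9.0, 9.1, 9.2, 9.3)
  b <- c(1.0, 9.1, 1.2, 9.3, 1.4, 9.5, 1.6, 9.7)
  names(a) <- names(b) <- paste0("r", 1:8)
  bc <- bivariate_classify(a, b, kA = 2, kB = 2)
  expect_equal(sum(bc$label == "high-high"), 2)
  expect_equal(sum(bc$label == "low-low"), 2)
  expect_equal(sum(bc$label == "high-low"), 2)
  expect_equal(sum(bc$label == "low-high"), 2)
})

test_that("share table reproduces count/n percentages and sums to 100", {
  lab <- rep("middle", 77)
  lab[1:7] <- "high-high"
  cl <- data.frame(classA = 1, classB = 1, label = lab)
  class(cl) <- c("bivariate_class", "data.frame")
  st <- share_table(list(p1 = cl), 77)
  expect_equal(round(st["p1", "high-high"], 1), 9.1)   # 7 of 77
  expect_equal(sum(st["p1", ]), 100)
  expect_error(share_table(list(p1 = cl[1:10, ]), 77), "does not match")
})

test_that("weights export as a plain-text adjacency list", {
  w <- queen_contiguity(make_lattice(1, 3))
  f <- withr::local_tempfile()
  write_weights(w, f)
  lines <- readLines(f)
  expect_equal(lines[1], "R001: R002")
  expect_equal(lines[2], "R002: R001 R003")
})
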