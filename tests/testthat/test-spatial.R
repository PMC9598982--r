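# aggregation, Moran's I, Gi*, hot-spot classes, zonal statistics

test_that("aggregate_to_units: identity, constants, hand means, nodata blocks", {
  m <- matrix(as.numeric(1:16), 4, 4)
  g <- hq_grid(m, pixel_size = 10)
  u1 <- aggregate_to_units(g, 1L)
  expect_equal(sort(u1$values), sort(as.vector(m)))
  u2 <- aggregate_to_units(g, 2L)
  expect_equal(length(u2$values), 4)
  # block means, blocks ordered row-major within block grid columns
  expected <- c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                mean(m[1:2, 3:4]), mean(m[3:4, 3:4]))
  expect_equal(u2$values, expected)
  # queen adjacency: all four blocks mutually adjacent
  expect_equal(sum(u2$adjacency), 12)
  # all-nodata block dropped
  m2 <- m; m2[1:2, 1:2] <- NA
  u3 <- aggregate_to_units(hq_grid(m2, 10), 2L)
  expect_equal(length(u3$values), 3)
  # constant raster -> equal unit values
  uc <- aggregate_to_units(hq_grid(matrix(5, 6, 6), 10), 3L)
  expect_true(all(uc$values == 5))
})

test_that("Moran's I: expectation, checkerboard, oracle, permutation reproducibility", {
  # 2x2 checkerboard with rook row-standardized weights -> I = -1
  vals <- c(1, -1, -1, 1)  # grid order: (1,1),(2,1),(1,2),(2,2)
  rook <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 0, 1), c(0, 1, 1, 0))
  w <- spatial_weights(rook, style = "row")
  mi <- morans_i(vals, w, permutations = 99, seed = 1)
  expect_equal(mi$I, -1)
  expect_equal(mi$expectation, -1 / 3)
  expect_equal(mi$I, brute_morans_i(vals, w$W))

  # vectorized == double loop at 1e-12 on random fields and weights
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:25, 1)
    adj <- matrix(runif(n * n) < 0.3, n, n)
    adj <- (adj | t(adj)); diag(adj) <- FALSE
    x <- rnorm(n)
    for (style in c("binary", "row")) {
      w <- spatial_weights(adj * 1, style = style)
      expect_equal(morans_i(x, w, permutations = 19, seed = 1)$I,
                   brute_morans_i(x, w$W), tolerance = 1e-12)
    }
  }

  # permutation p-value reproducible under a fixed seed
  set.seed(7); x <- rnorm(16)
  u <- aggregate_to_units(hq_grid(matrix(x, 4, 4), 10), 1L)
  w <- spatial_weights(u$adjacency, "row")
  p1 <- morans_i(u$values, w, permutations = 199, seed = 5)$p_perm
  p2 <- morans_i(u$values, w, permutations = 199, seed = 5)$p_perm
  expect_identical(p1, p2)

  expect_error(morans_i(rep(1, 9), w = spatial_weights(matrix(1, 9, 9))),
               "zero variance")
})

test_that("permutation invariance: relabeling units leaves I unchanged", {
  set.seed(11)
  n <- 20
  adj <- matrix(runif(n * n) < 0.25, n, n)
  adj <- (adj | t(adj)); diag(adj) <- FALSE
  x <- rnorm(n)
  w <- spatial_weights(adj * 1, "row")
  perm <- sample(n)
  w2 <- spatial_weights(adj[perm, perm] * 1, "row")
  expect_equal(morans_i(x, w, 19, 1)$I, morans_i(x[perm], w2, 19, 1)$I,
               tolerance = 1e-12)
})

test_that("Gi*: extremes, uniform weights, numerator sum under uniform weights", {
  # an extreme high value in a mildly elevated neighborhood: the unit holding
  # the extreme has the strictly largest local (self-inclusive) window sum
  m <- matrix(0, 5, 5); m[3, 3] <- 10
  m[cbind(c(2, 2, 2, 3, 3, 4, 4, 4), c(2, 3, 4, 2, 4, 2, 3, 4))] <- 1
  u <- aggregate_to_units(hq_grid(m, 10), 1L)
  w <- spatial_weights(u$adjacency, "binary", include_self = TRUE)
  z <- gi_star(u$values, w)
  center_unit <- which(u$row == 3 & u$col == 3)
  expect_equal(which.max(z), center_unit)
  expect_error(gi_star(rep(2, 25), w), "zero variance")
  expect_error(gi_star(u$values, spatial_weights(u$adjacency, "binary")),
               "include self")

  # uniform global weights (everyone neighbors everyone, incl self): z = 0,
  # and every numerator is exactly zero
  set.seed(3)
  x <- rnorm(12)
  wu <- spatial_weights(matrix(1, 12, 12), "binary", include_self = TRUE)
  expect_true(all(abs(gi_star(x, wu)) < 1e-8))
  Wu <- as.matrix(wu$W)
  num <- as.numeric(Wu %*% x) - mean(x) * rowSums(Wu)
  expect_equal(sum(abs(num)), 0, tolerance = 1e-9)
})

test_that("hot-spot classification thresholds and partition", {
  z <- c(0, 3, -2, 2, -3, 1.95, -1.95, 2.58, -2.58)
  cls <- classify_hotspots(z)
  expect_equal(as.character(cls),
               c("not significant", "hot", "sub-cold", "sub-hot", "cold",
                 "not significant", "not significant", "hot", "cold"))
  expect_error(classify_hotspots(c(1, NaN)), "non-finite")
  set.seed(2)
  zz <- rnorm(500, 0, 2)
  expect_false(anyNA(classify_hotspots(zz)))
})

test_that("zonal_mean: constant region, missing polygons, summary path", {
  m <- matrix(0.25, 20, 20); m[, 11:20] <- 0.75
  q <- hq_grid(m, pixel_size = 100)
  sq <- function(g, x0, x1, y0, y1)
    data.frame(group = g, x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  polys <- rbind(sq("A", 50, 450, 50, 450),      # inside the 0.25 half
                 sq("B", 1150, 1850, 1150, 1850), # inside the 0.75 half
                 sq("C", 5000, 6000, 5000, 6000)) # off the grid
  expect_warning(zm <- zonal_mean(q, polys), "missing")
  expect_equal(zm$groups$mean_quality[zm$groups$group == "A"], 0.25)
  expect_equal(zm$groups$mean_quality[zm$groups$group == "B"], 0.75)
  expect_true(is.na(zm$groups$mean_quality[zm$groups$group == "C"]))
  expect_equal(zm$overall_mean, 0.5)

  s <- zonal_summary(zm$groups)
  expect_equal(s$n_groups, 2)
  expect_equal(s$mean, 0.5)
  expect_equal(s$max, 0.75)
  expect_equal(s$max_group, "B")
})
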