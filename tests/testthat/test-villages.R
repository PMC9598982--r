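# village development: standardization, PCA, composite score, grades, KDE

test_that("standardize_indicators centers, scales, imputes, drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(10, NA, 30), c = c(5, 5, 5))
  expect_warning(s <- standardize_indicators(m), "constant")
  expect_equal(ncol(s), 2)
  expect_equal(attr(s, "dropped"), "c")
  expect_equal(unname(colMeans(s)), c(0, 0))
  expect_equal(unname(apply(s, 2, sd)), c(1, 1))
  # NA in b imputed with the median of (10, 30) = 20 -> symmetric column
  expect_equal(unname(s[, "b"]), unname(s[, "a"]))
  # idempotence
  s2 <- standardize_indicators(s)
  expect_equal(unname(s2[, 1:2]), unname(s[, 1:2]), tolerance = 1e-12)
  expect_error(standardize_indicators(cbind(a = c(1, 1), b = c(2, 2))),
               "all indicator columns are constant")
})

test_that("fit_pca: trace identity, Kaiser retention, sign orientation, weights", {
  cfg <- scene_config(n_villages = 200, seed = 31)
  v <- generate_villages(cfg)
  x <- standardize_indicators(v[, indicator_schema()$code])
  p <- fit_pca(x)
  expect_equal(sum(p$eigenvalues), 30, tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(p$k, sum(p$eigenvalues > 1))
  expect_equal(sum(p$weights), 1)
  expect_equal(unname(sqrt(colSums(p$loadings^2))), rep(1, p$k))
  for (j in seq_len(p$k))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # rank-1 noiseless input retains exactly one component
  cfg0 <- scene_config(n_villages = 300, noise_sd = 0, seed = 5)
  v0 <- generate_villages(cfg0)
  p0 <- fit_pca(standardize_indicators(v0[, indicator_schema()$code]))
  expect_equal(p0$k, 1)
})

test_that("comprehensive score is a mean-zero convex combination of scores", {
  cfg <- scene_config(n_villages = 150, seed = 13)
  v <- generate_villages(cfg)
  p <- fit_pca(standardize_indicators(v[, indicator_schema()$code]))
  z <- comprehensive_score(p)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_lte(max(abs(z)), max(abs(p$scores)))
  if (p$k == 1) expect_equal(z, as.numeric(p$scores[, 1]))
})

test_that("scale invariance: rescaling an indicator column leaves Z unchanged", {
  cfg <- scene_config(n_villages = 120, seed = 17)
  v <- generate_villages(cfg)
  ind <- v[, indicator_schema()$code]
  z1 <- comprehensive_score(fit_pca(standardize_indicators(ind)))
  ind$X31 <- ind$X31 * 1000
  ind$X11 <- ind$X11 * 7.5
  z2 <- comprehensive_score(fit_pca(standardize_indicators(ind)))
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("grade_villages implements the seven half-open intervals", {
  z <- c(-3, -0.5, -0.2, 0, 0.3, 0.5, 0.9, 1, 1.5, 2, 5)
  g <- grade_villages(z)
  expect_equal(as.character(g),
               c("I", "II", "II", "III", "III", "IV", "IV", "V", "VI",
                 "VII", "VII"))
  expect_error(grade_villages(c(0, NaN)), "non-finite")
  # partition: every finite score gets exactly one grade
  set.seed(1)
  zz <- rnorm(1000, 0, 2)
  expect_false(anyNA(grade_villages(zz)))
  expect_equal(sum(table(grade_villages(zz))), 1000)
})

test_that("parameter recovery: Z tracks the latent development factor", {
  for (seed in 1:5) {
    cfg <- scene_config(n_villages = 500, latent_sd = 1, noise_sd = 0.3,
                        seed = seed)
    v <- generate_villages(cfg)
    scored <- village_scores(v)
    rho <- cor(scored$score, v$latent, method = "spearman")
    expect_gte(abs(rho), 0.9)
  }
})

test_that("quartic kernel density: positivity, mass, linearity, peak location", {
  g <- hq_grid(matrix(0, 50, 50), pixel_size = 10)
  pt <- data.frame(x = 250, y = 250)
  h <- 60  # 6 pixels
  d1 <- kernel_density(pt, g, bandwidth = h)
  v1 <- grid_values(d1)
  expect_true(all(v1 >= 0))
  # peak at the pixel containing the point
  peak <- which(v1 == max(v1), arr.ind = TRUE)
  rc <- point_to_cell(g, pt$x, pt$y)
  expect_true(any(peak[, 1] == rc[1, "row"] & peak[, 2] == rc[1, "col"]))
  # total mass within 2% for bandwidth >= 3 pixels, away from edges
  expect_equal(sum(v1) * g$pixel_size^2, 1, tolerance = 0.02)
  # two coincident points double the surface exactly
  d2 <- kernel_density(rbind(pt, pt), g, bandwidth = h)
  expect_equal(grid_values(d2), 2 * v1, tolerance = 1e-12)
  # empty set warns and returns zeros
  expect_warning(d0 <- kernel_density(pt[0, ], g, bandwidth = h), "empty")
  expect_true(all(grid_values(d0) == 0))
})
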