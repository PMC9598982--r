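# threat layers, distance decay, degradation, quality, grading

test_that("decay_influence closed forms", {
  expect_equal(decay_influence(0, 1000, "linear"), 1)
  expect_equal(decay_influence(0, 1000, "exponential"), 1)
  expect_equal(decay_influence(1000, 1000, "linear"), 0)
  expect_equal(decay_influence(500, 1000, "linear"), 0.5)
  expect_equal(decay_influence(1000, 1000, "exponential"), exp(-2.99))
  expect_equal(decay_influence(1500, 1000, "exponential"), 0)  # hard cutoff
  expect_equal(decay_influence(2000, 1000, "linear"), 0)
  expect_error(decay_influence(-1, 1000, "linear"), "negative")
})

test_that("distance transform matches the exhaustive nearest-source oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    pres <- matrix(runif(20 * 20) < 0.05, 20, 20)
    expect_identical(distance_to_nearest(pres, 30),
                     brute_distance_to_nearest(pres, 30))
  }
  # no sources: all infinite
  expect_true(all(is.infinite(distance_to_nearest(matrix(FALSE, 5, 5), 10))))
})

test_that("build_threat_layers returns the 12 layers in table order", {
  sc <- random_small_scene(4)
  vs <- village_scores(sc$villages)
  th <- build_threat_layers(vs, sc$roads, sc$lulc)
  expect_s3_class(th, "hq_threats")
  expect_equal(names(th$presence), default_threats()$name)
  expect_length(th$presence, 12)
  # a grade with no villages still yields an (all-FALSE) layer
  missing_grades <- setdiff(c("I", "II", "III", "IV", "V", "VI", "VII"),
                            as.character(vs$grade))
  for (g in missing_grades)
    expect_false(any(th$presence[[paste0("village_", g)]]))
  # land-derived presences coincide with their codes
  v <- grid_values(sc$lulc)
  expect_equal(th$presence$cropland, !is.na(v) & v == 7)
  expect_equal(th$presence$other_nonforest, !is.na(v) & v == 1)
  expect_equal(th$presence$economic_forest, !is.na(v) & v == 8)
  expect_equal(th$presence$artificial_construction, !is.na(v) & v == 14)
  # bad grades rejected
  bad <- vs; bad$grade <- "VIII"
  expect_error(build_threat_layers(bad, sc$roads, sc$lulc), "I-VII")
})

test_that("degradation: hand-evaluated single-threat case and bounds", {
  # uniform fir-spruce forest (code 11), one cropland pixel as only threat
  m <- matrix(11L, 9, 9); m[5, 5] <- 7L
  lulc <- hq_grid(m, pixel_size = 100)
  th <- build_threat_layers(data.frame(x = numeric(), y = numeric(),
                                       grade = character()),
                            NULL, lulc)
  d <- degradation(lulc, th)
  dv <- grid_values(d)
  # on the source pixel: lulc is cropland (sensitivity 0) -> D = 0
  expect_equal(dv[5, 5], 0)
  # adjacent pixel: only cropland threat present, w/sum(w) = 0.5/8.15,
  # distance 100 m of d_max 1000 m exponential, S_11,cropland = 0.5
  expected <- (0.5 / sum(default_threats()$weight)) *
    exp(-2.99 * 100 / 1000) * 0.5
  expect_equal(dv[5, 4], expected, tolerance = 1e-12)
  expect_true(all(dv >= 0 & dv <= 1))
})

test_that("degradation with no threat presence anywhere is zero", {
  m <- matrix(11L, 6, 6)
  lulc <- hq_grid(m, pixel_size = 100)
  th <- build_threat_layers(data.frame(x = numeric(), y = numeric(),
                                       grade = character()), NULL, lulc)
  expect_true(all(grid_values(degradation(lulc, th)) == 0))
})

test_that("degradation matches the brute-force oracle on random scenes", {
  for (seed in 1:5) {
    sc <- random_small_scene(seed, nr = 12L, nc = 12L)
    vs <- village_scores(sc$villages)
    th <- build_threat_layers(vs, sc$roads, sc$lulc)
    d <- degradation(sc$lulc, th)
    expect_equal(grid_values(d), brute_degradation(sc$lulc, th,
                                                   default_sensitivity()),
                 tolerance = 1e-12)
  }
})

test_that("quality: suitability at D=0, half-saturation at D=k, zero at H=0", {
  m <- matrix(c(11L, 7L, 2L, 5L), 2, 2)  # H = 1, 0, 0.6, 0.2
  lulc <- hq_grid(m, pixel_size = 100)
  suit <- setNames(lulc_classes()$suitability, as.character(1:14))
  d0 <- hq_grid(matrix(0, 2, 2), 100)
  expect_equal(grid_values(quality(d0, lulc)),
               matrix(suit[as.character(as.vector(m))], 2, 2,
                      dimnames = NULL))
  dk <- hq_grid(matrix(0.5, 2, 2), 100)  # D = k
  expect_equal(grid_values(quality(dk, lulc)),
               matrix(suit[as.character(as.vector(m))] / 2, 2, 2))
  # H = 0 (cropland) means Q = 0 no matter the degradation
  d9 <- hq_grid(matrix(0.9, 2, 2), 100)
  expect_equal(grid_values(quality(d9, lulc))[2, 1], 0)
  expect_error(quality(d0, lulc, k = 0), "k must be positive")
})

test_that("grade_quality intervals, area table and partition", {
  q <- hq_grid(matrix(c(0, 0.19, 0.2, 0.4679, 0.6, 0.8, 1, 0.55, NA), 3, 3),
               pixel_size = 1000)
  gr <- grade_quality(q)
  gv <- grid_values(gr$grade)
  expect_equal(gv[1, 2], 3)   # 0.4679 is medium
  expect_equal(gv[1, 3], 5)   # 1.0 excellent, upper bound closed
  expect_equal(gv[1, 1], 1); expect_equal(gv[2, 1], 1)  # [0, 0.2)
  expect_equal(gv[3, 1], 2)
  expect_true(is.na(gv[3, 3]))
  expect_equal(sum(gr$area$percent), 100, tolerance = 0.01)
  expect_equal(sum(gr$area$area_km2), 8)  # 8 valid pixels of 1 km2
  expect_equal(gr$mean_quality, mean(grid_values(q), na.rm = TRUE))
  bad <- hq_grid(matrix(c(0.5, 1.2), 1, 2), 1000)
  expect_error(grade_quality(bad), "outside")
})

test_that("monotonicity: adding a threat pixel never increases quality", {
  for (seed in 1:8) {
    sc <- random_small_scene(seed, nr = 12L, nc = 12L)
    vs <- village_scores(sc$villages)
    th <- build_threat_layers(vs, sc$roads, sc$lulc)
    q1 <- grid_values(quality(degradation(sc$lulc, th), sc$lulc))
    # add one random cropland presence pixel
    set.seed(seed + 100)
    th2 <- th
    free <- which(!th2$presence$cropland)
    th2$presence$cropland[sample(free, 1)] <- TRUE
    q2 <- grid_values(quality(degradation(sc$lulc, th2), sc$lulc))
    expect_true(all(q2 <= q1 + 1e-12))
  }
})

test_that("locality: quality unchanged beyond d_max of a changed threat pixel", {
  sc <- random_small_scene(3, nr = 20L, nc = 20L)
  vs <- village_scores(sc$villages)
  th <- build_threat_layers(vs, sc$roads, sc$lulc)
  q1 <- grid_values(quality(degradation(sc$lulc, th), sc$lulc))
  th2 <- th
  th2$presence$cropland[1, 1] <- TRUE
  q2 <- grid_values(quality(degradation(sc$lulc, th2), sc$lulc))
  ctr <- pixel_centers(sc$lulc)
  dist_from_change <- sqrt(outer((ctr$y - ctr$y[1])^2,
                                 (ctr$x - ctr$x[1])^2, `+`))
  far <- dist_from_change > 1000  # cropland d_max = 1 km
  expect_equal(q2[far], q1[far])
})

test_that("upgrading one village I->VII weakly decreases quality within 2 km", {
  # The upgraded village must be the only one in its two grade layers:
  # influence is distance-to-nearest-source per layer, so another grade-I
  # (or VII) village shadowing the same pixels could otherwise offset the
  # change. Grades of the remaining villages are drawn from II-VI.
  for (seed in 1:5) {
    sc <- random_small_scene(seed, nr = 15L, nc = 15L)
    vs <- sc$villages
    set.seed(seed + 50)
    vs$grade <- factor(sample(c("II", "III", "IV", "V", "VI"), nrow(vs),
                              replace = TRUE),
                       levels = monkeyhab:::roman_grades)
    vs$grade[1] <- "I"
    th1 <- build_threat_layers(vs, sc$roads, sc$lulc)
    vs2 <- vs; vs2$grade[1] <- "VII"
    th2 <- build_threat_layers(vs2, sc$roads, sc$lulc)
    q1 <- grid_values(quality(degradation(sc$lulc, th1), sc$lulc))
    q2 <- grid_values(quality(degradation(sc$lulc, th2), sc$lulc))
    expect_true(all(q2 <= q1 + 1e-12))
    # and strictly decreases somewhere near the village on sensitive land
    expect_true(any(q2 < q1))
  }
})
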