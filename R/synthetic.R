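# Synthetic landscape generator: a patchy multi-class land-cover raster,
# villages whose 30 socio-economic indicators are driven by a single latent
# development factor, roads linking nearest-neighbor villages, a regular
# survey-plot grid, and monkey-group range polygons seeded in good habitat.
# Everything is deterministic given the config seed, so the full pipeline is
# testable without any field data.

#' Schema of the 30 village socio-economic indicators
#'
#' One row per indicator: code, measurement kind (`continuous`, `count`,
#' `percent`), a baseline level and scale used by the generator, and the sign
#' of its loading on the latent development factor. The two
#' distance-to-services indicators (X41, X42) and the out-of-school count
#' (X28) load negatively: development shortens distances to stations and
#' markets and reduces the number of children not attending school.
#'
#' @return data.frame with columns `code`, `kind`, `base`, `scale`, `sign`.
#' @export
indicator_schema <- function() {
  data.frame(
    code = c("X11", "X12", "X13", "X14", "X15", "X16",
             "X21", "X22", "X23", "X24", "X25", "X26", "X27", "X28",
             "X31", "X32", "X33", "X34", "X35", "X36",
             "X41", "X42", "X43", "X44", "X45", "X46",
             "X51", "X52", "X61", "X62"),
    kind = c(rep("continuous", 6),
             rep("count", 8),
             rep("continuous", 6),
             "continuous", "continuous", rep("count", 4),
             "count", "count", "percent", "percent"),
    base = c(2, 0.6, 1.2, 0.15, 0.8, 0.05,
             800, 700, 450, 380, 25, 2, 80, 8,
             6, 2.5, 1.2, 0.8, 1.5, 5000,
             12, 8, 15, 10, 12, 120,
             40, 25, 92, 85),
    scale = c(0.8, 0.25, 0.5, 0.06, 0.3, 0.02,
              300, 260, 170, 150, 12, 1, 35, 4,
              2.5, 1, 0.5, 0.35, 0.7, 1800,
              5, 3.5, 8, 5, 6, 50,
              18, 12, 6, 8),
    sign = c(rep(1, 13), -1,
             rep(1, 6),
             -1, -1, rep(1, 4),
             rep(1, 4)),
    stringsAsFactors = FALSE
  )
}

#' Default land-cover class proportions for synthetic scenes
#'
#' A mixed mountain landscape: roughly half forest and shrubland, about a
#' fifth cropland/villages/construction, the rest barren land, water and
#' low-suitability conifer forest.
#'
#' @return named numeric vector over codes 1-14 summing to 1.
#' @export
default_class_proportions <- function() {
  c(`1` = 0.05, `2` = 0.10, `3` = 0.10, `4` = 0.10, `5` = 0.04,
    `6` = 0.10, `7` = 0.12, `8` = 0.05, `9` = 0.02, `10` = 0.08,
    `11` = 0.08, `12` = 0.06, `13` = 0.08, `14` = 0.02)
}

#' Synthetic scene configuration
#'
#' @param grid_shape integer `(rows, cols)` of the land-cover raster.
#' @param pixel_size pixel edge in meters.
#' @param class_proportions named vector mapping land-cover codes (1-14) to
#'   target area fractions; must sum to 1.
#' @param n_villages number of villages (>= 2; PCA needs at least two rows).
#' @param latent_sd standard deviation of the latent development factor.
#' @param noise_sd standard deviation of per-indicator noise (same latent
#'   scale; the generator multiplies by each indicator's own scale).
#' @param n_groups number of monkey-group range polygons (>= 0).
#' @param plot_size survey plot edge in meters (default 2000 m: square plots
#'   of 4 km2).
#' @param smooth_sigma Gaussian smoothing radius (pixels) of the land-cover
#'   random field; larger values give larger patches.
#' @param seed integer RNG seed.
#' @return validated config list of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(120L, 120L), pixel_size = 100,
                         class_proportions = default_class_proportions(),
                         n_villages = 60L, latent_sd = 1, noise_sd = 0.3,
                         n_groups = 3L, plot_size = 2000, smooth_sigma = 3,
                         seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
              class_proportions = class_proportions,
              n_villages = as.integer(n_villages), latent_sd = latent_sd,
              noise_sd = noise_sd, n_groups = as.integer(n_groups),
              plot_size = plot_size, smooth_sigma = smooth_sigma,
              seed = as.integer(seed))
  codes <- suppressWarnings(as.integer(names(cfg$class_proportions)))
  if (any(is.na(codes)) || !all(codes %in% 1:14))
    stop("configuration error: class_proportions has unknown land-cover code(s)")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("configuration error: class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0))
    stop("configuration error: class_proportions must be non-negative")
  if (length(cfg$grid_shape) != 2L || any(cfg$grid_shape < 1L))
    stop("configuration error: grid_shape must be two positive integers")
  if (cfg$pixel_size <= 0) stop("configuration error: pixel_size must be > 0")
  if (cfg$n_villages < 2L)
    stop("configuration error: n_villages must be >= 2 (PCA undefined otherwise)")
  if (cfg$n_groups < 0L) stop("configuration error: n_groups must be >= 0")
  if (cfg$latent_sd <= 0) stop("configuration error: latent_sd must be > 0")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (cfg$plot_size <= 0) stop("configuration error: plot_size must be > 0")
  class(cfg) <- "scene_config"
  cfg
}

# separable Gaussian smoothing with renormalized edges
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(x) {
    pad <- matrix(0, r, ncol(x))
    f <- stats::filter(rbind(pad, x, pad), k, sides = 2)
    w <- stats::filter(rbind(pad, matrix(1, nrow(x), ncol(x)), pad), k,
                       sides = 2)
    (f / w)[(r + 1):(r + nrow(x)), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(m))))
}

#' Generate a synthetic land-cover raster
#'
#' Gaussian-smoothed white noise rank-thresholded into classes at the
#' requested cumulative proportions, which yields contiguous patches and
#' realized class fractions exact up to pixel rounding.
#'
#' @param config a [scene_config()].
#' @return an [hq_grid()] of integer land-cover codes.
#' @export
generate_lulc <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed + 1L, {
    nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
    field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                             config$smooth_sigma)
    props <- config$class_proportions[order(as.integer(names(config$class_proportions)))]
    codes <- as.integer(names(props))
    npix <- nr * nc
    counts <- diff(c(0L, round(cumsum(props) * npix)))
    v <- integer(npix)
    v[order(as.vector(field), seq_len(npix))] <- rep(codes, counts)
    hq_grid(matrix(v, nr, nc), pixel_size = config$pixel_size)
  })
}

#' Generate village indicator table
#'
#' Each village draws a latent development factor `f ~ N(0, latent_sd)`; each
#' indicator is `base + scale * (sign * f + eps)` with
#' `eps ~ N(0, noise_sd)`. Counts are rounded to non-negative integers,
#' percentages clipped to \[0, 100\], and continuous indicators floored at 0.
#' The latent factor is kept in column `latent` as ground truth for
#' parameter-recovery tests.
#'
#' @param config a [scene_config()].
#' @return data.frame: `village_id`, `latent`, then the 30 indicator columns.
#' @export
generate_villages <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (config$n_villages < 2L)
    stop("n_villages must be >= 2 (PCA undefined otherwise)")
  sch <- indicator_schema()
  with_seed(config$seed + 2L, {
    n <- config$n_villages
    f <- stats::rnorm(n, 0, config$latent_sd)
    x <- matrix(NA_real_, n, nrow(sch), dimnames = list(NULL, sch$code))
    for (j in seq_len(nrow(sch))) {
      eps <- stats::rnorm(n, 0, config$noise_sd)
      raw <- sch$base[j] + sch$scale[j] * (sch$sign[j] * f + eps)
      raw <- switch(sch$kind[j],
        count = pmax(0, round(raw)),
        percent = pmin(100, pmax(0, raw)),
        continuous = pmax(0, raw))
      x[, j] <- raw
    }
    cbind(data.frame(village_id = seq_len(n), latent = f), as.data.frame(x))
  })
}

# place villages preferring low-suitability pixels, jittered within the pixel
place_villages <- function(lulc, n, suitability) {
  v <- grid_values(lulc)
  h <- suitability[as.character(as.vector(v))]
  wgt <- (1 - h) + 0.01
  wgt[is.na(wgt)] <- 0
  idx <- sample.int(length(wgt), n, replace = TRUE, prob = wgt)
  d <- dim(v); px <- lulc$pixel_size
  row <- (idx - 1L) %% d[1] + 1L
  col <- (idx - 1L) %/% d[1] + 1L
  ctr <- pixel_centers(lulc)
  data.frame(
    x = ctr$x[col] + stats::runif(n, -0.5, 0.5) * px,
    y = ctr$y[row] + stats::runif(n, -0.5, 0.5) * px
  )
}

# one polyline per village to its nearest neighbor, deduplicated
connect_roads <- function(xy) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)
  pairs <- unique(t(apply(cbind(seq_len(n), nn), 1L, sort)))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(road_id = i,
               x = xy$x[pairs[i, ]], y = xy$y[pairs[i, ]])
  }))
}

# regular plot grid with raw ecological indices drawn over their legal ranges
sample_plots <- function(config, lulc) {
  ext <- grid_extent(lulc)
  nx <- floor((ext["xmax"] - ext["xmin"]) / config$plot_size)
  ny <- floor((ext["ymax"] - ext["ymin"]) / config$plot_size)
  if (nx < 1 || ny < 1)
    stop("grid too small to host survey plots of ", config$plot_size, " m")
  centers <- expand.grid(
    x = ext["xmin"] + (seq_len(nx) - 0.5) * config$plot_size,
    y = ext["ymin"] + (seq_len(ny) - 0.5) * config$plot_size
  )
  n <- nrow(centers)
  data.frame(
    plot_id = seq_len(n),
    x = centers$x, y = centers$y,
    forest_naturalness = sample(1:5, n, replace = TRUE),
    community_structure = sample(1:3, n, replace = TRUE),
    tree_species_structure = sample(1:7, n, replace = TRUE),
    vegetation_coverage = stats::runif(n, 0, 100),
    crown_density = stats::runif(n, 0.2, 1),
    tree_height = stats::runif(n, 0.9, 25),
    litter_depth = sample(1:3, n, replace = TRUE)
  )
}

# grow circular (24-gon) group ranges around high-suitability seed pixels,
# shrinking until no covered pixel center has zero suitability
sample_groups <- function(config, lulc, suitability) {
  if (config$n_groups == 0L)
    return(data.frame(group = character(), x = numeric(), y = numeric()))
  v <- grid_values(lulc)
  h <- matrix(suitability[as.character(as.vector(v))], nrow(v), ncol(v))
  cand <- which(h >= 0.8)
  if (length(cand) == 0)
    stop("no high-suitability pixels to seed group ranges")
  ctr <- pixel_centers(lulc)
  px <- lulc$pixel_size
  ext <- grid_extent(lulc)
  ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
  out <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    ok <- FALSE
    for (try in 1:200) {
      idx <- cand[sample.int(length(cand), 1L)]
      row <- (idx - 1L) %% nrow(v) + 1L
      col <- (idx - 1L) %/% nrow(v) + 1L
      cx <- ctr$x[col]; cy <- ctr$y[row]
      r <- 6 * px
      while (r >= 1.2 * px) {
        rows <- which(abs(ctr$y - cy) <= r)
        cols <- which(abs(ctr$x - cx) <= r)
        sub <- expand.grid(row = rows, col = cols)
        d2 <- (ctr$x[sub$col] - cx)^2 + (ctr$y[sub$row] - cy)^2
        sub <- sub[d2 <= r^2, , drop = FALSE]
        hh <- h[cbind(sub$row, sub$col)]
        in_ext <- cx - r >= ext["xmin"] && cx + r <= ext["xmax"] &&
          cy - r >= ext["ymin"] && cy + r <= ext["ymax"]
        if (nrow(sub) > 0 && all(!is.na(hh)) && all(hh > 0) && in_ext) break
        r <- r - 0.5 * px
      }
      if (r >= 1.2 * px) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place group range ", g,
                  " in suitability > 0 habitat")
    out[[g]] <- data.frame(group = sprintf("C%d", g),
                           x = cx + r * cos(ang), y = cy + r * sin(ang))
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic scene
#'
#' Assembles the land-cover raster, villages (placed with probability
#' proportional to 1 - suitability, mirroring the co-occurrence of dense
#' settlement and poor habitat), nearest-neighbor roads, the regular survey
#' plot grid, and monkey-group range polygons grown from high-suitability
#' pixels. Identical config (including seed) gives a bit-identical scene.
#'
#' @param config a [scene_config()].
#' @param suitability named suitability vector per land-cover code
#'   (default [lulc_classes()]).
#' @return object of class `hq_scene`: list with `config`, `lulc`,
#'   `villages` (with coordinates, indicators and hidden `latent`), `roads`,
#'   `plots`, `groups`.
#' @export
generate_scene <- function(config,
                           suitability = stats::setNames(
                             lulc_classes()$suitability,
                             as.character(lulc_classes()$code))) {
  stopifnot(inherits(config, "scene_config"))
  lulc <- generate_lulc(config)
  villages <- generate_villages(config)
  xy <- with_seed(config$seed + 3L,
                  place_villages(lulc, config$n_villages, suitability))
  villages <- cbind(villages[, "village_id", drop = FALSE], xy,
                    villages[, setdiff(names(villages), "village_id")])
  roads <- with_seed(config$seed + 4L, connect_roads(xy))
  plots <- with_seed(config$seed + 5L, sample_plots(config, lulc))
  groups <- with_seed(config$seed + 6L, sample_groups(config, lulc, suitability))
  structure(list(config = config, lulc = lulc, villages = villages,
                 roads = roads, plots = plots, groups = groups),
            class = "hq_scene")
}

#' @exportS3Method base::print
print.hq_scene <- function(x, ...) {
  cat(sprintf(
    "<hq_scene> %dx%d land-cover raster, %d villages, %d road segments, %d plots, %d groups\n",
    nrow(x$lulc$values), ncol(x$lulc$values), nrow(x$villages),
    length(unique(x$roads$road_id)), nrow(x$plots),
    length(unique(x$groups$group))))
  invisible(x)
}
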