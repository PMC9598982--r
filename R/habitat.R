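# Threat-based habitat degradation and quality. Twelve threat factors
# (villages by development grade I-VII, village roads, and four land-derived
# threats) radiate influence that decays with distance to the nearest source
# pixel up to a hard maximum effective distance. Degradation D aggregates
# weight-normalized influence times the land-cover class's sensitivity;
# quality Q down-weights habitat suitability H through a half-saturation
# response in D.

#' Distance-decayed threat influence
#'
#' Linear decay: `max(0, 1 - d/d_max)`. Exponential decay:
#' `exp(-(2.99/d_max) d)` for `d <= d_max`, hard-clamped to 0 beyond, so the
#' influence is about 0.05 at the maximum effective distance and exactly 0
#' past it.
#'
#' @param d distance(s) in meters, >= 0.
#' @param d_max maximum effective distance in meters, > 0.
#' @param decay `"exponential"` or `"linear"`.
#' @return influence in \[0, 1\].
#' @export
decay_influence <- function(d, d_max, decay = c("exponential", "linear")) {
  decay <- match.arg(decay)
  if (any(d < 0, na.rm = TRUE)) stop("negative distance")
  if (d_max <= 0) stop("d_max must be positive")
  if (decay == "linear") pmax(0, 1 - d / d_max)
  else ifelse(d <= d_max, exp(-(2.99 / d_max) * d), 0)
}

# rasterize points: TRUE in every pixel containing a point
rasterize_points <- function(grid, x, y) {
  m <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (length(x)) {
    rc <- point_to_cell(grid, x, y)
    rc <- rc[stats::complete.cases(rc), , drop = FALSE]
    m[rc] <- TRUE
  }
  m
}

# rasterize polylines by dense sampling along each segment
rasterize_lines <- function(grid, lines) {
  m <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (is.null(lines) || nrow(lines) == 0) return(m)
  step <- grid$pixel_size / 3
  for (id in unique(lines$road_id)) {
    seg <- lines[lines$road_id == id, , drop = FALSE]
    for (i in seq_len(nrow(seg) - 1L)) {
      len <- sqrt((seg$x[i + 1] - seg$x[i])^2 + (seg$y[i + 1] - seg$y[i])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      rc <- point_to_cell(grid, seg$x[i] + t * (seg$x[i + 1] - seg$x[i]),
                          seg$y[i] + t * (seg$y[i + 1] - seg$y[i]))
      rc <- rc[stats::complete.cases(rc), , drop = FALSE]
      m[rc] <- TRUE
    }
  }
  m
}

#' Build the twelve threat presence layers
#'
#' Villages are split by development grade into seven point-presence rasters
#' (a grade with no villages yields an all-zero layer, still returned); roads
#' are rasterized onto every pixel the line touches; land-cover codes 1
#' (other non-forest land), 8 (planted economic forests), 7 (cropland) and
#' 14 (artificial construction) become the four land-derived threat
#' presences. Layers are returned in the [default_threats()] order.
#'
#' @param villages data.frame with `x`, `y` and `grade` (factor or character
#'   `I`..`VII`).
#' @param roads polyline data.frame (`road_id`, `x`, `y`) or `NULL`.
#' @param lulc land-cover [hq_grid()].
#' @param defs threat attribute table (default [default_threats()]).
#' @return object of class `hq_threats`: list with `defs`, `presence` (named
#'   list of logical matrices) and the reference `grid`.
#' @export
build_threat_layers <- function(villages, roads, lulc,
                                defs = default_threats()) {
  stopifnot(inherits(lulc, "hq_grid"))
  gr <- as.character(villages$grade)
  if (length(gr) && !all(gr %in% roman_grades))
    stop("village grade outside I-VII: ",
         paste(unique(setdiff(gr, roman_grades)), collapse = ", "))
  v <- grid_values(lulc)
  lut <- c(other_nonforest = 1, economic_forest = 8, cropland = 7,
           artificial_construction = 14)
  presence <- lapply(seq_len(nrow(defs)), function(i) {
    nm <- defs$name[i]
    if (grepl("^village_road$", nm)) {
      rasterize_lines(lulc, roads)
    } else if (grepl("^village_", nm)) {
      g <- sub("^village_", "", nm)
      sel <- gr == g
      rasterize_points(lulc, villages$x[sel], villages$y[sel])
    } else if (nm %in% names(lut)) {
      !is.na(v) & v == lut[[nm]]
    } else {
      stop("threat '", nm, "' has no presence rule")
    }
  })
  names(presence) <- defs$name
  structure(list(defs = defs, presence = presence, grid = lulc),
            class = "hq_threats")
}

#' Distance to the nearest presence pixel
#'
#' Exact Euclidean distance transform between pixel centers (meters); `Inf`
#' everywhere when the layer has no presence pixel.
#'
#' @param presence logical matrix.
#' @param pixel_size pixel edge in meters.
#' @return numeric matrix of distances in meters.
#' @export
distance_to_nearest <- function(presence, pixel_size) {
  sqrt(edt_squared(presence)) * pixel_size
}

#' Habitat degradation raster
#'
#' Per pixel with land-cover class j:
#' `D = sum_r (w_r / sum w) * i_r * S_jr`, where `i_r` is the decayed
#' influence of the distance to threat r's nearest source pixel and `S_jr`
#' the class's sensitivity to r. Weights are normalized over the supplied
#' threat list, so D is provably in \[0, 1\].
#'
#' @param lulc land-cover [hq_grid()].
#' @param threats an `hq_threats` from [build_threat_layers()].
#' @param sens sensitivity matrix (rows = land-cover codes, columns = threat
#'   names; default [default_sensitivity()]).
#' @return [hq_grid()] of degradation D (NA at nodata pixels).
#' @export
degradation <- function(lulc, threats, sens = default_sensitivity()) {
  stopifnot(inherits(lulc, "hq_grid"), inherits(threats, "hq_threats"))
  if (!same_geometry(lulc, threats$grid))
    stop("grid geometry mismatch between land cover and threat layers")
  v <- grid_values(lulc)
  codes <- unique(v[!is.na(v)])
  if (!all(as.character(codes) %in% rownames(sens)))
    stop("unknown land-cover code(s): ",
         paste(setdiff(codes, rownames(sens)), collapse = ", "))
  defs <- threats$defs
  wsum <- sum(defs$weight)
  d <- matrix(0, nrow(v), ncol(v))
  cls <- as.character(as.vector(v))
  for (i in seq_len(nrow(defs))) {
    pres <- threats$presence[[defs$name[i]]]
    if (!any(pres)) next
    dist <- distance_to_nearest(pres, lulc$pixel_size)
    infl <- decay_influence(dist, defs$d_max_km[i] * 1000, defs$decay[i])
    s <- rep(0, length(cls))
    ok <- !is.na(cls)
    s[ok] <- sens[cls[ok], defs$name[i]]
    d <- d + (defs$weight[i] / wsum) * infl * matrix(s, nrow(v), ncol(v))
  }
  d[is.na(v)] <- NA
  hq_grid(d, lulc$pixel_size, lulc$xmin, lulc$ymin)
}

#' Habitat quality raster
#'
#' Half-saturation response of suitability to degradation:
#' `Q = H_j * (1 - D^z / (D^z + k^z))`, so Q equals the class suitability H
#' at D = 0, falls to H/2 at D = k, and is 0 wherever H = 0.
#'
#' @param d degradation [hq_grid()] from [degradation()].
#' @param lulc land-cover [hq_grid()].
#' @param suitability named suitability vector per land-cover code.
#' @param k half-saturation constant (> 0, default 0.5).
#' @param z response exponent (default 2.5).
#' @return [hq_grid()] of quality Q in \[0, 1\].
#' @export
quality <- function(d, lulc,
                    suitability = stats::setNames(lulc_classes()$suitability,
                                                  as.character(lulc_classes()$code)),
                    k = 0.5, z = 2.5) {
  stopifnot(inherits(d, "hq_grid"), inherits(lulc, "hq_grid"))
  if (k <= 0) stop("k must be positive")
  if (!same_geometry(d, lulc)) stop("grid geometry mismatch")
  v <- grid_values(lulc)
  dd <- grid_values(d)
  h <- matrix(suitability[as.character(as.vector(v))], nrow(v), ncol(v))
  q <- h * (1 - dd^z / (dd^z + k^z))
  q[is.na(v)] <- NA
  hq_grid(q, lulc$pixel_size, lulc$xmin, lulc$ymin)
}

quality_grade_labels <- c("very poor", "poor", "medium", "good", "excellent")

#' Grade a habitat quality raster and summarize areas
#'
#' Five grades by quality interval: very poor \[0, 0.2), poor \[0.2, 0.4),
#' medium \[0.4, 0.6), good \[0.6, 0.8), excellent \[0.8, 1\]. The area
#' table reports km2 (pixel count x pixel area) and percentage per grade
#' over non-nodata pixels, plus the overall mean quality.
#'
#' @param q quality [hq_grid()].
#' @param breaks interior break points (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @return list: `grade` ([hq_grid()] of codes 1-5), `area`
#'   (data.frame `grade`, `label`, `area_km2`, `percent`), `mean_quality`.
#' @export
grade_quality <- function(q, breaks = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(inherits(q, "hq_grid"))
  qq <- grid_values(q)
  vals <- qq[!is.na(qq)]
  if (length(vals) == 0) stop("quality raster is all nodata")
  if (any(vals < 0 | vals > 1)) stop("quality values outside [0, 1]")
  g <- findInterval(qq, breaks) + 1L
  g[is.na(qq)] <- NA_integer_
  counts <- tabulate(g[!is.na(g)], nbins = 5L)
  px_km2 <- (q$pixel_size / 1000)^2
  area <- data.frame(
    grade = 1:5, label = quality_grade_labels,
    area_km2 = counts * px_km2,
    percent = 100 * counts / sum(counts)
  )
  list(grade = hq_grid(matrix(g, nrow(qq), ncol(qq)),
                       q$pixel_size, q$xmin, q$ymin),
       area = area, mean_quality = mean(vals))
}

#' Full habitat-quality model on one scene
#'
#' Builds the threat layers, computes degradation and quality, and grades
#' the result.
#'
#' @param lulc land-cover [hq_grid()].
#' @param villages data.frame with `x`, `y`, `grade`.
#' @param roads polyline data.frame or `NULL`.
#' @param params parameter list (default [default_params()]).
#' @return list: `threats`, `degradation`, `quality`, plus the elements of
#'   [grade_quality()].
#' @export
habitat_quality <- function(lulc, villages, roads = NULL,
                            params = default_params()) {
  th <- build_threat_layers(villages, roads, lulc, params$threats)
  d <- degradation(lulc, th, params$sensitivity)
  q <- quality(d, lulc, params$suitability, k = params$k, z = params$z)
  gr <- grade_quality(q, params$quality_grade_breaks)
  c(list(threats = th, degradation = d, quality = q), gr)
}
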