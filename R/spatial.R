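# Spatial interpretation of the quality surface: block aggregation, global
# Moran's I with permutation and analytic (randomization) inference,
# Getis-Ord Gi* hot-spot z-scores with a five-class labelling, and zonal
# means over monkey-group range polygons.

#' Aggregate a raster to square analysis units
#'
#' Mean value per `unit_size` x `unit_size` block of pixels (nodata pixels
#' ignored; blocks that are entirely nodata are dropped), plus queen
#' adjacency between the retained blocks. Statistics are computed on these
#' units rather than on millions of raw pixels.
#'
#' @param q an [hq_grid()].
#' @param unit_size block edge in pixels (>= 1; 1 = identity aggregation).
#' @return object of class `hq_units`: `values`, block `row`/`col`, center
#'   `x`/`y`, sparse binary `adjacency` (zero diagonal), `unit_size`, and
#'   `block_of` (matrix mapping each pixel to its unit index, NA if dropped).
#' @export
aggregate_to_units <- function(q, unit_size = 5L) {
  stopifnot(inherits(q, "hq_grid"))
  unit_size <- as.integer(unit_size)
  if (unit_size < 1L) stop("unit_size must be >= 1")
  v <- grid_values(q)
  nbr <- ceiling(nrow(v) / unit_size)
  nbc <- ceiling(ncol(v) / unit_size)
  brow <- (seq_len(nrow(v)) - 1L) %/% unit_size + 1L
  bcol <- (seq_len(ncol(v)) - 1L) %/% unit_size + 1L
  bid <- matrix(brow, nrow(v), ncol(v)) +
    (matrix(bcol, nrow(v), ncol(v), byrow = TRUE) - 1L) * nbr
  sums <- tapply(as.vector(v), as.vector(bid), function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  means <- as.numeric(sums)
  ids <- as.integer(names(sums))
  ord <- order(ids)
  ids <- ids[ord]; means <- means[ord]
  keep <- !is.na(means)
  ids <- ids[keep]; means <- means[keep]
  r <- (ids - 1L) %% nbr + 1L
  cc <- (ids - 1L) %/% nbr + 1L
  # queen adjacency among retained blocks
  key <- function(rr, ccv) (ccv - 1L) * nbr + rr
  pos <- integer(nbr * nbc); pos[key(r, cc)] <- seq_along(ids)
  from <- integer(0); to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc2 <- cc + dc
    ok <- rr >= 1 & rr <= nbr & cc2 >= 1 & cc2 <= nbc
    j <- integer(length(ids)); j[ok] <- pos[key(rr[ok], cc2[ok])]
    sel <- ok & j > 0
    from <- c(from, which(sel)); to <- c(to, j[sel])
  }
  adj <- Matrix::sparseMatrix(i = from, j = to, x = 1,
                              dims = c(length(ids), length(ids)))
  ux <- q$xmin + (cc - 0.5) * unit_size * q$pixel_size
  uy <- q$ymin + nrow(v) * q$pixel_size - (r - 0.5) * unit_size * q$pixel_size
  block_of <- matrix(pos[as.vector(bid)], nrow(v), ncol(v))
  block_of[block_of == 0L] <- NA_integer_
  structure(list(values = means, row = r, col = cc, x = ux, y = uy,
                 adjacency = adj, unit_size = unit_size, block_of = block_of,
                 grid = list(pixel_size = q$pixel_size, xmin = q$xmin,
                             ymin = q$ymin, nbr = nbr, nbc = nbc)),
            class = "hq_units")
}

#' Spatial weights from an adjacency structure
#'
#' @param adjacency square sparse (or dense) binary neighbor matrix.
#' @param style `"binary"` or `"row"` (row-standardized).
#' @param include_self add each unit as its own neighbor (required for Gi*).
#' @return object of class `hq_weights`: `W` (dgCMatrix), `style`,
#'   `include_self`.
#' @export
spatial_weights <- function(adjacency, style = c("row", "binary"),
                            include_self = FALSE) {
  style <- match.arg(style)
  W <- Matrix::Matrix(adjacency, sparse = TRUE)
  W <- methods::as(methods::as(methods::as(W, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop("adjacency must be square")
  if (include_self) Matrix::diag(W) <- 1
  else Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  if (style == "row") {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- methods::as(Matrix::Diagonal(x = 1 / rs) %*% W, "CsparseMatrix")
  }
  structure(list(W = W, style = style, include_self = include_self),
            class = "hq_weights")
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with deviations from
#' the mean. Expectation under spatial randomness is `-1/(n-1)`. Inference
#' is reported two ways: a permutation test (two-sided, `permutations`
#' random relabelings) and the analytic normal approximation under the
#' randomization assumption.
#'
#' @param values numeric vector, one per unit.
#' @param w an [spatial_weights()] with zero diagonal.
#' @param permutations number of permutations (default 999).
#' @param seed optional seed for the permutation null.
#' @return list: `I`, `expectation`, `variance`, `z` (analytic), `p_norm`,
#'   `p_perm`, `permutations`.
#' @export
morans_i <- function(values, w, permutations = 999L, seed = NULL) {
  stopifnot(inherits(w, "hq_weights"))
  if (w$include_self) stop("Moran's I requires weights with zero diagonal")
  n <- length(values)
  if (n < 4) stop("need at least 4 units")
  if (stats::sd(values) == 0) stop("zero variance in values")
  W <- w$W
  if (nrow(W) != n) stop("weights dimension does not match values")
  zc <- values - mean(values)
  S0 <- sum(W)
  denom <- sum(zc^2)
  I <- (n / S0) * as.numeric(zc %*% (W %*% zc)) / denom
  EI <- -1 / (n - 1)
  # randomization variance (standard S1/S2/kurtosis form)
  Wd <- W + Matrix::t(W)
  S1 <- 0.5 * sum(Wd^2)
  S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
  b2 <- n * sum(zc^4) / denom^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  p_norm <- 2 * stats::pnorm(-abs(zstat))
  perm_stat <- function() {
    zp <- zc[sample.int(n)]
    (n / S0) * as.numeric(zp %*% (W %*% zp)) / denom
  }
  sims <- if (is.null(seed)) replicate(permutations, perm_stat())
          else with_seed(seed, replicate(permutations, perm_stat()))
  p_perm <- (1 + sum(abs(sims - EI) >= abs(I - EI))) / (permutations + 1)
  list(I = I, expectation = EI, variance = VI, z = zstat,
       p_norm = p_norm, p_perm = p_perm, permutations = permutations)
}

#' Getis-Ord Gi* z-scores
#'
#' The standard Gi* statistic in z-score form, computed with weights that
#' include each unit as its own neighbor:
#' `Gi* = (sum_j w_ij x_j - Xbar sum_j w_ij) /
#'        (S sqrt((n sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1)))`
#' with Xbar and S the global mean and (population) standard deviation.
#'
#' @param values numeric vector.
#' @param w an [spatial_weights()] built with `include_self = TRUE`.
#' @return numeric vector of z-scores.
#' @export
gi_star <- function(values, w) {
  stopifnot(inherits(w, "hq_weights"))
  if (!w$include_self) stop("Gi* requires weights that include self-neighbors")
  n <- length(values)
  if (n < 4) stop("need at least 4 units")
  if (stats::sd(values) == 0) stop("zero variance in values")
  W <- w$W
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  sw <- Matrix::rowSums(W)
  sw2 <- Matrix::rowSums(W^2)
  num <- as.numeric(W %*% values) - xbar * sw
  den <- S * sqrt(pmax(0, (n * sw2 - sw^2) / (n - 1)))
  z <- ifelse(den < .Machine$double.eps, 0, num / den)
  as.numeric(z)
}

#' Classify Gi* z-scores into hot-spot classes
#'
#' Five classes: hot (z >= 2.58), sub-hot (1.96 <= z < 2.58), not
#' significant, sub-cold (-2.58 < z <= -1.96), cold (z <= -2.58) — the 99%
#' and 95% confidence tiers on each side.
#'
#' @param z numeric Gi* z-scores.
#' @return factor with levels `cold`, `sub-cold`, `not significant`,
#'   `sub-hot`, `hot`.
#' @export
classify_hotspots <- function(z) {
  if (any(!is.finite(z))) stop("non-finite Gi* z-score")
  lab <- ifelse(z >= 2.58, "hot",
         ifelse(z >= 1.96, "sub-hot",
         ifelse(z <= -2.58, "cold",
         ifelse(z <= -1.96, "sub-cold", "not significant"))))
  factor(lab, levels = c("cold", "sub-cold", "not significant",
                         "sub-hot", "hot"))
}

#' Zonal mean of a raster over polygons
#'
#' Mean value over pixels whose centers fall inside each polygon. Polygons
#' covering no (non-nodata) pixel are reported as `NA` with a warning.
#'
#' @param q an [hq_grid()].
#' @param polygons data.frame with `group`, `x`, `y` vertex columns (one
#'   closed ring per group).
#' @return list: `groups` (data.frame `group`, `mean_quality`, `n_pixels`)
#'   and `overall_mean` (arithmetic mean across groups with data).
#' @export
zonal_mean <- function(q, polygons) {
  stopifnot(inherits(q, "hq_grid"))
  v <- grid_values(q)
  ctr <- pixel_centers(q)
  gs <- unique(polygons$group)
  res <- data.frame(group = gs, mean_quality = NA_real_,
                    n_pixels = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(gs)) {
    ring <- polygons[polygons$group == gs[i], , drop = FALSE]
    rows <- which(ctr$y >= min(ring$y) & ctr$y <= max(ring$y))
    cols <- which(ctr$x >= min(ring$x) & ctr$x <= max(ring$x))
    if (!length(rows) || !length(cols)) next
    sub <- expand.grid(row = rows, col = cols)
    inside <- points_in_polygon(ctr$x[sub$col], ctr$y[sub$row],
                                ring$x, ring$y)
    vals <- v[cbind(sub$row, sub$col)][inside]
    vals <- vals[!is.na(vals)]
    res$n_pixels[i] <- length(vals)
    if (length(vals)) res$mean_quality[i] <- mean(vals)
  }
  if (anyNA(res$mean_quality))
    warning("polygon(s) covering no data reported as missing: ",
            paste(res$group[is.na(res$mean_quality)], collapse = ", "))
  list(groups = res,
       overall_mean = mean(res$mean_quality, na.rm = TRUE))
}

#' Summary of per-group habitat quality
#'
#' Reporting path for a per-group quality table: arithmetic mean across
#' groups, and the best/worst groups.
#'
#' @param groups data.frame with `group` and `mean_quality`.
#' @return list: `n_groups`, `mean`, `max`, `max_group`, `min`, `min_group`.
#' @export
zonal_summary <- function(groups) {
  stopifnot(all(c("group", "mean_quality") %in% names(groups)))
  g <- groups[!is.na(groups$mean_quality), , drop = FALSE]
  if (nrow(g) == 0) stop("no groups with data")
  list(n_groups = nrow(g),
       mean = mean(g$mean_quality),
       max = max(g$mean_quality),
       max_group = g$group[which.max(g$mean_quality)],
       min = min(g$mean_quality),
       min_group = g$group[which.min(g$mean_quality)])
}
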