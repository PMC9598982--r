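# Village development scoring: PCA on the correlation matrix of the 30
# socio-economic indicators, Kaiser retention (eigenvalue > 1), a
# variance-explained weighted composite score Z, seven ordinal development
# grades, and a quartic kernel-density surface of village development.

#' Standardize an indicator matrix
#'
#' Median-imputes missing values, drops zero-variance columns with a warning,
#' and centers/scales each remaining column to mean 0 and unit sample
#' variance (n - 1 denominator).
#'
#' @param m numeric matrix or data.frame of indicator columns.
#' @return standardized matrix; dropped column names in attribute `dropped`.
#' @export
standardize_indicators <- function(m) {
  x <- as.matrix(m)
  if (!is.numeric(x)) stop("indicator matrix must be numeric")
  if (nrow(x) < 2) stop("need at least 2 villages")
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) {
      med <- stats::median(x[, j], na.rm = TRUE)
      if (is.na(med)) stop("column ", colnames(x)[j], " is entirely missing")
      x[is.na(x[, j]), j] <- med
    }
  }
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0
  if (all(const)) stop("all indicator columns are constant")
  if (any(const)) {
    warning("dropping constant indicator column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  out <- scale(x)
  attr(out, "dropped") <- colnames(m)[const]
  out
}

#' Principal component analysis on the correlation matrix
#'
#' Eigen-decomposition of the indicator correlation matrix. Components with
#' eigenvalue > 1 are retained (Kaiser criterion). Each retained loading
#' vector is sign-oriented so its largest-magnitude entry is positive, making
#' results deterministic across runs and platforms. Component weights are the
#' variance-explained proportions among retained components.
#'
#' @param x standardized matrix from [standardize_indicators()].
#' @return object of class `hq_pca`: `eigenvalues` (all, descending),
#'   `loadings` (p x k, unit-norm columns), `scores` (n x k), `k`, `weights`
#'   (length k, summing to 1).
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows for PCA")
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  ev <- e$values
  k <- sum(ev > 1)
  if (k < 1)
    stop("no eigenvalue exceeds 1; fall back by retaining the first component")
  load <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  scores <- x %*% load
  structure(list(eigenvalues = ev, loadings = load, scores = scores,
                 k = k, weights = ev[seq_len(k)] / sum(ev[seq_len(k)])),
            class = "hq_pca")
}

#' @exportS3Method base::print
print.hq_pca <- function(x, ...) {
  cat(sprintf("<hq_pca> %d components retained (eigenvalue > 1) of %d\n",
              x$k, length(x$eigenvalues)))
  cat(sprintf("  variance explained by retained set: %.1f%%\n",
              100 * sum(x$eigenvalues[seq_len(x$k)]) / length(x$eigenvalues)))
  invisible(x)
}

#' Comprehensive village development score
#'
#' Weighted sum of the retained component scores, weights being the
#' variance-explained proportions: `Z = sum_i w_i * score_i`. Z has mean 0
#' over villages by construction.
#'
#' @param p an `hq_pca` from [fit_pca()].
#' @return numeric vector Z, one per village.
#' @export
comprehensive_score <- function(p) {
  stopifnot(inherits(p, "hq_pca"))
  as.numeric(p$scores %*% p$weights)
}

#' Assign village development grades I-VII
#'
#' Grades by composite-score intervals, half-open upward: I below -0.5, then
#' steps of 0.5 up to VII at Z >= 2. A boundary score belongs to the higher
#' grade.
#'
#' @param z numeric composite scores.
#' @param breaks the six interior break points (default
#'   `c(-0.5, 0, 0.5, 1, 1.5, 2)`).
#' @return factor with levels `I`..`VII`.
#' @export
grade_villages <- function(z, breaks = c(-0.5, 0, 0.5, 1, 1.5, 2)) {
  if (any(!is.finite(z))) stop("non-finite composite score")
  g <- findInterval(z, breaks) + 1L
  factor(roman_grades[g], levels = roman_grades)
}

#' Score and grade villages end to end
#'
#' Convenience wrapper: standardize the 30 indicators, fit the PCA, compute
#' the composite score Z and assign grades.
#'
#' @param indicators data.frame with the indicator columns (any non-indicator
#'   columns such as ids/coordinates are carried through untouched).
#' @param indicator_cols names of the indicator columns (default: the
#'   [indicator_schema()] codes present in `indicators`).
#' @param breaks grade break points, see [grade_villages()].
#' @return `indicators` with columns `score` (Z) and `grade` appended, and
#'   the `hq_pca` fit in attribute `pca`.
#' @export
village_scores <- function(indicators,
                           indicator_cols = intersect(indicator_schema()$code,
                                                      names(indicators)),
                           breaks = c(-0.5, 0, 0.5, 1, 1.5, 2)) {
  if (length(indicator_cols) < 2)
    stop("need at least 2 indicator columns")
  x <- standardize_indicators(indicators[, indicator_cols, drop = FALSE])
  p <- fit_pca(x)
  z <- comprehensive_score(p)
  out <- indicators
  out$score <- z
  out$grade <- grade_villages(z, breaks)
  attr(out, "pca") <- p
  out
}

#' Quartic kernel density surface
#'
#' Weighted point density on a raster grid with the quartic (biweight)
#' kernel `K(d) = 3/(pi h^2) (1 - d^2/h^2)^2` for `d < h`. The kernel
#' integrates to 1, so the surface integrates to the total weight (up to
#' discretization and edge loss).
#'
#' @param points data.frame with columns `x`, `y`.
#' @param grid an [hq_grid()] supplying the output geometry.
#' @param weights optional per-point weights (default 1).
#' @param bandwidth kernel radius h in meters (default: largest grid extent
#'   / 30, a common GIS default).
#' @return [hq_grid()] of density per square meter.
#' @export
kernel_density <- function(points, grid, weights = NULL, bandwidth = NULL) {
  stopifnot(inherits(grid, "hq_grid"))
  d <- dim(grid$values)
  out <- matrix(0, d[1], d[2])
  if (is.null(bandwidth)) {
    ext <- grid_extent(grid)
    bandwidth <- max(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"]) / 30
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is.null(points) || nrow(points) == 0) {
    warning("empty point set: returning zero density surface")
    return(hq_grid(out, grid$pixel_size, grid$xmin, grid$ymin))
  }
  if (is.null(weights)) weights <- rep(1, nrow(points))
  stopifnot(length(weights) == nrow(points))
  ctr <- pixel_centers(grid)
  h2 <- bandwidth^2
  norm <- 3 / (pi * h2)
  for (i in seq_len(nrow(points))) {
    rows <- which(abs(ctr$y - points$y[i]) < bandwidth)
    cols <- which(abs(ctr$x - points$x[i]) < bandwidth)
    if (!length(rows) || !length(cols)) next
    d2 <- outer((ctr$y[rows] - points$y[i])^2, (ctr$x[cols] - points$x[i])^2, `+`)
    kern <- norm * (1 - d2 / h2)^2 * (d2 < h2)
    out[rows, cols] <- out[rows, cols] + weights[i] * kern
  }
  hq_grid(out, grid$pixel_size, grid$xmin, grid$ymin)
}
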