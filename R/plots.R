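# Forest survey-plot ecological quality: each of seven indices is typed
# I/II/III (scored 1/2/3, lower is better), the composite Y is the weighted
# sum of type scores, and Y maps to four ecological grades. Also the
# empirical procedure that estimates a threat's maximum effective distance
# from the distance-correlation of plot quality.

plot_index_names <- names(default_plot_weights())

# classification criteria per index: categorical sets or half-open numeric
# intervals, left-closed as printed
classify_one <- function(index_name, v) {
  switch(index_name,
    forest_naturalness = ifelse(v %in% c(1, 2), 1L,
                         ifelse(v %in% c(3, 4), 2L,
                         ifelse(v == 5, 3L, NA_integer_))),
    community_structure = ifelse(v == 1, 1L, ifelse(v == 2, 2L,
                          ifelse(v == 3, 3L, NA_integer_))),
    tree_species_structure = ifelse(v %in% c(6, 7), 1L,
                             ifelse(v %in% c(3, 4, 5), 2L,
                             ifelse(v %in% c(1, 2), 3L, NA_integer_))),
    vegetation_coverage = ifelse(v >= 70 & v <= 100, 1L,
                          ifelse(v >= 50 & v < 70, 2L,
                          ifelse(v >= 0 & v < 50, 3L, NA_integer_))),
    crown_density = ifelse(v >= 0.7 & v <= 1, 1L,
                    ifelse(v >= 0.4 & v < 0.7, 2L,
                    ifelse(v >= 0.2 & v < 0.4, 3L, NA_integer_))),
    tree_height = ifelse(v >= 15, 1L,
                  ifelse(v >= 5, 2L,
                  ifelse(v >= 0.9 & v < 5, 3L, NA_integer_))),
    litter_depth = ifelse(v == 1, 1L, ifelse(v == 2, 2L,
                   ifelse(v == 3, 3L, NA_integer_))),
    stop("unknown evaluation index '", index_name, "'")
  )
}

#' Type score of a plot evaluation index
#'
#' Maps a raw index value to its type score 1, 2 or 3 (types I, II, III;
#' lower is ecologically better). Numeric intervals are closed on the left:
#' e.g. total vegetation coverage in \[70, 100\] is type I, \[50, 70) type
#' II. Values outside every listed interval (e.g. crown density below 0.2)
#' are classified type III with a warning.
#'
#' @param index_name one of `forest_naturalness`, `community_structure`,
#'   `tree_species_structure`, `vegetation_coverage`, `crown_density`,
#'   `tree_height`, `litter_depth`.
#' @param raw_value numeric vector of raw index values.
#' @return integer vector of type scores in `{1, 2, 3}`.
#' @export
classify_index <- function(index_name, raw_value) {
  index_name <- match.arg(index_name, plot_index_names)
  if (any(!is.finite(raw_value))) stop("non-finite raw index value")
  s <- classify_one(index_name, raw_value)
  if (anyNA(s)) {
    warning(sum(is.na(s)), " value(s) of ", index_name,
            " outside all listed intervals: classified type III")
    s[is.na(s)] <- 3L
  }
  s
}

#' Plot ecological quality score
#'
#' `Y = sum_i W_i X_i` over the seven indices; with the default weights
#' (summing to 1) Y lies in \[1, 3\] and lower means better ecological
#' condition.
#'
#' @param type_scores numeric vector of 7 type scores in `{1, 2, 3}`; if
#'   named, matched to the weight names, else taken in weight order.
#' @param weights weights per index (default [default_plot_weights()]).
#' @return Y.
#' @export
plot_quality <- function(type_scores, weights = default_plot_weights()) {
  if (length(type_scores) != length(weights))
    stop("expected ", length(weights), " type scores, got ", length(type_scores))
  if (!all(type_scores %in% 1:3))
    stop("type scores must all be in {1, 2, 3}")
  if (!is.null(names(type_scores))) {
    if (!setequal(names(type_scores), names(weights)))
      stop("type score names do not match the weight names")
    type_scores <- type_scores[names(weights)]
  }
  sum(weights * type_scores)
}

#' Ecological grade of a plot
#'
#' Four grades by Y interval: Excellent (code 1) below 1.4, Good (2) in
#' \[1.4, 1.8), Medium (3) in \[1.8, 2.2\], Poor (4) above 2.2.
#'
#' @param y numeric vector of composite scores.
#' @param breaks the three break points (default `c(1.4, 1.8, 2.2)`).
#' @return integer grade codes 1-4 with labels in attribute `labels`.
#' @export
grade_plot <- function(y, breaks = c(1.4, 1.8, 2.2)) {
  if (any(!is.finite(y))) stop("non-finite plot score")
  code <- ifelse(y < breaks[1], 1L,
          ifelse(y < breaks[2], 2L,
          ifelse(y <= breaks[3], 3L, 4L)))
  structure(code, labels = c("Excellent", "Good", "Medium", "Poor"))
}

#' Score and grade survey plots
#'
#' Types every raw index, computes Y and assigns the ecological grade.
#'
#' @param plots data.frame with the seven raw index columns (named as in
#'   [default_plot_weights()]); other columns are carried through.
#' @param weights index weights.
#' @return `plots` with `X_<index>` type-score columns, `Y`, and
#'   `ecological_grade` appended.
#' @export
score_plots <- function(plots, weights = default_plot_weights()) {
  miss <- setdiff(names(weights), names(plots))
  if (length(miss))
    stop("missing index column(s): ", paste(miss, collapse = ", "))
  xs <- sapply(names(weights), function(nm) classify_index(nm, plots[[nm]]))
  xs <- matrix(xs, nrow = nrow(plots),
               dimnames = list(NULL, paste0("X_", names(weights))))
  y <- as.numeric(xs %*% weights)
  out <- cbind(plots, xs)
  out$Y <- y
  out$ecological_grade <- as.integer(grade_plot(y))
  out
}

# distance from each point to the nearest feature; features is a point set
# (x, y) or a polyline set (road_id, x, y with consecutive vertices)
nearest_feature_distance <- function(px, py, features) {
  if (is.null(features) || nrow(features) == 0) return(rep(Inf, length(px)))
  if ("road_id" %in% names(features)) {
    d2 <- rep(Inf, length(px))
    for (id in unique(features$road_id)) {
      seg <- features[features$road_id == id, , drop = FALSE]
      for (i in seq_len(nrow(seg) - 1L)) {
        d2 <- pmin(d2, dist2_point_segment(px, py, seg$x[i], seg$y[i],
                                           seg$x[i + 1L], seg$y[i + 1L]))
      }
    }
    sqrt(d2)
  } else {
    sapply(seq_along(px), function(i)
      sqrt(min((features$x - px[i])^2 + (features$y - py[i])^2)))
  }
}

#' Estimate a threat's maximum effective distance from plot quality
#'
#' Computes each plot's distance to the nearest feature (village points or
#' road polylines) and sweeps a cutoff d upward in bins. At each d, the
#' Pearson correlation between plot quality Y and distance is tested among
#' the plots farther than d. The estimate is the smallest d beyond which the
#' correlation is no longer significant at `alpha`: past that distance the
#' feature shows no detectable association with plot quality. If the
#' correlation stays significant throughout, `max_search` is returned with a
#' warning. This is an interpretation of an under-specified published
#' procedure; see the methods vignette.
#'
#' @param plots data.frame with `x`, `y` and quality column `Y`.
#' @param features point set (`x`, `y`) or polyline set (`road_id`, `x`, `y`).
#' @param max_search cap on the threshold, meters.
#' @param bin sweep step, meters.
#' @param alpha significance level (default 0.05).
#' @return threshold distance in meters.
#' @export
threat_distance_threshold <- function(plots, features, max_search, bin,
                                      alpha = 0.05) {
  if (nrow(plots) < 10) stop("need at least 10 plots")
  if (bin <= 0) stop("bin must be positive")
  if (!"Y" %in% names(plots)) stop("plots must carry a quality column `Y`")
  if (is.null(features) || nrow(features) == 0) {
    warning("no features supplied: returning max_search")
    return(max_search)
  }
  d <- nearest_feature_distance(plots$x, plots$y, features)
  for (cut in seq(bin, max_search, by = bin)) {
    sel <- d > cut
    if (sum(sel) < 4 || stats::sd(plots$Y[sel]) == 0 || stats::sd(d[sel]) == 0)
      return(cut)
    p <- stats::cor.test(plots$Y[sel], d[sel])$p.value
    if (p > alpha) return(cut)
  }
  warning("correlation significant up to max_search; returning max_search")
  max_search
}
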