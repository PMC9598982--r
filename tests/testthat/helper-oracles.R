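# Independent oracles: literal, exhaustive implementations kept deliberately
# separate from the package's vectorized / transform-based code paths.

# exhaustive nearest-source search over all presence pixels
brute_distance_to_nearest <- function(presence, pixel_size) {
  nr <- nrow(presence); nc <- ncol(presence)
  src <- which(presence, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (nrow(src) == 0) return(out)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d2 <- min((src[, 1] - r)^2 + (src[, 2] - c)^2)
    out[r, c] <- sqrt(d2) * pixel_size
  }
  out
}

# literal per-pixel, per-threat degradation accumulation
brute_degradation <- function(lulc, threats, sens) {
  v <- monkeyhab::grid_values(lulc)
  defs <- threats$defs
  wsum <- sum(defs$weight)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  dists <- lapply(defs$name, function(nm)
    brute_distance_to_nearest(threats$presence[[nm]], lulc$pixel_size))
  for (r in seq_len(nrow(v))) for (c in seq_len(ncol(v))) {
    if (is.na(v[r, c])) next
    acc <- 0
    for (i in seq_len(nrow(defs))) {
      d <- dists[[i]][r, c]
      if (!is.finite(d)) next
      infl <- monkeyhab::decay_influence(d, defs$d_max_km[i] * 1000,
                                         defs$decay[i])
      acc <- acc + (defs$weight[i] / wsum) * infl *
        sens[as.character(v[r, c]), defs$name[i]]
    }
    out[r, c] <- acc
  }
  out
}

# literal double-loop Moran's I
brute_morans_i <- function(values, W) {
  W <- as.matrix(W)
  n <- length(values)
  zc <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}

# small random scene with villages/roads on a given grid
random_small_scene <- function(seed, nr = 15L, nc = 15L, pixel = 100,
                               n_villages = 6L) {
  cfg <- scene_config(grid_shape = c(nr, nc), pixel_size = pixel,
                      n_villages = n_villages, n_groups = 0L,
                      plot_size = nr * pixel, seed = seed)
  generate_scene(cfg)
}
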