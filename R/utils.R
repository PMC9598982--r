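# small shared helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

roman_grades <- c("I", "II", "III", "IV", "V", "VI", "VII")

# squared point-to-segment distance, vectorized over points
dist2_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
}

# even-odd ray casting; vertices (vx, vy) form a closed ring (no repeat needed)
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(px)
  inside <- rep(FALSE, n)
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) /
        ifelse(denom == 0, 1, denom)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}
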