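# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking.

# Monte-Carlo disk-in-rectangle fraction: sample points uniformly over the
# disk, count the fraction landing inside the FOV rectangle.
mc_disk_fraction <- function(x, y, r, fov, n = 1e5, chunk = 2e6) {
  if (r <= 0) {
    return(as.numeric(abs(x) <= fov$width / 2 & abs(y) <= fov$height / 2))
  }
  hw <- fov$width / 2; hh <- fov$height / 2
  hits <- 0
  left <- n
  while (left > 0) {
    m <- min(left, chunk)
    rad <- r * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    px <- x + rad * cos(th)
    py <- y + rad * sin(th)
    hits <- hits + sum(abs(px) <= hw & abs(py) <= hh)
    left <- left - m
  }
  hits / n
}

# Exhaustive minimum linking cost over every partial matching plus
# birth/death alternatives (for small instances).
oracle_link_cost <- function(cm, birth_cost, death_cost) {
  n1 <- nrow(cm); n2 <- ncol(cm)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return(invisible())
    if (i > n1) {
      tot <- cost + (n2 - length(used)) * birth_cost
      if (tot < best) best <<- tot
      return(invisible())
    }
    rec(i + 1L, used, cost + death_cost)
    for (j in seq_len(n2)) {
      if (!(j %in% used) && is.finite(cm[i, j])) {
        rec(i + 1L, c(used, j), cost + cm[i, j])
      }
    }
  }
  rec(1L, integer(0), 0)
  best
}

# Naive event-by-event pure-birth simulator using the printed waiting-time
# rule directly (no vectorization): cell count at time t_min.
oracle_birth_count <- function(t_min, interval_min = 720) {
  t <- 0; n <- 1L
  repeat {
    w <- -(interval_min / n) * log(stats::runif(1))
    if (t + w > t_min) return(n)
    t <- t + w
    n <- n + 1L
  }
}

# Small rendering geometry shared by tracker tests: a 222-um FOV sampled at
# 4x coarser pixels than the reference camera, which keeps synthetic movies
# light while preserving all physical scales.
fov_small <- function() fov_from_camera(256, 256, 0.8672)

# Detection row constructor for hand-built linking/tracking fixtures.
det_row <- function(x, y, intensity, area = 50) {
  n <- max(length(x), length(y), length(intensity))
  data.frame(x_px = rep_len(x, n), y_px = rep_len(y, n),
             intensity = rep_len(intensity, n), area = rep_len(area, n))
}
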