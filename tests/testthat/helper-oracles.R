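# Independent brute-force oracles used to validate the fast implementations.

# Definition-based Voronoi adjacency for tiny patterns: points i and j share
# a (positive length) Voronoi ridge iff some point c on their bisector is
# strictly closer to them than to every other point. Writing c(t) = m + t*u
# (m the midpoint, u the bisector direction), each condition
# |c - k|^2 > |c - i|^2 is linear in t, so adjacency reduces to a non-empty
# interval after intersecting half-lines. O(n) per pair, exact.
oracle_voronoi_edges <- function(x, y) {
  n <- length(x)
  span <- max(diff(range(x)), diff(range(y)))
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- c(x[i] + x[j], y[i] + y[j]) / 2
      u <- c(-(y[j] - y[i]), x[j] - x[i])
      u <- u / sqrt(sum(u^2))
      tlo <- -Inf
      thi <- Inf
      feasible <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        kv <- c(x[k] - x[i], y[k] - y[i])
        b <- -2 * sum(u * kv)
        a <- -2 * sum((m - c(x[i], y[i])) * kv) + sum(kv^2)
        if (b > 0) tlo <- max(tlo, -a / b)
        else if (b < 0) thi <- min(thi, -a / b)
        else if (a <= 0) { feasible <- FALSE; break }
      }
      if (feasible && thi - tlo > 1e-7 * max(1, span))
        out <- rbind(out, c(i, j))
    }
  }
  as.data.frame(out)
}

# Brute-force two-sample KS statistic: ECDF sweep over the pooled support.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# Brute-force Spearman correlation: rank then Pearson on the ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force disc membership: pixel centers within `radius` of a position.
oracle_disc_pixels <- function(px, py, radius, grid_size) {
  centers <- expand.grid(i = seq_len(grid_size), j = seq_len(grid_size))
  cx <- centers$i - 0.5
  cy <- centers$j - 0.5
  centers[(cx - px)^2 + (cy - py)^2 <= radius^2, ]
}

# Unwrap periodic agent tracks from simulation snapshots into trajectories.
unwrap_agent_tracks <- function(sim, agent_ids) {
  L <- as.numeric(sim$params$grid_size)
  lapply(agent_ids, function(a) {
    xs <- vapply(sim$snapshots, function(s) s$positions[a, 1], numeric(1))
    ys <- vapply(sim$snapshots, function(s) s$positions[a, 2], numeric(1))
    x <- cumsum(c(xs[1], spotdyn:::wrap_diff(diff(xs), L)))
    y <- cumsum(c(ys[1], spotdyn:::wrap_diff(diff(ys), L)))
    trajectory(sim$times, x, y, track_id = a)
  })
}
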