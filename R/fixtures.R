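## Synthetic-data generators with known ground truth. Every analysis stage
## in the package has a generator here whose parameters it should recover;
## all draw from R's global RNG so set.seed() makes them deterministic.

#' Generate a merging pair of trajectories
#'
#' Two tracks approach head-on along the x-axis so that their separation is
#' exactly `d_rel(t) = d0 - v0 * t - (a / 2) * t^2` (a constant-acceleration
#' approach), plus i.i.d. Gaussian positional noise; the series is truncated
#' at contact. [merging_kinematics()] applied to the noiseless output
#' recovers `(a, v0, d0)` exactly.
#'
#' @param a closing acceleration (>= 0 gives accelerating approach).
#' @param v0 initial closing speed.
#' @param d0 initial separation (> 0).
#' @param noise_sd positional noise standard deviation per coordinate.
#' @param n_points number of samples (>= 20).
#' @param dt sampling interval.
#' @return list with trajectories `a` and `b`, the noiseless `d_rel`
#'   data.frame, and the analytic `contact_time`.
#' @export
gen_merger_pair <- function(a = 0.004, v0 = 0.01, d0 = 2, noise_sd = 0,
                            n_points = 40L, dt = 0.25) {
  stopifnot(d0 > 0, n_points >= 20L)
  if (a <= 0 && v0 <= 0)
    stop("no approach: need a > 0 or v0 > 0")
  contact <- if (a > 0) {
    (-v0 + sqrt(v0^2 + 2 * a * d0)) / a
  } else d0 / v0
  t <- (seq_len(n_points) - 1L) * dt
  d <- d0 - v0 * t - a / 2 * t^2
  keep <- d > 0 & t <= contact
  t <- t[keep]
  d <- d[keep]
  if (length(t) < 3L) stop("parameters give contact before 3 samples; reduce dt")
  xa <- d / 2
  xb <- -d / 2
  noise <- function(n) if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  tra <- trajectory(t, xa + noise(length(t)), noise(length(t)),
                    track_id = "A", merge_class = "two_spot_merger")
  trb <- trajectory(t, xb + noise(length(t)), noise(length(t)),
                    track_id = "B", merge_class = "two_spot_merger")
  list(a = tra, b = trb, d_rel = data.frame(t = t, d = d),
       contact_time = contact)
}

#' Generate track ensembles with known MSD scaling
#'
#' Brownian tracks (`alpha_target = 1`, Gaussian increments with diffusion
#' coefficient `D`) or constant-random-velocity tracks (`alpha_target = 2`,
#' uniform random heading, constant speed), the two closed-form reference
#' cases for [msd_exponent()].
#'
#' @param alpha_target 1 (Brownian) or 2 (ballistic).
#' @param n_tracks,n_points ensemble shape.
#' @param dt sampling interval.
#' @param D diffusion coefficient of the Brownian case.
#' @param speed constant speed of the ballistic case.
#' @return list of [trajectory()] objects.
#' @export
gen_scaling_tracks <- function(alpha_target, n_tracks = 200L, n_points = 100L,
                               dt = 0.25, D = 1, speed = 1) {
  stopifnot(alpha_target %in% c(1, 2), n_points >= 2L)
  t <- (seq_len(n_points) - 1L) * dt
  lapply(seq_len(n_tracks), function(i) {
    if (alpha_target == 1) {
      sig <- sqrt(2 * D * dt)
      x <- cumsum(c(0, rnorm(n_points - 1L, 0, sig)))
      y <- cumsum(c(0, rnorm(n_points - 1L, 0, sig)))
    } else {
      th <- runif(1, 0, 2 * pi)
      x <- speed * cos(th) * t
      y <- speed * sin(th) * t
    }
    trajectory(t, x, y, track_id = i)
  })
}

#' Generate a scene of planted aggregates plus free agents
#'
#' Dense uniform discs of agents at well-separated random centers, plus
#' uniformly scattered free agents; the ground-truth centers are returned so
#' segmentation recall/precision can be scored exactly.
#'
#' @param n_clusters number of planted discs.
#' @param agents_per_cluster agents per disc.
#' @param cluster_radius disc radius, px.
#' @param n_free number of uniformly scattered agents.
#' @param grid_size pixels per side of the periodic domain.
#' @param min_separation minimum center separation (default
#'   `4 * cluster_radius`, plus a margin from the domain edge for
#'   convenience of non-periodic checks).
#' @param max_tries placement attempts before giving up.
#' @return list with `positions` (n x 2), `centers` (n_clusters x 2).
#' @export
gen_planted_aggregates <- function(n_clusters, agents_per_cluster,
                                   cluster_radius, n_free, grid_size,
                                   min_separation = 4 * cluster_radius,
                                   max_tries = 1e5) {
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  margin <- 2 * cluster_radius + 3
  while (nrow(centers) < n_clusters) {
    cand <- runif(2, margin, grid_size - margin)
    ok <- nrow(centers) == 0L ||
      min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >
      min_separation
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place well-separated clusters; reduce n_clusters or radius")
  }
  pos <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n_clusters)) {
    r <- cluster_radius * sqrt(runif(agents_per_cluster))
    th <- runif(agents_per_cluster, 0, 2 * pi)
    pos <- rbind(pos, cbind(centers[k, 1] + r * cos(th),
                            centers[k, 2] + r * sin(th)))
  }
  if (n_free > 0)
    pos <- rbind(pos, cbind(runif(n_free, 0, grid_size),
                            runif(n_free, 0, grid_size)))
  pos <- pos %% grid_size
  colnames(pos) <- c("x", "y")
  colnames(centers) <- c("x", "y")
  list(positions = pos, centers = centers)
}

#' Generate a polydisperse hard-sphere packing
#'
#' Sequential random insertion where every point carries a Gaussian-drawn
#' radius (mean `mean_d / 2`, coefficient of variation `cv`, truncated
#' positive) and a candidate is rejected when closer to any accepted point
#' than the sum of their radii. `cv = 0` reduces exactly to
#' [hard_sphere_pattern()] with `d_min = mean_d`.
#'
#' @param n number of points.
#' @param L side length.
#' @param mean_d mean exclusion diameter.
#' @param cv coefficient of variation of the radius distribution.
#' @param unit unit label.
#' @param max_rejects consecutive-rejection cap.
#' @return list with `pattern` (a [point_pattern()]) and `radii`.
#' @export
gen_polydisperse_packing <- function(n, L, mean_d, cv = 0.3, unit = "mm",
                                     max_rejects = 1e6) {
  stopifnot(cv >= 0, mean_d > 0, n >= 1)
  mean_r <- mean_d / 2
  draw_radius <- function() {
    if (cv == 0) return(mean_r)
    repeat {
      r <- rnorm(1, mean_r, cv * mean_r)
      if (r > 0) return(r)
    }
  }
  px <- numeric(n)
  py <- numeric(n)
  pr <- numeric(n)
  acc <- 0L
  rejects <- 0
  while (acc < n) {
    cx <- runif(1, 0, L)
    cy <- runif(1, 0, L)
    cr <- draw_radius()
    ok <- acc == 0L || all(sqrt((px[seq_len(acc)] - cx)^2 +
                                (py[seq_len(acc)] - cy)^2) >=
                           pr[seq_len(acc)] + cr)
    if (ok) {
      acc <- acc + 1L
      px[acc] <- cx
      py[acc] <- cy
      pr[acc] <- cr
      rejects <- 0
    } else {
      rejects <- rejects + 1
      if (rejects >= max_rejects)
        stop(sprintf("packing saturated after %d points: density infeasible",
                     acc))
    }
  }
  list(pattern = point_pattern(px, py, L, unit), radii = pr)
}
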