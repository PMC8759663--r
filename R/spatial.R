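## Spatial point-pattern statistics: Voronoi neighbor distances, radial pair
## correlation, structure factor, and the random / hard-sphere null patterns.

#' Point pattern in a square region
#'
#' @param x,y coordinates; all points must lie inside `[0, L]^2`.
#' @param L side length of the square region.
#' @param unit unit label (informational), e.g. `"mm"` or `"px"`.
#' @return object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, L, unit = "mm") {
  stopifnot(length(x) == length(y), length(x) >= 1, L > 0)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite coordinates")
  if (any(x < 0 | x > L | y < 0 | y > L))
    stop("all points must lie inside [0, L]^2")
  structure(list(x = as.numeric(x), y = as.numeric(y), L = L, unit = unit),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in a %g x %g %s square (density %.4g / %s^2)\n",
              length(x$x), x$L, x$L, x$unit, length(x$x) / x$L^2, x$unit))
  invisible(x)
}

#' Voronoi-neighbor distances of a point pattern
#'
#' Computes the Voronoi tessellation of the pattern and pools the Euclidean
#' distances between every pair of points whose cells share a (positive
#' length) Voronoi edge, each unordered pair once. This is the
#' "all nearest neighbors" distance set: every point contributes its full
#' Voronoi neighborhood, not just its single closest neighbor. By default
#' pairs involving hull points (unbounded cells) are included, which is what
#' reproduces the pooled distribution of a uniform random pattern;
#' `include_hull = FALSE` restricts to pairs with at least one bounded-cell
#' member.
#'
#' @param pattern a [point_pattern()] (n >= 4).
#' @param include_hull logical, see above.
#' @return numeric vector of pooled pair distances.
#' @export
voronoi_neighbor_distances <- function(pattern, include_hull = TRUE) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(pattern$x) < 4L)
    stop("Voronoi neighbor analysis needs at least 4 points")
  vn <- cpp_voronoi_neighbors(pattern$x, pattern$y)
  i <- vn$i
  j <- vn$j
  if (!include_hull) {
    keep <- vn$bounded[i] | vn$bounded[j]
    i <- i[keep]
    j <- j[keep]
  }
  sqrt((pattern$x[i] - pattern$x[j])^2 + (pattern$y[i] - pattern$y[j])^2)
}

#' Radial pair correlation function g(r)
#'
#' Estimator with edge handling by focal-point exclusion: every point
#' farther than `r_max` from all four boundaries is a focal point; distances
#' from each focal point to all other points are histogrammed into bins
#' `[n*dr, (n+1)*dr)`, each bin is divided by the pattern density
#' `rho = N / L^2` and by the annulus area `pi * (r_out^2 - r_in^2)`, and the
#' result is averaged over focal points. No periodic wrap is used (plates
#' are not periodic).
#'
#' @param pattern a [point_pattern()].
#' @param r_max maximum distance (must be < L/2).
#' @param dr bin width (> 0).
#' @return object of class `gofr`: data.frame with bin centers `r` and `g`,
#'   with attributes `rho`, `dr`, `r_max`, `n_focal`.
#' @export
pair_correlation <- function(pattern, r_max = 20, dr = 0.1) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!(r_max < pattern$L / 2)) stop("r_max must be < L/2")
  if (dr <= 0) stop("dr must be > 0")
  x <- pattern$x
  y <- pattern$y
  n <- length(x)
  rho <- n / pattern$L^2
  focal <- which(x >= r_max & x <= pattern$L - r_max &
                 y >= r_max & y <= pattern$L - r_max)
  if (length(focal) == 0L)
    stop("no focal points farther than r_max from every boundary")
  nb <- floor(r_max / dr + 1e-9)
  breaks <- (0:nb) * dr
  counts <- numeric(nb)
  for (f in focal) {
    d <- sqrt((x - x[f])^2 + (y - y[f])^2)
    d <- d[-f]
    d <- d[d < nb * dr]
    if (length(d) > 0L) {
      h <- tabulate(pmin(floor(d / dr) + 1L, nb), nbins = nb)
      counts <- counts + h
    }
  }
  r_in <- breaks[-(nb + 1L)]
  r_out <- breaks[-1L]
  ann <- pi * (r_out^2 - r_in^2)
  g <- counts / (length(focal) * rho * ann)
  out <- data.frame(r = (r_in + r_out) / 2, g = g)
  attr(out, "rho") <- rho
  attr(out, "dr") <- dr
  attr(out, "r_max") <- r_max
  attr(out, "n_focal") <- length(focal)
  class(out) <- c("gofr", "data.frame")
  out
}

#' Structure factor s(k) from g(r)
#'
#' Numerically integrates
#' `s(k) = 1 + (2 * pi * rho / k) * integral_0^rmax (g(r) - 1) * sin(k r) dr`
#' by the trapezoidal rule over the g(r) bins. This sine-kernel form is the
#' transform used in the reference analysis this package mirrors; the exact 2D
#' transform uses a Bessel kernel,
#' `s(k) = 1 + 2 * pi * rho * integral (g(r) - 1) * J0(k r) * r dr`,
#' available with `kernel = "bessel"`.
#'
#' @param g a `gofr` object from [pair_correlation()].
#' @param rho point density; defaults to the density stored in `g`.
#' @param k_grid wavenumbers (all > 0).
#' @param kernel `"sine"` (default) or `"bessel"`.
#' @return object of class `sofk`: data.frame with `k` and `s`.
#' @export
structure_factor <- function(g, rho = attr(g, "rho"),
                             k_grid = seq(0.1, 5, by = 0.05),
                             kernel = c("sine", "bessel")) {
  kernel <- match.arg(kernel)
  if (any(k_grid <= 0)) stop("k_grid must be strictly positive (k = 0 is excluded)")
  r <- g$r
  h <- g$g - 1
  s <- vapply(k_grid, function(k) {
    f <- if (kernel == "sine") h * sin(k * r) else h * besselJ(k * r, 0) * r
    integral <- sum(diff(r) * (f[-1] + f[-length(f)]) / 2)
    if (kernel == "sine") 1 + 2 * pi * rho / k * integral
    else 1 + 2 * pi * rho * integral
  }, numeric(1))
  out <- data.frame(k = k_grid, s = s)
  class(out) <- c("sofk", "data.frame")
  out
}

#' Uniform random (binomial) point pattern
#'
#' `n` i.i.d. uniform points on `[0, L]^2`; the complete-spatial-randomness
#' null used for comparison with aggregate patterns.
#'
#' @param n number of points.
#' @param L side length.
#' @param unit unit label.
#' @return a [point_pattern()].
#' @export
random_pattern <- function(n, L, unit = "mm") {
  stopifnot(n >= 1)
  point_pattern(runif(n, 0, L), runif(n, 0, L), L, unit)
}

#' Hard-sphere (minimum separation) point pattern
#'
#' Sequential random insertion with rejection: candidates closer than
#' `d_min` to any accepted point are rejected. Errors out after
#' `max_rejects` consecutive rejections (packing saturation).
#'
#' @param n number of points.
#' @param L side length.
#' @param d_min minimum pairwise separation.
#' @param unit unit label.
#' @param max_rejects consecutive-rejection cap.
#' @return a [point_pattern()].
#' @export
hard_sphere_pattern <- function(n, L, d_min, unit = "mm",
                                max_rejects = 1e6) {
  stopifnot(n >= 1, d_min >= 0)
  px <- numeric(n)
  py <- numeric(n)
  acc <- 0L
  rejects <- 0
  while (acc < n) {
    cx <- runif(1, 0, L)
    cy <- runif(1, 0, L)
    if (acc == 0L ||
        min((px[seq_len(acc)] - cx)^2 + (py[seq_len(acc)] - cy)^2) >= d_min^2) {
      acc <- acc + 1L
      px[acc] <- cx
      py[acc] <- cy
      rejects <- 0
    } else {
      rejects <- rejects + 1
      if (rejects >= max_rejects)
        stop(sprintf(paste0("hard-sphere packing saturated after %d accepted ",
                            "points (%g consecutive rejections): density ",
                            "infeasible for d_min = %g"),
                     acc, rejects, d_min))
    }
  }
  point_pattern(px, py, L, unit)
}

#' Two-sample Kolmogorov-Smirnov comparison of distance samples
#'
#' Two-sided two-sample KS test (`stats::ks.test`, asymptotic p-value):
#' `D = sup |F_a - F_b|` over the pooled support.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return list with `D` and `p_value`.
#' @export
compare_patterns_ks <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  res <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}
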