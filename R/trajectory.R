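## Trajectory analysis: speeds, path directness, MSD scaling, relative
## distance kinematics of merging pairs, force-law fits and cohort summaries.

#' Aggregate trajectory
#'
#' A time-ordered sequence of positions (and optionally areas) for one
#' tracked aggregate. Times must be strictly increasing and at least two
#' points are required; merging kinematics additionally require 20 points.
#'
#' @param t times (hr, or frames).
#' @param x,y positions (mm or px).
#' @param area aggregate areas, optional.
#' @param track_id identifier.
#' @param merge_class one of `"non_merger"`, `"two_spot_merger"`,
#'   `"three_spot_merger"`, or NA.
#' @return data.frame of class `trajectory` with attributes `track_id` and
#'   `merge_class`.
#' @export
trajectory <- function(t, x, y, area = NULL, track_id = NA,
                       merge_class = NA_character_) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2L) stop("a trajectory needs at least 2 points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  d <- data.frame(t = t, x = x, y = y,
                  area = if (is.null(area)) NA_real_ else area)
  attr(d, "track_id") <- track_id
  attr(d, "merge_class") <- merge_class
  class(d) <- c("trajectory", "data.frame")
  d
}

#' Split linked tracks into trajectory objects
#'
#' @param tracks data.frame from [link_tracks()] (columns `track_id`,
#'   `time`, `x`, `y`, `area`).
#' @param classes optional named class vector from [classify_merging()].
#' @param min_points drop tracks with fewer points than this (default 2).
#' @return named list of [trajectory()] objects.
#' @export
tracks_to_trajectories <- function(tracks, classes = NULL, min_points = 2L) {
  ids <- sort(unique(tracks$track_id))
  out <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < min_points) next
    cls <- if (!is.null(classes)) unname(classes[as.character(id)]) else NA_character_
    out[[as.character(id)]] <- trajectory(tr$time, tr$x, tr$y, tr$area,
                                          track_id = id, merge_class = cls)
  }
  out
}

#' Average speed of a trajectory
#'
#' Default definition: total path length (sum of consecutive displacements)
#' divided by elapsed time. `mode = "frame"` instead averages the per-frame
#' speeds (displacement over interval, averaged over intervals).
#'
#' @param traj a [trajectory()].
#' @param mode `"path"` (default) or `"frame"`.
#' @return speed in position units per time unit.
#' @export
average_speed <- function(traj, mode = c("path", "frame")) {
  mode <- match.arg(mode)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  dt <- diff(traj$t)
  elapsed <- traj$t[nrow(traj)] - traj$t[1]
  if (elapsed <= 0) stop("zero elapsed time")
  if (mode == "path") sum(steps) / elapsed else mean(steps / dt)
}

#' Path length over net displacement
#'
#' Ratio of total path length to the straight-line distance between start
#' and end; 1 for a straight path, always >= 1. Zero net displacement is
#' undefined and returned as `NA` (such tracks are excluded, not infinite).
#'
#' @param traj a [trajectory()].
#' @return ratio >= 1, or NA.
#' @export
distance_over_displacement <- function(traj) {
  path <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  n <- nrow(traj)
  net <- sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2)
  if (net == 0) return(NA_real_)
  path / net
}

#' Anomalous-diffusion exponent from ensemble MSD
#'
#' Ensemble-averaged squared displacement from each track's first point at
#' common lag times, fitted with a least-squares line on log-log axes over
#' lags up to `max_lag_fraction` of the shortest track. The slope is the
#' power-law exponent alpha (1 = Brownian, 2 = ballistic; between 1 and 2 =
#' superdiffusive).
#'
#' @param trajs list of [trajectory()] objects with a common frame interval.
#' @param max_lag_fraction fit window as a fraction of the shortest track.
#' @param min_lags minimum number of usable lags (default 5).
#' @return object of class `msd_fit` with elements `alpha`, `prefactor`,
#'   `lag_time`, `msd`, `fit` (the underlying `lm`).
#' @export
msd_exponent <- function(trajs, max_lag_fraction = 0.5, min_lags = 5L) {
  if (length(trajs) == 0L) stop("no trajectories supplied")
  nmin <- min(vapply(trajs, nrow, integer(1)))
  max_lag <- floor(max_lag_fraction * (nmin - 1L))
  if (max_lag < min_lags)
    stop(sprintf("insufficient lags: shortest track supports %d, need >= %d",
                 max_lag, min_lags))
  dts <- unlist(lapply(trajs, function(tr) diff(tr$t)))
  dt <- median(dts)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    mean(vapply(trajs, function(tr) {
      (tr$x[1 + k] - tr$x[1])^2 + (tr$y[1 + k] - tr$y[1])^2
    }, numeric(1)))
  }, numeric(1))
  lag_time <- lags * dt
  ok <- msd > 0
  if (sum(ok) < min_lags) stop("too few non-zero MSD values to fit")
  fit <- lm(log(msd[ok]) ~ log(lag_time[ok]))
  out <- list(alpha = unname(coef(fit)[2]),
              prefactor = exp(unname(coef(fit)[1])),
              lag_time = lag_time, msd = msd, n_tracks = length(trajs),
              fit = fit)
  class(out) <- "msd_fit"
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD power-law fit over %d tracks, %d lags:\n  MSD(t) = %.4g * t^%.3f\n",
              x$n_tracks, length(x$lag_time), x$prefactor, x$alpha))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(alpha = object$alpha, prefactor = object$prefactor)
}

#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(x$lag_time, x$msd, log = "xy", xlab = "lag time",
                 ylab = "MSD", ...)
  graphics::abline(log10(x$prefactor), x$alpha, col = 2)
  invisible(x)
}

#' Relative distance of two trajectories
#'
#' Euclidean separation `d_rel(t) = |r_A(t) - r_B(t)|` at every common time.
#'
#' @param a,b [trajectory()] objects with overlapping time support.
#' @return data.frame with columns `t` and `d`.
#' @export
relative_distance <- function(a, b) {
  common <- intersect(a$t, b$t)
  if (length(common) == 0L) stop("trajectories share no common times")
  ia <- match(common, a$t)
  ib <- match(common, b$t)
  data.frame(t = common,
             d = sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2))
}

#' Constant-acceleration fit of a merging pair's relative distance
#'
#' Least-squares quadratic fit `d_rel(t) = d0 + b1 * t + b2 * t^2`. The
#' closing acceleration is reported as `-2 * b2`, so that an accelerating
#' approach (d_rel concave down) is positive, and the initial closing speed
#' as `-b1`. Series with fewer than `min_points` points are excluded (the
#' returned object carries `excluded = TRUE` and a reason) because short
#' series do not constrain the curvature.
#'
#' @param d_rel data.frame from [relative_distance()] (columns `t`, `d`).
#' @param min_points inclusion threshold (default 20).
#' @return object of class `merge_kinematics` with `acceleration` (closing,
#'   positive toward contact), `v0` (initial closing speed), `d0`,
#'   `rms_residual`, `se` (standard errors), `fit`.
#' @export
merging_kinematics <- function(d_rel, min_points = 20L) {
  if (nrow(d_rel) < min_points) {
    out <- list(excluded = TRUE,
                reason = sprintf("only %d points (< %d required)",
                                 nrow(d_rel), min_points))
    class(out) <- "merge_kinematics"
    return(out)
  }
  # center time for conditioning; report in original origin
  t0 <- d_rel$t[1]
  tt <- d_rel$t - t0
  fit <- lm(d ~ tt + I(tt^2), data = data.frame(d = d_rel$d, tt = tt))
  b <- coef(fit)
  # vcov warns on interpolating (zero-residual) fits; that case is legitimate
  # here (noiseless fixtures) and the SEs are simply 0
  sef <- sqrt(diag(suppressWarnings(vcov(fit))))
  res <- residuals(fit)
  out <- list(excluded = FALSE,
              acceleration = unname(-2 * b[3]),
              v0 = unname(-b[2]),
              d0 = unname(b[1]),
              rms_residual = sqrt(mean(res^2)),
              se = c(acceleration = unname(2 * sef[3]), v0 = unname(sef[2]),
                     d0 = unname(sef[1])),
              t_origin = t0, fit = fit)
  class(out) <- "merge_kinematics"
  out
}

#' @export
print.merge_kinematics <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("merging kinematics: excluded (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("constant-acceleration merging fit:\n  closing acceleration %.4g (SE %.3g), v0 %.4g, d0 %.4g, rms residual %.4g\n",
              x$acceleration, x$se["acceleration"], x$v0, x$d0,
              x$rms_residual))
  invisible(x)
}

#' @export
coef.merge_kinematics <- function(object, ...) {
  if (isTRUE(object$excluded)) return(c(acceleration = NA_real_,
                                        v0 = NA_real_, d0 = NA_real_))
  c(acceleration = object$acceleration, v0 = object$v0, d0 = object$d0)
}

#' @export
predict.merge_kinematics <- function(object, t, ...) {
  if (isTRUE(object$excluded)) stop("excluded fit")
  tt <- t - object$t_origin
  object$d0 - object$v0 * tt - object$acceleration / 2 * tt^2
}

#' @export
summary.merge_kinematics <- function(object, ...) {
  if (isTRUE(object$excluded)) return(object)
  summary(object$fit)
}

#' Distance-dependent force-law fit
#'
#' Estimates acceleration versus relative distance and fits either an
#' exponential law `a(d) = A0 * exp(-n * d)` or a power law
#' `a(d) = A0 / d^n` by nonlinear least squares. The acceleration is
#' obtained from central second differences of a 3-point moving average of
#' `d_rel` (sign flipped so closing acceleration is positive). Following the
#' inclusion rule used for these fits, the result is flagged excluded when
#' the exponent's standard error is at least half its magnitude, or when
#' the fit fails to converge.
#'
#' @param d_rel data.frame from [relative_distance()].
#' @param model `"exponential"` or `"power"`.
#' @param smooth_window moving-average window (odd, default 3).
#' @return object of class `force_law_fit` with `A0`, `n`, `se`, `excluded`.
#' @export
force_law_fit <- function(d_rel, model = c("exponential", "power"),
                          smooth_window = 3L) {
  model <- match.arg(model)
  t <- d_rel$t
  d <- d_rel$d
  if (length(d) < smooth_window + 4L)
    stop("series too short to differentiate")
  sm <- stats::filter(d, rep(1 / smooth_window, smooth_window), sides = 2)
  keep <- !is.na(sm)
  sm <- as.numeric(sm[keep])
  tk <- t[keep]
  dt <- median(diff(tk))
  m <- length(sm)
  acc <- -(sm[3:m] - 2 * sm[2:(m - 1)] + sm[1:(m - 2)]) / dt^2
  dd <- sm[2:(m - 1)]
  dat <- data.frame(a = acc, d = dd)
  dat <- dat[is.finite(dat$a) & is.finite(dat$d) & dat$d > 0, ]
  fail <- function(reason) {
    structure(list(model = model, A0 = NA_real_, n = NA_real_,
                   se = c(A0 = NA_real_, n = NA_real_),
                   excluded = TRUE, reason = reason),
              class = "force_law_fit")
  }
  if (nrow(dat) < 5L) return(fail("too few usable points"))
  start <- if (model == "exponential") {
    list(A0 = max(abs(dat$a)) + 1e-12, n = 1 / max(dat$d))
  } else {
    list(A0 = stats::median(abs(dat$a)) * stats::median(dat$d) + 1e-12, n = 1)
  }
  form <- if (model == "exponential") a ~ A0 * exp(-n * d) else a ~ A0 / d^n
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("did not converge"))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  excl <- !is.finite(se[2]) || se[2] / abs(cf[2]) >= 0.5
  structure(list(model = model, A0 = unname(cf[1]), n = unname(cf[2]),
                 se = c(A0 = unname(se[1]), n = unname(se[2])),
                 excluded = excl,
                 reason = if (excl) "SE(n)/|n| >= 0.5" else NA_character_,
                 fit = fit, data = dat),
            class = "force_law_fit")
}

#' @export
print.force_law_fit <- function(x, ...) {
  law <- if (x$model == "exponential") "a(d) = A0 * exp(-n d)" else "a(d) = A0 / d^n"
  cat(sprintf("force-law fit, %s:\n  A0 = %.4g, n = %.4g (SE %.3g)%s\n",
              law, x$A0, x$n, x$se["n"],
              if (isTRUE(x$excluded)) sprintf("  [excluded: %s]", x$reason) else ""))
  invisible(x)
}

#' Per-trajectory mean minimum nearest-neighbor distance
#'
#' For each trajectory, the nearest-neighbor distance to co-existing tracks
#' is computed at every frame, and the per-frame minima are averaged over
#' the trajectory's frames. Trajectories with no co-existing neighbor at any
#' frame get NA.
#'
#' @param trajs list of [trajectory()] objects.
#' @return numeric vector, one value per trajectory.
#' @export
mean_min_nn_distance <- function(trajs) {
  vapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    dmin <- vapply(seq_len(nrow(tr)), function(k) {
      t0 <- tr$t[k]
      best <- Inf
      for (j in seq_along(trajs)) {
        if (j == i) next
        o <- trajs[[j]]
        m <- match(t0, o$t)
        if (is.na(m)) next
        dd <- sqrt((o$x[m] - tr$x[k])^2 + (o$y[m] - tr$y[k])^2)
        if (dd < best) best <- dd
      }
      best
    }, numeric(1))
    dmin <- dmin[is.finite(dmin)]
    if (length(dmin) == 0L) NA_real_ else mean(dmin)
  }, numeric(1))
}

#' Cohort summary of classified trajectories
#'
#' Computes per-class counts and fractions, per-class mean speed and
#' distance-over-displacement, the unpaired two-sample t-test of merger
#' versus non-merger speeds (Student's equal-variance by default; set
#' `welch = TRUE` for the Welch variant), the Spearman rank correlation of
#' merging acceleration versus total merged area (when supplied), and the
#' Spearman correlation of speed versus mean minimum nearest-neighbor
#' distance among non-mergers.
#'
#' @param trajs list of [trajectory()] objects carrying `merge_class`.
#' @param accel optional numeric vector of closing accelerations of merging
#'   events.
#' @param merged_area optional numeric vector, total aggregate area per
#'   merging event (same length/order as `accel`).
#' @param welch logical; use Welch's t-test instead of Student's.
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(trajs, accel = NULL, merged_area = NULL,
                           welch = FALSE) {
  cls <- vapply(trajs, function(tr) {
    mc <- attr(tr, "merge_class")
    if (is.null(mc) || is.na(mc)) "non_merger" else mc
  }, character(1))
  speed <- vapply(trajs, average_speed, numeric(1))
  dod <- vapply(trajs, distance_over_displacement, numeric(1))
  lv <- c("non_merger", "two_spot_merger", "three_spot_merger")
  counts <- table(factor(cls, levels = lv))
  stats_by <- function(v) {
    vapply(lv, function(l) {
      vv <- v[cls == l & is.finite(v)]
      if (length(vv) < 2L) NA_real_ else mean(vv)
    }, numeric(1))
  }
  merger <- cls != "non_merger"
  ttest <- NULL
  if (sum(merger) >= 2L && sum(!merger) >= 2L &&
      (sd(speed[merger]) > 0 || sd(speed[!merger]) > 0)) {
    ttest <- t.test(speed[merger], speed[!merger], var.equal = !welch)
  }
  sp_aa <- NULL
  if (!is.null(accel) && !is.null(merged_area) && length(accel) >= 3L) {
    ok <- is.finite(accel) & is.finite(merged_area)
    if (sum(ok) >= 3L)
      sp_aa <- suppressWarnings(
        cor.test(accel[ok], merged_area[ok], method = "spearman"))
  }
  sp_nn <- NULL
  nm <- which(!merger)
  if (length(nm) >= 3L) {
    nn <- mean_min_nn_distance(trajs)[nm]
    ok <- is.finite(nn) & is.finite(speed[nm])
    if (sum(ok) >= 3L)
      sp_nn <- suppressWarnings(
        cor.test(speed[nm][ok], nn[ok], method = "spearman"))
  }
  out <- list(counts = counts, fractions = counts / length(trajs),
              mean_speed = stats_by(speed),
              mean_dist_over_disp = stats_by(dod),
              speed = speed, dist_over_disp = dod, classes = cls,
              speed_ttest = ttest,
              spearman_accel_area = sp_aa,
              spearman_speed_nn = sp_nn)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort summary over", sum(x$counts), "trajectories\n")
  for (l in names(x$counts)) {
    cat(sprintf("  %-18s n = %3d (%.1f%%)  mean speed %s  mean dist/disp %s\n",
                l, x$counts[[l]], 100 * x$fractions[[l]],
                formatC(x$mean_speed[[l]], digits = 3, format = "g"),
                formatC(x$mean_dist_over_disp[[l]], digits = 3, format = "g")))
  }
  if (!is.null(x$speed_ttest))
    cat(sprintf("  merger vs non-merger speed: diff %.4g, t-test p = %.3g\n",
                diff(rev(x$speed_ttest$estimate)),
                x$speed_ttest$p.value))
  if (!is.null(x$spearman_accel_area))
    cat(sprintf("  Spearman(acceleration, merged area): rho = %.3f, p = %.3g\n",
                x$spearman_accel_area$estimate, x$spearman_accel_area$p.value))
  if (!is.null(x$spearman_speed_nn))
    cat(sprintf("  Spearman(speed, min NN distance): rho = %.3f, p = %.3g\n",
                x$spearman_speed_nn$estimate, x$spearman_speed_nn$p.value))
  invisible(x)
}
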