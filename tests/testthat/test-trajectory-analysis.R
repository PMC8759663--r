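test_that("average speed and path directness follow their definitions", {
  straight <- trajectory(t = seq(0, 20, length.out = 11),
                         x = seq(0, 1, length.out = 11), y = rep(0, 11))
  expect_equal(average_speed(straight), 0.05)
  expect_equal(distance_over_displacement(straight), 1)

  stationary <- trajectory(t = 0:5, x = rep(2, 6), y = rep(3, 6))
  expect_equal(average_speed(stationary), 0)
  expect_true(is.na(distance_over_displacement(stationary)))

  # two equal legs at a right angle: path 2L, displacement L*sqrt(2)
  bent <- trajectory(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(distance_over_displacement(bent), sqrt(2))

  # triangle inequality: ratio >= 1 for arbitrary tracks
  set.seed(8)
  for (i in 1:10) {
    tr <- trajectory(t = 0:19, x = cumsum(rnorm(20)), y = cumsum(rnorm(20)))
    r <- distance_over_displacement(tr)
    if (!is.na(r)) expect_gte(r, 1 - 1e-12)
  }
})

test_that("MSD exponent recovers ballistic and Brownian scaling", {
  set.seed(71)
  ball <- gen_scaling_tracks(2, n_tracks = 100, n_points = 60)
  fb <- msd_exponent(ball)
  expect_lt(abs(fb$alpha - 2), 0.05)

  brow <- gen_scaling_tracks(1, n_tracks = 300, n_points = 100)
  fw <- msd_exponent(brow)
  expect_lt(abs(fw$alpha - 1), 0.1)

  expect_error(msd_exponent(gen_scaling_tracks(1, 5, 8)), "lags")
})

test_that("speed and MSD scale exactly under spatial rescaling", {
  set.seed(72)
  trs <- gen_scaling_tracks(1, n_tracks = 40, n_points = 50)
  c0 <- 2.5
  scaled <- lapply(trs, function(tr)
    trajectory(tr$t, tr$x * c0, tr$y * c0, track_id = attr(tr, "track_id")))
  expect_equal(vapply(scaled, average_speed, numeric(1)),
               c0 * vapply(trs, average_speed, numeric(1)))
  f1 <- msd_exponent(trs)
  f2 <- msd_exponent(scaled)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-12)
  expect_equal(f2$prefactor, c0^2 * f1$prefactor, tolerance = 1e-9)
})

test_that("relative distance handles identity, offset, and linear recession", {
  a <- trajectory(t = 0:9, x = 0:9, y = rep(0, 10))
  expect_true(all(relative_distance(a, a)$d == 0))
  b <- trajectory(t = 0:9, x = 0:9, y = rep(3, 10))
  expect_true(all(relative_distance(a, b)$d == 3))
  ra <- trajectory(t = 1:9, x = 1:9, y = rep(0, 9))
  rb <- trajectory(t = 1:9, x = -(1:9), y = rep(0, 9))
  expect_equal(relative_distance(ra, rb)$d, 2 * (1:9))
  late <- trajectory(t = 100:105, x = 0:5, y = rep(0, 6))
  expect_error(relative_distance(a, late), "common")
})

test_that("quadratic merging fit: exact recovery, noise within 3 SE, inclusion rule", {
  set.seed(81)
  pair <- gen_merger_pair(a = 0.004, v0 = 0.01, d0 = 2, noise_sd = 0,
                          n_points = 40, dt = 0.25)
  fit <- merging_kinematics(pair$d_rel)
  expect_false(fit$excluded)
  expect_equal(fit$acceleration, 0.004, tolerance = 1e-9)
  expect_equal(fit$v0, 0.01, tolerance = 1e-9)
  expect_equal(fit$d0, 2, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-10)
  # fitted curve reproduces the input at the sampled times
  expect_equal(predict(fit, pair$d_rel$t), pair$d_rel$d, tolerance = 1e-8)

  # noisy pairs: recovery within 3 standard errors (checked over replicates)
  hits <- 0
  for (i in 1:20) {
    noisy <- gen_merger_pair(a = 0.004, v0 = 0.01, d0 = 2, noise_sd = 0.01,
                             n_points = 60, dt = 0.25)
    d <- relative_distance(noisy$a, noisy$b)
    f <- merging_kinematics(d)
    if (abs(f$acceleration - 0.004) <= 3 * f$se["acceleration"]) hits <- hits + 1
  }
  expect_gte(hits, 18)

  short <- merging_kinematics(pair$d_rel[1:10, ])
  expect_true(short$excluded)
  expect_match(short$reason, "points")
})

test_that("force-law fits recover planted exponents and flag flat laws", {
  # exact exponential force law integrated numerically
  t <- seq(0, 60, by = 0.25)
  A0 <- 0.02; nexp <- 0.8
  d <- numeric(length(t)); v <- numeric(length(t))
  d[1] <- 4
  for (i in seq_along(t)[-1]) {
    acc <- A0 * exp(-nexp * d[i - 1])
    v[i] <- v[i - 1] + acc * 0.25
    d[i] <- max(d[i - 1] - v[i] * 0.25, 1e-6)
  }
  keep <- d > 0.05
  fit <- force_law_fit(data.frame(t = t[keep], d = d[keep]), "exponential")
  expect_false(fit$excluded)
  expect_lt(abs(fit$n - nexp), 3 * fit$se["n"] + 0.1)

  # constant acceleration: power-law exponent approximately zero
  set.seed(91)
  pair <- gen_merger_pair(a = 0.01, v0 = 0.02, d0 = 3, noise_sd = 0,
                          n_points = 60, dt = 0.25)
  pfit <- force_law_fit(pair$d_rel, "power")
  expect_lt(abs(pfit$n), 0.05)
})

test_that("Spearman statistic agrees with the brute-force oracle on small samples", {
  set.seed(92)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- suppressWarnings(cor.test(x, y, method = "spearman"))$estimate
    expect_equal(unname(got), oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("cohort summary: planted correlations and degenerate classes", {
  set.seed(93)
  mk <- function(cls, speed) {
    n <- 25
    trajectory(t = 0:(n - 1), x = seq(0, speed * (n - 1), length.out = n),
               y = rnorm(n, 0, 1e-4), merge_class = cls)
  }
  trajs <- c(lapply(1:6, function(i) mk("non_merger", 0.02 + 0.001 * i)),
             lapply(1:4, function(i) mk("two_spot_merger", 0.05 + 0.001 * i)))
  accel <- c(0.001, 0.002, 0.003, 0.004)
  area <- c(1, 2, 3, 4) # perfectly monotone with accel
  cs <- cohort_summary(trajs, accel = accel, merged_area = area)
  expect_equal(as.integer(cs$counts), c(6L, 4L, 0L))
  expect_equal(unname(cs$spearman_accel_area$estimate), 1)
  expect_lt(cs$speed_ttest$p.value, 0.01)
  expect_gt(cs$mean_speed[["two_spot_merger"]],
            cs$mean_speed[["non_merger"]])
  # degenerate: identical tracks in one class give no t-test
  same <- lapply(1:4, function(i) mk("non_merger", 0.02))
  cs2 <- cohort_summary(same)
  expect_null(cs2$speed_ttest)
})

test_that("per-frame minimum NN distance averages correctly", {
  a <- trajectory(t = 0:4, x = rep(0, 5), y = rep(0, 5))
  b <- trajectory(t = 0:4, x = rep(3, 5), y = rep(0, 5))
  c3 <- trajectory(t = 0:4, x = rep(10, 5), y = rep(0, 5))
  nn <- mean_min_nn_distance(list(a, b, c3))
  expect_equal(nn, c(3, 3, 7))
})
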