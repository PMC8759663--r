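p_base <- sim_params(n_agents = 100, grid_size = 32, t_final = 1)

test_that("receptor-law drift: zero gradient, saturation, and closed form", {
  expect_equal(chemotactic_drift(5, c(0, 0), p_base), c(0, 0))
  g <- c(0.3, -0.2)
  expect_equal(chemotactic_drift(0, g, p_base), p_base$chi0 * g)
  # saturation: magnitude non-increasing in c, vanishing at large c
  cs <- c(0, 1, 10, 100, 1e6)
  mags <- vapply(cs, function(cc)
    sqrt(sum(chemotactic_drift(cc, g, p_base)^2)), numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_lt(mags[length(mags)], 1e-9 * mags[1])
  expect_error(chemotactic_drift(-1, g, p_base), "c_local")
})

test_that("field step: uniform decay, single-agent deposition, mass balance", {
  p <- p_base
  f0 <- matrix(2.5, 32, 32)
  f1 <- update_field(f0, NULL, p)
  expect_equal(f1, f0 * (1 - p$decay_rate * p$dt))

  z <- matrix(0, 32, 32)
  f2 <- update_field(z, matrix(c(10.4, 20.7), ncol = 2), p)
  expect_equal(sum(f2 > 0), 1L)
  expect_equal(f2[11, 21], p$secretion_rate * p$dt)

  # mass balance over repeated noisy steps
  set.seed(1)
  f <- matrix(runif(32 * 32), 32, 32)
  pos <- cbind(runif(57, 0, 32), runif(57, 0, 32))
  for (i in 1:20) {
    expected <- sum(f) * (1 - p$decay_rate * p$dt) + 57 * p$secretion_rate * p$dt
    f <- update_field(f, pos, p)
    expect_equal(sum(f), expected, tolerance = 1e-12)
    expect_true(all(f >= 0))
  }
})

test_that("with no secretion and no diffusion the field follows the decay closed form", {
  p <- sim_params(n_agents = 10, grid_size = 16, secretion_rate = 0, D_chem = 0)
  f <- matrix(3, 16, 16)
  for (n in 1:50) {
    f <- update_field(f, NULL, p)
    expect_equal(f[1, 1], 3 * (1 - p$decay_rate * p$dt)^n, tolerance = 1e-12)
  }
})

test_that("motility switch follows the four-state cycle", {
  p <- sim_params(n_agents = 1, grid_size = 16, c_star = 10,
                  t_refractory = 0.02, t_blind = 0.03, p_reactivate = 1)
  st <- motility_states()
  # below threshold: unchanged
  r <- step_motility_state(st["MOTILE"], 0, 5, p)
  expect_equal(unname(r$state), unname(st[["MOTILE"]]))
  # at/above threshold: immobilized with refractory clock
  r <- step_motility_state(st["MOTILE"], 0, 10, p)
  expect_equal(unname(r$state), unname(st[["IMMOTILE_FIXED"]]))
  expect_equal(unname(r$clock), 0.02)
  # refractory counts down in dt steps, then stochastic, then blind, then motile
  state <- r$state; clock <- r$clock
  seen <- c(state)
  for (i in 1:20) {
    r <- step_motility_state(state, clock, 50, p) # high c must not re-trigger
    state <- r$state; clock <- r$clock
    seen <- c(seen, state)
  }
  expect_equal(rle(seen)$values[1:5], c(1L, 2L, 3L, 0L, 1L)) # cycle in order
})

test_that("immotile episode durations match the geometric-wait expectation", {
  n <- 3000
  p <- sim_params(n_agents = n, grid_size = 16, t_refractory = 0.6,
                  p_reactivate = 0.01, t_blind = 0.5)
  set.seed(7)
  state <- rep(motility_states()[["IMMOTILE_FIXED"]], n)
  clock <- rep(p$t_refractory, n)
  left_at <- rep(NA_real_, n)
  step <- 0L
  while (anyNA(left_at) && step < 1e5) {
    step <- step + 1L
    r <- step_motility_state(state, clock, rep(0, n), p)
    newly_blind <- state != 3L & r$state == 3L
    left_at[newly_blind & is.na(left_at)] <- step * p$dt
    state <- r$state; clock <- r$clock
  }
  expected <- p$t_refractory + p$dt / p$p_reactivate
  expect_lt(abs(mean(left_at) - expected) / expected, 0.05)
})

test_that("position step: frozen limit and anchored immotile agents", {
  p <- sim_params(n_agents = 5, grid_size = 16, D_agent = 0, chi0 = 0,
                  r_agent = 0)
  pos <- cbind(runif(5, 0, 16), runif(5, 0, 16))
  expect_equal(unname(step_positions(pos, rep(0L, 5), matrix(1, 16, 16), p)),
               unname(pos))
  # strong gradient, immotile agents must not move
  p2 <- sim_params(n_agents = 5, grid_size = 16, D_agent = 1, chi0 = 50,
                   r_agent = 0.5)
  f <- outer(1:16, 1:16, function(i, j) i * 2.0)
  set.seed(2)
  newpos <- step_positions(pos, rep(1L, 5), f, p2)
  expect_equal(unname(newpos), unname(pos))
})

test_that("pure Brownian agents have MSD exponent 1 within 0.1", {
  p <- sim_params(n_agents = 200, grid_size = 64, t_final = 5, D_agent = 1,
                  chi0 = 0, c_star = 1e9, secretion_rate = 0,
                  snapshot_every = 20)
  sim <- run_simulation(p, seed = 11, keep_fields = FALSE)
  trajs <- unwrap_agent_tracks(sim, 1:200)
  fit <- msd_exponent(trajs, max_lag_fraction = 0.5)
  expect_lt(abs(fit$alpha - 1), 0.1)
})

test_that("runs conserve agents and are bit-identical under the same seed", {
  p <- sim_params(n_agents = 150, grid_size = 32, t_final = 0.5,
                  snapshot_every = 25)
  a <- run_simulation(p, seed = 5)
  b <- run_simulation(p, seed = 5)
  expect_true(all(vapply(a$snapshots, function(s) nrow(s$positions),
                         integer(1)) == 150L))
  expect_identical(a$snapshots, b$snapshots)
  c2 <- run_simulation(p, seed = 6)
  expect_false(identical(a$snapshots[[3]]$positions,
                         c2$snapshots[[3]]$positions))
})

test_that("scale calibration recovers the closed-form spatial factor", {
  set.seed(3)
  scn <- gen_planted_aggregates(n_clusters = 4, agents_per_cluster = 300,
                                cluster_radius = 3, n_free = 200,
                                grid_size = 96)
  snap1 <- list(time = 0, positions = scn$positions,
                state = rep(0L, nrow(scn$positions)))
  snap2 <- list(time = 1, positions = scn$positions + 0.5,
                state = rep(0L, nrow(scn$positions)))
  fake <- structure(list(params = sim_params(n_agents = nrow(scn$positions),
                                             grid_size = 96),
                         times = c(0, 1), snapshots = list(snap1, snap2)),
                    class = "spotdyn_sim")
  cal <- calibrate_scales(fake, reference_area_mm2 = 1.0,
                          reference_speed_mm_hr = 0.5, frames = 1:2)
  expect_equal(cal$mm_per_px, sqrt(1.0 / cal$mean_area_px2))
  # every motile agent moved by exactly sqrt(2)/2 px per unit time
  expect_equal(cal$mean_speed_px_per_tu, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cal$hr_per_time_unit,
               cal$mean_speed_px_per_tu * cal$mm_per_px / 0.5)
  # identity case: reference equal to measurement gives scale factor 1
  cal2 <- calibrate_scales(fake, reference_area_mm2 = cal$mean_area_px2,
                           reference_speed_mm_hr = cal$mean_speed_px_per_tu,
                           frames = 1:2)
  expect_equal(cal2$mm_per_px, 1)
  expect_equal(cal2$hr_per_time_unit, 1)
})
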