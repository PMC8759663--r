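## Core model dynamics. The heavy kernels live in src/; these wrappers carry
## the scientific contracts (receptor law, state cycle, stability checks) and
## are what run_simulation() composes each step.

#' Motility state codes
#'
#' Agents cycle `MOTILE -> IMMOTILE_FIXED -> IMMOTILE_STOCHASTIC -> BLIND ->
#' MOTILE`. Integer codes 0:3 in that order are used in snapshots and on disk.
#' @return named integer vector mapping state names to codes.
#' @export
motility_states <- function() {
  c(MOTILE = 0L, IMMOTILE_FIXED = 1L, IMMOTILE_STOCHASTIC = 2L, BLIND = 3L)
}

#' Receptor-law chemotactic drift
#'
#' Drift velocity of a motile agent in a chemoattractant field:
#' `v = chi0 * grad_c / (1 + c_local / c_half)^2`. The magnitude grows with
#' the gradient but saturates with the absolute concentration, modelling
#' receptor occupancy; it is non-increasing in `c_local` at fixed gradient
#' and vanishes as `c_local -> Inf`.
#'
#' @param c_local local concentration (scalar or length-n vector), >= 0.
#' @param grad_c gradient: length-2 vector or n x 2 matrix.
#' @param params a [sim_params()] object (uses `chi0`, `c_half`).
#' @return drift velocity, same shape as `grad_c`, px/time.
#' @export
chemotactic_drift <- function(c_local, grad_c, params) {
  if (any(!is.finite(c_local)) || any(c_local < 0))
    stop("c_local must be finite and >= 0")
  if (is.null(dim(grad_c))) grad_c <- matrix(grad_c, ncol = 2)
  sat <- (1 + c_local / params$c_half)^2
  v <- params$chi0 * grad_c / sat
  if (nrow(v) == 1L) drop(v) else v
}

#' One explicit chemoattractant field step
#'
#' Advances the field by one step: 5-point-stencil diffusion with periodic
#' wrap, multiplicative decay `(1 - decay_rate * dt)`, and deposition of
#' `secretion_rate * dt` into each agent's containing pixel. Periodic
#' diffusion conserves mass, so the total after a step equals
#' `previous_total * (1 - decay_rate * dt) + n_agents * secretion_rate * dt`.
#'
#' @param field square matrix of non-negative concentrations.
#' @param positions n x 2 matrix of agent positions (px), or NULL for none.
#' @param params a [sim_params()] object.
#' @return the updated field matrix.
#' @export
update_field <- function(field, positions, params) {
  validate_sim_params(params)
  if (is.null(positions) || NROW(positions) == 0L)
    positions <- matrix(numeric(0), ncol = 2)
  cpp_field_step(field, positions[, 1], positions[, 2],
                 params$D_chem, params$decay_rate, params$secretion_rate,
                 params$dt)
}

#' One motility-transition step
#'
#' Applies the three-phase motility switch to every agent, at most one
#' transition per agent per step:
#' * `MOTILE` with `c_local >= c_star` becomes `IMMOTILE_FIXED` with the
#'   refractory clock set to `t_refractory`;
#' * `IMMOTILE_FIXED` becomes `IMMOTILE_STOCHASTIC` when the clock expires;
#' * `IMMOTILE_STOCHASTIC` becomes `BLIND` with probability `p_reactivate`
#'   this step (clock set to `t_blind`);
#' * `BLIND` becomes `MOTILE` when the clock expires.
#'
#' Reactivation draws are made in fixed agent order from R's RNG, so runs
#' are reproducible under `set.seed()`.
#'
#' @param state integer vector of state codes (see [motility_states()]).
#' @param clock numeric vector of per-agent state clocks (time units).
#' @param c_local concentration at each agent's position.
#' @param params a [sim_params()] object.
#' @return list with updated `state` and `clock` vectors.
#' @export
step_motility_state <- function(state, clock, c_local, params) {
  cpp_motility_step(as.integer(state), as.numeric(clock),
                    as.numeric(c_local), params$c_star, params$t_refractory,
                    params$p_reactivate, params$t_blind, params$dt)
}

#' One position step (Euler-Maruyama plus finite-size repulsion)
#'
#' Motile agents move by receptor-law chemotactic drift (field and gradient
#' bilinearly interpolated at the agent position) plus Brownian noise
#' `sqrt(2 * D_agent * dt)` per axis; blind agents move by the Brownian term
#' only; immotile agents never move. A pairwise soft repulsion then separates
#' pairs closer than `r_agent` (the finite-size rule), displacing only the
#' motile/blind member(s) so that immotile agents remain anchored. Positions
#' are wrapped into the periodic domain.
#'
#' @param positions n x 2 matrix of positions (px).
#' @param state integer state codes.
#' @param field chemoattractant matrix.
#' @param params a [sim_params()] object.
#' @return updated n x 2 position matrix.
#' @export
step_positions <- function(positions, state, field, params) {
  res <- cpp_position_step(positions[, 1], positions[, 2], as.integer(state),
                           field, params$D_agent, params$chi0, params$c_half,
                           params$dt, as.numeric(params$grid_size),
                           params$r_agent)
  cbind(x = res$x, y = res$y)
}

#' Run the agent-based aggregation model
#'
#' Initializes `n_agents` motile agents uniformly at random on the periodic
#' grid with a zero chemoattractant field, then iterates (field update,
#' motility-state update, position update) with step `dt` until `t_final`,
#' recording a snapshot every `snapshot_every` steps (plus the initial
#' state). Identical `(params, seed)` give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param keep_fields logical; store the field matrix in every snapshot
#'   (default TRUE). With many snapshots of a large grid this dominates
#'   memory; when FALSE only the final field is kept.
#' @param progress logical; print occasional progress lines.
#' @return An object of class `spotdyn_sim`: list with `params`, `seed`,
#'   `times`, and `snapshots`, each snapshot a list with `time`, `positions`
#'   (n x 2), `state`, and (optionally) `field`.
#' @examples
#' p <- sim_params(n_agents = 200, grid_size = 32, t_final = 0.5,
#'                 snapshot_every = 50)
#' sim <- run_simulation(p, seed = 1)
#' length(sim$snapshots)
#' @export
run_simulation <- function(params, seed = NULL, keep_fields = TRUE,
                           progress = FALSE) {
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_agents
  L <- as.numeric(params$grid_size)
  pos <- cbind(x = runif(n, 0, L), y = runif(n, 0, L))
  state <- rep.int(0L, n)
  clock <- numeric(n)
  field <- matrix(0, params$grid_size, params$grid_size)
  n_steps <- as.integer(round(params$t_final / params$dt))
  snaps <- list()
  record <- function(step_idx) {
    s <- list(time = step_idx * params$dt, positions = pos, state = state)
    if (keep_fields) s$field <- field
    snaps[[length(snaps) + 1L]] <<- s
  }
  record(0L)
  for (step in seq_len(n_steps)) {
    field <- update_field(field, pos, params)
    c_loc <- cpp_interp_field(field, pos[, 1], pos[, 2])
    ms <- step_motility_state(state, clock, c_loc, params)
    state <- ms$state
    clock <- ms$clock
    pos <- step_positions(pos, state, field, params)
    if (step %% params$snapshot_every == 0L) {
      if (!all(is.finite(field)) || !all(is.finite(pos)))
        stop(sprintf("non-finite field or position at step %d (t = %g)",
                     step, step * params$dt))
      record(step)
      if (progress)
        message(sprintf("t = %.2f / %g  motile fraction %.2f",
                        step * params$dt, params$t_final, mean(state == 0L)))
    }
  }
  out <- list(params = params, seed = seed,
              times = vapply(snaps, `[[`, numeric(1), "time"),
              snapshots = snaps, final_field = field)
  class(out) <- "spotdyn_sim"
  out
}

#' @export
print.spotdyn_sim <- function(x, ...) {
  ns <- length(x$snapshots)
  cat(sprintf("spotdyn simulation: %d agents, %d x %d grid, %d snapshots (t = %g .. %g)\n",
              x$params$n_agents, x$params$grid_size, x$params$grid_size,
              ns, x$times[1], x$times[ns]))
  cat(sprintf("  final motile fraction: %.3f\n", motile_fraction(x)[ns]))
  invisible(x)
}

#' Fraction of motile agents per snapshot
#'
#' Counts both `MOTILE` and `BLIND` agents as motile (both are moving);
#' `strict = TRUE` counts only `MOTILE`.
#' @param sim a `spotdyn_sim` object.
#' @param strict logical, see above.
#' @return numeric vector, one value per snapshot.
#' @export
motile_fraction <- function(sim, strict = FALSE) {
  vapply(sim$snapshots, function(s) {
    if (strict) mean(s$state == 0L) else mean(s$state == 0L | s$state == 3L)
  }, numeric(1))
}

#' Calibrate physical scales of a simulation
#'
#' Sets the spatial scale by equating the mean segmented aggregate area of
#' the simulation with a reference area, and the time scale by equating the
#' mean motile-agent speed with a reference speed:
#' `mm_per_px = sqrt(reference_area_mm2 / mean_area_px2)` and
#' `hr_per_time_unit` chosen so the measured mean motile speed, expressed in
#' mm/hr, equals `reference_speed_mm_hr`. Motile speed is measured as the
#' mean per-snapshot-interval displacement of agents that are motile in both
#' of a pair of consecutive snapshots.
#'
#' @param sim a `spotdyn_sim` object with at least 2 snapshots.
#' @param reference_area_mm2 reference mean aggregate area, mm^2.
#' @param reference_speed_mm_hr reference mean single-cell speed, mm/hr.
#' @param radius,count_threshold,min_area segmentation settings passed to
#'   [local_density_map()] / [segment_aggregates()].
#' @param frames snapshot indices to segment (default: the last quarter).
#' @return list with `mm_per_px`, `hr_per_time_unit`, the measured
#'   `mean_area_px2` and `mean_speed_px_per_tu`.
#' @export
calibrate_scales <- function(sim, reference_area_mm2, reference_speed_mm_hr,
                             radius = 3, count_threshold = 40, min_area = 10,
                             frames = NULL) {
  ns <- length(sim$snapshots)
  if (ns < 2L) stop("calibration needs at least two snapshots")
  if (is.null(frames)) frames <- seq.int(max(1L, ns - ns %/% 4L), ns)
  areas <- unlist(lapply(frames, function(f) {
    dm <- local_density_map(sim$snapshots[[f]]$positions, radius = radius,
                            grid_size = sim$params$grid_size)
    det <- segment_aggregates(dm, count_threshold = count_threshold,
                              min_area = min_area)
    det$area
  }))
  if (length(areas) == 0L)
    stop("no aggregates segmented in the selected snapshots; cannot calibrate")
  mean_area <- mean(areas)
  mm_per_px <- sqrt(reference_area_mm2 / mean_area)

  disp <- numeric(0)
  L <- as.numeric(sim$params$grid_size)
  for (f in frames[-1]) {
    a <- sim$snapshots[[f - 1L]]
    b <- sim$snapshots[[f]]
    mot <- a$state == 0L & b$state == 0L
    if (!any(mot)) next
    dx <- wrap_diff(b$positions[mot, 1] - a$positions[mot, 1], L)
    dy <- wrap_diff(b$positions[mot, 2] - a$positions[mot, 2], L)
    disp <- c(disp, sqrt(dx^2 + dy^2) / (b$time - a$time))
  }
  if (length(disp) == 0L) stop("no motile agents found; cannot calibrate time")
  mean_speed <- mean(disp) # px per time unit
  hr_per_tu <- mean_speed * mm_per_px / reference_speed_mm_hr
  list(mm_per_px = mm_per_px, hr_per_time_unit = hr_per_tu,
       mean_area_px2 = mean_area, mean_speed_px_per_tu = mean_speed)
}

# minimum-image signed difference on a periodic interval of length L
wrap_diff <- function(d, L) {
  d - L * round(d / L)
}
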