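#' Simulation parameters
#'
#' Builds and validates the full parameter set of the agent-based aggregation
#' model. Lengths are in grid pixels, time in internal simulation time units;
#' the mapping to millimetres and hours is established afterwards with
#' [calibrate_scales()]. The defaults are the package's control parameter set:
#' they produce aggregate formation with a persistent motile fraction and
#' experiment-like relative spot size and spacing after calibration.
#'
#' The explicit chemoattractant diffusion step is only stable when
#' `D_chem * dt <= 0.25` (pixel spacing is 1); violations are rejected here
#' rather than surfacing as numerical blow-up mid-run.
#'
#' @param n_agents number of agents (cells); constant over a run.
#' @param grid_size pixels per side of the square periodic domain.
#' @param dt time step, time units.
#' @param t_final final time, time units.
#' @param D_agent agent diffusion coefficient, px^2/time.
#' @param D_chem chemoattractant diffusion coefficient, px^2/time.
#' @param secretion_rate chemoattractant deposited per agent per unit time.
#' @param decay_rate first-order chemoattractant decay rate, 1/time.
#' @param chi0 chemotactic sensitivity coefficient.
#' @param c_half receptor-saturation concentration of the receptor law.
#' @param c_star concentration threshold that triggers immobilization.
#' @param t_refractory fixed immotile interval after immobilization, time
#'   units (calibrated against 3 min of wall clock).
#' @param p_reactivate per-step probability of regaining motility once the
#'   refractory interval has expired (calibrated so the expected stochastic
#'   wait `dt / p_reactivate` corresponds to 30 min).
#' @param t_blind gradient-blind Brownian interval after reactivation, time
#'   units (calibrated against 15 min).
#' @param r_agent finite-size interaction radius for the pairwise soft
#'   repulsion, px (0 disables it).
#' @param snapshot_every number of steps between recorded snapshots.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [run_simulation()], [read_sim_config()]
#' @examples
#' p <- sim_params(n_agents = 500, grid_size = 64, t_final = 1)
#' p$dt
#' @export
sim_params <- function(n_agents = 100000L,
                       grid_size = 384L,
                       dt = 0.005,
                       t_final = 2000,
                       D_agent = 1.0,
                       D_chem = 10.0,
                       secretion_rate = 1.0,
                       decay_rate = 0.05,
                       chi0 = 25.0,
                       c_half = 15.0,
                       c_star = 30.0,
                       t_refractory = 0.6,
                       p_reactivate = 0.005 / 6,
                       t_blind = 3.0,
                       r_agent = 0.25,
                       snapshot_every = 1000L) {
  p <- list(n_agents = as.integer(n_agents), grid_size = as.integer(grid_size),
            dt = dt, t_final = t_final, D_agent = D_agent, D_chem = D_chem,
            secretion_rate = secretion_rate, decay_rate = decay_rate,
            chi0 = chi0, c_half = c_half, c_star = c_star,
            t_refractory = t_refractory, p_reactivate = p_reactivate,
            t_blind = t_blind, r_agent = r_agent,
            snapshot_every = as.integer(snapshot_every))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_agents >= 1L, p$grid_size >= 4L, p$dt > 0, p$t_final > 0,
            p$snapshot_every >= 1L)
  nonneg <- c("D_agent", "D_chem", "secretion_rate", "decay_rate", "chi0",
              "c_half", "c_star", "t_refractory", "t_blind", "r_agent")
  for (f in nonneg) {
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop(sprintf("parameter '%s' must be finite and >= 0", f))
  }
  if (p$p_reactivate < 0 || p$p_reactivate > 1)
    stop("p_reactivate must lie in [0, 1]")
  if (p$D_chem * p$dt > 0.25)
    stop(sprintf(paste0("explicit diffusion is unstable: D_chem * dt = %.4g ",
                        "exceeds the stability bound 0.25 px^2"),
                 p$D_chem * p$dt))
  if (p$decay_rate * p$dt >= 1)
    stop("decay_rate * dt must be < 1 for the multiplicative decay step")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Agent-based aggregation model parameters\n")
  cat(sprintf("  agents: %d on a %d x %d periodic grid\n",
              x$n_agents, x$grid_size, x$grid_size))
  cat(sprintf("  time: dt = %g, t_final = %g (%d steps), snapshot every %d steps\n",
              x$dt, x$t_final, as.integer(round(x$t_final / x$dt)),
              x$snapshot_every))
  cat(sprintf("  motion: D_agent = %g, chi0 = %g, c_half = %g, r_agent = %g\n",
              x$D_agent, x$chi0, x$c_half, x$r_agent))
  cat(sprintf("  field: D_chem = %g, secretion = %g, decay = %g\n",
              x$D_chem, x$secretion_rate, x$decay_rate))
  cat(sprintf("  motility switch: c* = %g, t_refractory = %g, p_reactivate = %g, t_blind = %g\n",
              x$c_star, x$p_reactivate, x$t_refractory, x$t_blind))
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Plain-text `key = value` files whose keys mirror the [sim_params()]
#' argument names exactly. Lines starting with `#` and blank lines are
#' ignored. Unknown keys are an error (they are almost always typos).
#'
#' @param path file path.
#' @param params a `sim_params` object (for writing).
#' @return `read_sim_config()` returns a validated `sim_params` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  known <- names(formals(sim_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyNA(vals)) stop("non-numeric config value(s)")
  do.call(sim_params, as.list(setNames(vals, keys)))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  lines <- sprintf("%s = %.17g", names(unclass(params)),
                   as.numeric(unlist(unclass(params))))
  writeLines(c("# spotdyn simulation configuration", lines), path)
  invisible(path)
}
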