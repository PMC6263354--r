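#' Simulation configuration for circuit dynamics
#'
#' Each gate's output promoter activity `y` relaxes toward its
#' steady-state response with first-order kinetics,
#' `dy/dt = alpha * P(x(t)) - gamma * (y - y_min)`,
#' where `P` is the x-dependent production part of the gate's steady-state
#' response (for repressor gates,
#' `(y_max - y_min) * K^n / (K^n + x(t)^n)`; the same
#' alpha-production / gamma-relaxation structure is applied to the AND and
#' ANDN response surfaces) and `alpha` and `gamma` are the rate constants
#' for turning a gate on and off (both 1 per hour by default).
#'
#' The system is integrated with a fixed step (default explicit Euler at
#' `dt = 0.025` h over a 27-h horizon, mirroring the discrete reference
#' solution; a classical Runge-Kutta integrator is offered for
#' verification). Initial gate states are the steady-state solution at
#' `init_sensor_values`; the shipped defaults store the published
#' initialization (x1 = 1.294, x2 = 0.006, x3 = 0.028 RPU) verbatim.
#'
#' @param t_start,t_end simulation window (hours).
#' @param dt time step (hours), > 0.
#' @param alpha,gamma gate on/off rate constants (1/h), > 0.
#' @param integrator `"euler"` or `"rk4"`.
#' @param init_sensor_values named sensor wire activities (RPU) used to
#'   compute initial gate states.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_start = 0, t_end = 27, dt = 0.025,
                       alpha = 1, gamma = 1,
                       integrator = c("euler", "rk4"),
                       init_sensor_values = c(x1 = 1.294, x2 = 0.006,
                                              x3 = 0.028)) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (alpha <= 0 || gamma <= 0) stop("alpha and gamma must be > 0")
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 alpha = alpha, gamma = gamma, integrator = integrator,
                 init_sensor_values = init_sensor_values),
            class = "sim_config")
}

#' Right-hand side of a gate's ODE
#'
#' `dy/dt = alpha * P(x) - gamma * (y - y_min)` where `P(x)` is the
#' x-dependent production part of the gate's steady-state response. With
#' `alpha = gamma` and constant inputs the fixed point is exactly the
#' steady-state response function.
#'
#' @param g a [gate()].
#' @param xs list of input values at time t (RPU).
#' @param y current gate output (RPU, >= 0).
#' @param cfg a [sim_config()] providing `alpha` and `gamma`.
#' @return `dy/dt` in RPU/h.
#' @export
gate_rhs <- function(g, xs, y, cfg = sim_config()) {
  cfg$alpha * gate_production(g, xs) - cfg$gamma * (y - g$params$y_min)
}

#' Steady-state initialization of gate outputs
#'
#' Solves the gate ODE system at steady state by topological substitution:
#' each gate's fixed point is `y = y_min + (alpha/gamma) * P(x)` with its
#' inputs already at their fixed points. With `alpha = gamma` this equals
#' [circuit_steady_state()] at the initial sensor values.
#'
#' @param circ a [circuit()].
#' @param cfg a [sim_config()]; its `init_sensor_values` must cover every
#'   sensor wire of the circuit (by name, or positionally when the counts
#'   agree).
#' @return Named numeric vector of initial gate outputs (RPU).
#' @export
steady_state_init <- function(circ, cfg = sim_config()) {
  stopifnot(inherits(circ, "circuit"), inherits(cfg, "sim_config"))
  sv <- cfg$init_sensor_values
  if (!all(circ$inputs %in% names(sv))) {
    if (length(sv) == length(circ$inputs)) {
      names(sv) <- circ$inputs
    } else {
      stop("init_sensor_values missing wire(s): ",
           paste(setdiff(circ$inputs, names(sv)), collapse = ", "))
    }
  }
  wires <- sv[circ$inputs]
  ratio <- cfg$alpha / cfg$gamma
  for (g in circ$gates) {
    xs <- as.list(unname(wires[g$inputs]))
    wires[g$id] <- g$params$y_min + ratio * gate_production(g, xs)
  }
  wires[vapply(circ$gates, function(g) g$id, character(1))]
}

#' Simulate circuit dynamics under time-varying sensor inputs
#'
#' Fixed-step integration of the gate ODE system from its steady-state
#' initialization. Sensor wires are linearly interpolated from their time
#' courses at every step (terminal values held beyond the sampled range);
#' every gate trajectory is sampled at every step. Deterministic for a
#' given configuration.
#'
#' @param circ a [circuit()].
#' @param sensor_tcs named list of [time_course()] objects, one per sensor
#'   wire.
#' @param cfg a [sim_config()].
#' @return Named list of [time_course()] objects, one per gate, sampled at
#'   every integration step.
#' @export
simulate_circuit <- function(circ, sensor_tcs, cfg = sim_config()) {
  stopifnot(inherits(circ, "circuit"))
  missing <- setdiff(circ$inputs, names(sensor_tcs))
  if (length(missing))
    stop("no time course for sensor wire(s): ",
         paste(missing, collapse = ", "))
  span <- cfg$t_end - cfg$t_start
  if (cfg$dt >= span) stop("dt must be smaller than the simulated span")

  times <- seq(cfg$t_start, cfg$t_end, by = cfg$dt)
  gate_ids <- vapply(circ$gates, function(g) g$id, character(1))
  ng <- length(gate_ids)

  # pre-sample sensor inputs at step times (and half steps for rk4)
  sens_at <- function(t) {
    v <- vapply(circ$inputs, function(w) tc_interpolate(sensor_tcs[[w]], t),
                numeric(1))
    names(v) <- circ$inputs
    v
  }

  y <- steady_state_init(circ, cfg)
  traj <- matrix(NA_real_, nrow = length(times), ncol = ng,
                 dimnames = list(NULL, gate_ids))
  if (ng == 0L) return(list())
  traj[1L, ] <- y

  deriv <- function(t, y) {
    wires <- c(sens_at(t), y)
    d <- numeric(ng)
    names(d) <- gate_ids
    for (g in circ$gates) {
      xs <- as.list(unname(wires[g$inputs]))
      d[g$id] <- gate_rhs(g, xs, wires[[g$id]], cfg)
    }
    d
  }

  neg_seen <- FALSE
  for (i in seq_len(length(times) - 1L)) {
    t <- times[i]
    h <- times[i + 1L] - t
    if (cfg$integrator == "euler") {
      y <- y + h * deriv(t, y)
    } else {
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(y)))
      stop(sprintf("NaN at step %d (t = %.3f h) in gate '%s'", i,
                   times[i + 1L], gate_ids[which(!is.finite(y))[1L]]))
    if (any(y < 0)) {
      if (!neg_seen) {
        warning("negative transient clamped at 0 (gate '",
                gate_ids[which(y < 0)[1L]], "')")
        neg_seen <- TRUE
      }
      y <- pmax(y, 0)
    }
    traj[i + 1L, ] <- y
  }

  out <- lapply(gate_ids, function(id) time_course(times, traj[, id],
                                                   name = id))
  names(out) <- gate_ids
  out
}

#' Write a simulation run to disk
#'
#' Writes one time-course CSV for the run plus a JSON run manifest echoing
#' the configuration (see [write_run_manifest()]).
#'
#' @param traj named list of [time_course()] objects from
#'   [simulate_circuit()].
#' @param cfg the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest (circuit simulation itself is
#'   deterministic).
#' @return The run directory, invisibly.
#' @export
write_simulation_run <- function(traj, cfg, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "trajectories.csv")
  write_timecourse_csv(traj, csv)
  write_run_manifest(
    file.path(dir, "manifest.json"),
    command = "simulate",
    config = unclass(cfg),
    seed = seed,
    inputs = csv)
  invisible(dir)
}
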