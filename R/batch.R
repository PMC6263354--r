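#' Batch fermentation parameters
#'
#' Phenomenological model of a glucose-limited batch culture: Monod growth,
#' yield-coupled glucose consumption, quasi-static dissolved oxygen with a
#' biomass-proportional demand, and overflow acetate produced
#' proportionally to biomass while glucose remains. The shipped defaults
#' are calibrated so that glucose is exhausted near 15 h, dissolved oxygen
#' crosses the oxygen sensor's half-maximum (36 umol/l) near 8 h, and
#' acetate crosses 15 mM near 14 h.
#'
#' @param X0 initial biomass (OD units).
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_s Monod constant (% glucose).
#' @param Y_xs biomass yield (OD per % glucose).
#' @param glucose0 initial glucose (%, typical 0.4 / 0.8 / 1.6).
#' @param q_ac overflow acetate production (mM per OD per h) while glucose
#'   remains; no acetate consumption phase is modeled.
#' @param o2_demand oxygen demand coefficient (umol/l per unit
#'   `(mu + m_o2) * X`).
#' @param m_o2 maintenance respiration rate (1/h): oxygen demand that
#'   persists at zero growth, keeping DO depressed after glucose
#'   exhaustion (stationary-phase cultures keep respiring).
#' @param kla gas-transfer relaxation rate (1/h); large values make DO
#'   quasi-static.
#' @param DO_sat oxygen saturation (umol/l; 100% DO calibration point).
#' @param DO_floor lowest reliably measurable DO (umol/l); trajectories are
#'   clipped here.
#' @return An object of class `batch_params`.
#' @export
batch_params <- function(X0 = 0.05, mu_max = 0.31, K_s = 0.02, Y_xs = 3,
                         glucose0 = 1.6, q_ac = 1.4, o2_demand = 940,
                         m_o2 = 0.05, kla = 10, DO_sat = 210,
                         DO_floor = 20) {
  vals <- c(X0, mu_max, K_s, Y_xs, q_ac, o2_demand, m_o2, kla, DO_sat,
            DO_floor)
  if (any(vals <= 0)) stop("all batch parameters must be positive")
  if (glucose0 < 0) stop("glucose0 must be >= 0")
  structure(list(X0 = X0, mu_max = mu_max, K_s = K_s, Y_xs = Y_xs,
                 glucose0 = glucose0, q_ac = q_ac, o2_demand = o2_demand,
                 m_o2 = m_o2, kla = kla, DO_sat = DO_sat,
                 DO_floor = DO_floor),
            class = "batch_params")
}

#' Simulate batch-growth stimulus trajectories
#'
#' Fixed-step integration of
#' `dX/dt = mu_max * G/(K_s + G) * X`,
#' `dG/dt = -(1/Y_xs) * mu * X`,
#' `dDO/dt = kla * (DO_sat - o2_demand * (mu + m_o2) * X - DO)` (clipped
#' at `DO_floor`), and `dA/dt = q_ac * X` while glucose remains (overflow
#' production stops once G falls below a trace threshold of 1e-4 %,
#' since Monod consumption only reaches zero asymptotically).
#'
#' @param p a [batch_params()].
#' @param t_end simulated span (h).
#' @param dt integration step (h).
#' @return Named list of [time_course()] objects: `biomass` (OD),
#'   `glucose` (%), `DO` (umol/l), `acetate` (mM).
#' @export
simulate_batch <- function(p = batch_params(), t_end = 27, dt = 0.01) {
  stopifnot(inherits(p, "batch_params"))
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  X <- G <- DO <- A <- numeric(n)
  X[1] <- p$X0; G[1] <- p$glucose0; DO[1] <- p$DO_sat; A[1] <- 0
  for (i in seq_len(n - 1L)) {
    mu <- p$mu_max * G[i] / (p$K_s + G[i])
    dX <- mu * X[i]
    dG <- -dX / p$Y_xs
    do_target <- p$DO_sat - p$o2_demand * (mu + p$m_o2) * X[i]
    dDO <- p$kla * (do_target - DO[i])
    dA <- if (G[i] > 1e-4) p$q_ac * X[i] else 0
    X[i + 1] <- X[i] + dt * dX
    G[i + 1] <- max(G[i] + dt * dG, 0)
    DO[i + 1] <- max(DO[i] + dt * dDO, p$DO_floor)
    A[i + 1] <- A[i] + dt * dA
    if (X[i + 1] < 0 || !all(is.finite(c(X[i + 1], G[i + 1], DO[i + 1],
                                         A[i + 1]))))
      stop(sprintf("negative or non-finite state at t = %.3f h; reduce dt",
                   times[i + 1]))
  }
  list(biomass = time_course(times, X, "biomass"),
       glucose = time_course(times, G, "glucose"),
       DO = time_course(times, DO, "DO"),
       acetate = time_course(times, A, "acetate"))
}

#' First crossing time of a time course
#'
#' Linearly interpolated time at which a trajectory first crosses a
#' threshold in the given direction.
#'
#' @param tc a [time_course()].
#' @param threshold threshold value.
#' @param direction `"down"` (first time value <= threshold) or `"up"`
#'   (first time value >= threshold).
#' @return Crossing time (h), or `NA` if never crossed.
#' @export
crossing_time <- function(tc, threshold, direction = c("down", "up")) {
  direction <- match.arg(direction)
  v <- if (direction == "down") -tc$values else tc$values
  thr <- if (direction == "down") -threshold else threshold
  idx <- which(v >= thr)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(tc$times[1L])
  # linear interpolation between samples i-1 and i
  f <- (thr - v[i - 1L]) / (v[i] - v[i - 1L])
  tc$times[i - 1L] + f * (tc$times[i] - tc$times[i - 1L])
}

#' Map batch stimuli through the sensors onto RPU wires
#'
#' Applies each sensor's transfer function pointwise to its stimulus
#' trajectory (glucose %, dissolved oxygen, acetate mM) and rescales the
#' normalized output onto the sensor's measured RPU range
#' `[rpu_min, rpu_max]`.
#'
#' @param sensors named list of three [hill_sensor()] objects (`glucose`,
#'   `oxygen`, `acetate`), e.g. [default_sensors()].
#' @param batch output of [simulate_batch()].
#' @param cal a [sensor_calibration()].
#' @return Named list of [time_course()] objects (`glucose`, `oxygen`,
#'   `acetate`) in RPU.
#' @export
sensor_outputs_from_batch <- function(sensors = default_sensors(),
                                      batch = simulate_batch(),
                                      cal = sensor_calibration()) {
  stimuli <- list(glucose = batch$glucose, oxygen = batch$DO,
                  acetate = batch$acetate)
  out <- lapply(names(stimuli), function(nm) {
    sn <- sensors[[nm]]
    tc <- stimuli[[nm]]
    y <- sensor_response(sn, tc$values)
    frac <- (y - sn$y_min) / (sn$y_max - sn$y_min)
    rpu <- cal$rpu_min[[nm]] + frac * (cal$rpu_max[[nm]] - cal$rpu_min[[nm]])
    time_course(tc$times, rpu, name = nm)
  })
  names(out) <- names(stimuli)
  out
}

#' Sensor wire state of the inoculum culture
#'
#' The inoculum is grown without glucose, aerobically and without acetate,
#' so at t = 0 the glucose and acetate wires sit at their minimal RPU and
#' the (depletion-activating) oxygen wire is also off. Used to initialize
#' gate states for end-to-end batch simulations.
#'
#' @param cal a [sensor_calibration()].
#' @param wires names to give the three wires, in the order glucose,
#'   oxygen, acetate.
#' @return Named numeric vector of RPU values.
#' @export
inoculum_sensor_values <- function(cal = sensor_calibration(),
                                   wires = c("glucose", "oxygen",
                                             "acetate")) {
  stats::setNames(c(cal$rpu_min[["glucose"]], cal$rpu_min[["oxygen"]],
                    cal$rpu_min[["acetate"]]), wires)
}

#' Reference dose grids for sensor characterization
#'
#' Twelve-level dose series spanning each sensor's physiological stimulus
#' range (glucose 0-1.6%, dissolved oxygen 0-210 umol/l = saturation,
#' acetate 0-100 mM), designed for dose-response recovery: the activating
#' sensors use a zero dose (which pins the off state) plus a log-spaced
#' ladder through the transition; the depletion-activating oxygen sensor
#' uses a design weighted toward high DO, where its off state lives.
#'
#' @param sensor_name `"glucose"`, `"oxygen"` or `"acetate"`.
#' @return Numeric vector of 12 doses.
#' @export
reference_dose_grid <- function(sensor_name = c("glucose", "oxygen",
                                                "acetate")) {
  sensor_name <- match.arg(sensor_name)
  switch(sensor_name,
    glucose = c(0, exp(seq(log(0.005), log(1.6), length.out = 11))),
    oxygen = c(0, 1, 2, 24, 33, 52, 75, 88, 97, 190, 200, 210),
    acetate = c(0, exp(seq(log(0.7), log(100), length.out = 11))))
}

#' Generate noisy synthetic dose-response data
#'
#' Samples a sensor's Hill response at the given doses and perturbs each
#' replicate with multiplicative lognormal noise of the stated coefficient
#' of variation. Seeded and reproducible.
#'
#' @param sensor a [hill_sensor()].
#' @param doses dose vector (ascending, >= 0).
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   >= 0.
#' @param n_rep replicates per dose.
#' @param seed RNG seed.
#' @return A [dose_response()].
#' @export
generate_dose_response <- function(sensor, doses, noise_cv = 0.05,
                                   n_rep = 3, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  mu <- sensor_response(sensor, doses)
  resp <- withr_seed(seed, {
    if (noise_cv == 0) {
      matrix(rep(mu, n_rep), ncol = n_rep)
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(stats::rlnorm(length(mu) * n_rep,
                                    meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      ncol = n_rep)
      mu * noise
    }
  })
  dose_response(doses, resp)
}

#' Generate a lognormal cytometry-like population
#'
#' Samples `n_cells` lognormal values with the requested median and
#' coefficient of variation, standing in for a gated population
#' fluorescence histogram.
#'
#' @param median target population median (a.u.), > 0.
#' @param cv coefficient of variation, >= 0 (0 gives constant samples).
#' @param n_cells number of cells, >= 1.
#' @param seed RNG seed.
#' @return Numeric vector of samples.
#' @export
generate_population <- function(median, cv = 0.4, n_cells = 1e4,
                                seed = 1L) {
  if (median <= 0) stop("median must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (cv == 0) return(rep(median, n_cells))
  sdlog <- sqrt(log(1 + cv^2))
  withr_seed(seed, stats::rlnorm(n_cells, meanlog = log(median),
                                 sdlog = sdlog))
}

#' Recover sensor parameters from replicated synthetic dose-responses
#'
#' Runs the full parameter-recovery exercise for one sensor: generate a
#' noisy synthetic dose-response from the reference sensor model
#' ([reference_dose_grid()] doses, 3 replicates, 5% CV), fit it with
#' [fit_hill()], and read off the recovered half-maximum point and dynamic
#' range. The exercise is replicated over `n_datasets` independently
#' seeded datasets and summarized by the median, since a single noise
#' draw at these measurement conditions carries sampling error comparable
#' to the quantities' tolerances; the recovery fits hold the Hill slope at
#' the generating model's unit value (see `fix_n` in [fit_hill()]).
#'
#' @param sensor_name `"glucose"`, `"oxygen"` or `"acetate"`.
#' @param seed base seed; dataset i uses `seed + i - 1`.
#' @param n_datasets replicated synthetic datasets (default 11).
#' @param noise_cv,n_rep measurement noise CV and replicate count.
#' @return List with `ec50`, `fold` (medians over datasets), the
#'   generating `sensor`, and per-dataset vectors `ec50_all`, `fold_all`.
#' @export
recover_sensor_parameters <- function(sensor_name, seed = 1L,
                                      n_datasets = 11L, noise_cv = 0.05,
                                      n_rep = 3L) {
  sensor <- default_sensors()[[sensor_name]]
  if (is.null(sensor)) stop("unknown sensor: ", sensor_name)
  doses <- reference_dose_grid(sensor_name)
  ec <- fold <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    dr <- generate_dose_response(sensor, doses, noise_cv = noise_cv,
                                 n_rep = n_rep, seed = seed + i - 1L)
    f <- fit_hill(dr, mode = sensor$mode, fix_n = 1)
    ec[i] <- f$estimates[["ec50"]]
    fold[i] <- f$estimates[["y_max"]] / f$estimates[["y_min"]]
  }
  list(ec50 = stats::median(ec), fold = stats::median(fold),
       sensor = sensor, ec50_all = ec, fold_all = fold)
}

#' Recover knockdown folds from synthetic cytometry populations
#'
#' Calibrates a single mechanism to a target steady-state fold
#' ([calibrate_knockdown()]), simulates the knockdown to steady state,
#' draws lognormal populations (CV 0.4, 10^4 cells) around the uninduced
#' and induced steady-state protein levels, and estimates the fold as the
#' ratio of population medians ([estimate_fold()]).
#'
#' @param target_fold the fold the mechanism is calibrated to.
#' @param mechanism `"crispri"`, `"srna"` or `"protease"`.
#' @param seed RNG seed for the populations.
#' @param n_cells,cv population size and coefficient of variation.
#' @param p an [expression_params()].
#' @return List with `fold` (estimated), `ci`, `config`, and the
#'   steady-state levels `pre` and `post`.
#' @export
recover_knockdown_fold <- function(target_fold,
                                   mechanism = c("crispri", "srna",
                                                 "protease"),
                                   seed = 1L, n_cells = 1e4, cv = 0.4,
                                   p = expression_params()) {
  mechanism <- match.arg(mechanism)
  k <- calibrate_knockdown(target_fold, mechanism, p)
  # steady-state protein levels before and after induction: take the
  # simulated trajectory's start and its long-time limit
  horizon <- k$induction_time + 12 / min(p$d_m, p$d_p)
  fastest <- max(p$d_m + k$srna_extra_decay,
                 p$d_p + k$protease_extra_decay)
  tc <- simulate_knockdown(p, k, horizon = horizon,
                           dt = min(0.025, 0.2 / fastest))
  pre_level <- tc$values[1L]
  post_level <- tc$values[length(tc$values)]
  pre <- generate_population(pre_level, cv = cv, n_cells = n_cells,
                             seed = seed)
  post <- generate_population(post_level, cv = cv, n_cells = n_cells,
                              seed = seed + 1L)
  est <- estimate_fold(pre, post, seed = seed + 2L)
  list(fold = est$fold, ci = est$ci, config = k,
       pre = pre_level, post = post_level)
}

#' Run the full batch-to-circuit pipeline
#'
#' Convenience wrapper: simulates the default batch culture, maps the
#' stimuli through the three sensors onto RPU wires, and integrates a
#' circuit over those wires with gates initialized from the inoculum
#' sensor state.
#'
#' @param circ a three-input [circuit()] whose inputs are named
#'   `glucose`, `oxygen`, `acetate` (default: [pulse_circuit()]).
#' @param p a [batch_params()].
#' @param sensors sensor list as in [sensor_outputs_from_batch()].
#' @param cal a [sensor_calibration()].
#' @param cfg a [sim_config()]; its `init_sensor_values` are replaced by
#'   the inoculum state.
#' @return List with `batch`, `wires` and `trajectories`.
#' @export
run_batch_pipeline <- function(circ = pulse_circuit(),
                               p = batch_params(),
                               sensors = default_sensors(),
                               cal = sensor_calibration(),
                               cfg = sim_config()) {
  batch <- simulate_batch(p, t_end = cfg$t_end)
  wires <- sensor_outputs_from_batch(sensors, batch, cal)
  cfg$init_sensor_values <- inoculum_sensor_values(cal, circ$inputs)
  traj <- simulate_circuit(circ, stats::setNames(wires, circ$inputs), cfg)
  list(batch = batch, wires = wires, trajectories = traj)
}
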