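#' Hill sensor transfer function
#'
#' A phenomenological sensor is described by a four-parameter Hill function:
#' minimal output `y_min`, maximal output `y_max`, half-maximum stimulus
#' `ec50` and Hill coefficient `hill_n`. Two modes are supported:
#' `"activating"` (output rises with stimulus; glucose and acetate sensors)
#' and `"depletion_activating"` (output rises as the stimulus is depleted;
#' the low-oxygen sensor, whose stimulus axis is dissolved oxygen).
#'
#' @param name sensor name.
#' @param y_min,y_max minimal and maximal output (RPU or arbitrary
#'   fluorescence units); `y_max > y_min >= 0`.
#' @param ec50 stimulus at half-maximal response, in stimulus units; > 0.
#' @param hill_n Hill coefficient; > 0.
#' @param mode `"activating"` or `"depletion_activating"`.
#' @param stimulus_units free-text stimulus units, e.g. `"% glucose (g/g)"`,
#'   `"umol/l DO"` or `"mM acetate"`.
#' @return An object of class `hill_sensor`.
#' @export
#' @examples
#' glu <- hill_sensor("glucose", y_min = 1/18, y_max = 1, ec50 = 0.1)
#' sensor_response(glu, 0.1)  # exactly the midpoint
hill_sensor <- function(name, y_min, y_max, ec50, hill_n = 1,
                        mode = c("activating", "depletion_activating"),
                        stimulus_units = "") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(y_min), is.numeric(y_max), is.numeric(ec50),
            is.numeric(hill_n), length(y_min) == 1L, length(y_max) == 1L)
  if (!(y_max > y_min && y_min >= 0))
    stop("invalid sensor: need y_max > y_min >= 0")
  if (ec50 <= 0) stop("invalid sensor: ec50 must be > 0")
  if (hill_n <= 0) stop("invalid sensor: hill_n must be > 0")
  if (!is.finite(y_max / max(y_min, .Machine$double.xmin)))
    stop("invalid sensor: dynamic range not finite")
  structure(
    list(name = name, y_min = y_min, y_max = y_max, ec50 = ec50,
         hill_n = hill_n, mode = mode, stimulus_units = stimulus_units),
    class = "hill_sensor")
}

#' @export
print.hill_sensor <- function(x, ...) {
  cat(sprintf("<hill_sensor> %s (%s)\n", x$name, x$mode))
  cat(sprintf("  y_min %.4g  y_max %.4g  ec50 %.4g %s  n %.3g\n",
              x$y_min, x$y_max, x$ec50, x$stimulus_units, x$hill_n))
  cat(sprintf("  dynamic range %.3g-fold\n", dynamic_range(x)))
  invisible(x)
}

#' Evaluate a sensor's response to a stimulus
#'
#' Activating sensors follow
#' `y = y_min + (y_max - y_min) * s^n / (ec50^n + s^n)`;
#' depletion-activating sensors (low oxygen) follow
#' `y = y_min + (y_max - y_min) * ec50^n / (ec50^n + s^n)`,
#' so the output rises as the stimulus falls. Vectorized over `stimulus`.
#'
#' @param sensor a [hill_sensor()].
#' @param stimulus non-negative stimulus value(s) in the sensor's units.
#' @return Output value(s) in `[y_min, y_max]`.
#' @export
sensor_response <- function(sensor, stimulus) {
  stopifnot(inherits(sensor, "hill_sensor"))
  if (any(!is.finite(stimulus)) || any(stimulus < 0))
    stop("stimulus must be finite and >= 0")
  n <- sensor$hill_n
  kn <- sensor$ec50^n
  sn <- stimulus^n
  frac <- switch(sensor$mode,
    activating = sn / (kn + sn),
    depletion_activating = kn / (kn + sn))
  # s = 0 with activating mode: 0/0 avoided because kn > 0
  sensor$y_min + (sensor$y_max - sensor$y_min) * frac
}

#' Fold dynamic range of a sensor
#'
#' @param sensor a [hill_sensor()].
#' @return `y_max / y_min` (Inf if `y_min` is 0).
#' @export
dynamic_range <- function(sensor) {
  stopifnot(inherits(sensor, "hill_sensor"))
  sensor$y_max / sensor$y_min
}

#' RPU calibration for the three sensors
#'
#' Fluorescence is converted to relative promoter units (RPU) by multiplying
#' background-subtracted fluorescence by a global conversion factor
#' (default `1e-3`). The calibration also records the measured minimum and
#' maximum RPU of each sensor's output promoter, used as the "low"/"high"
#' wire levels when digitizing circuits and when mapping normalized sensor
#' outputs onto RPU.
#'
#' Defaults: glucose 0.006–0.237, low oxygen 0.020–1.346,
#' acetate 0.002–0.700 RPU.
#'
#' @param rpu_conversion_factor fluorescence-to-RPU factor, > 0.
#' @param rpu_min,rpu_max named numeric vectors of per-sensor RPU extremes
#'   (names `glucose`, `oxygen`, `acetate`).
#' @return An object of class `sensor_calibration`.
#' @export
sensor_calibration <- function(rpu_conversion_factor = 1e-3,
                               rpu_min = c(glucose = 0.006, oxygen = 0.020,
                                           acetate = 0.002),
                               rpu_max = c(glucose = 0.237, oxygen = 1.346,
                                           acetate = 0.700)) {
  if (rpu_conversion_factor <= 0) stop("conversion factor must be > 0")
  if (!all(names(rpu_min) == names(rpu_max)))
    stop("rpu_min and rpu_max must share names")
  if (!all(rpu_max > rpu_min) || !all(rpu_min > 0))
    stop("need rpu_max > rpu_min > 0 for every sensor")
  structure(list(rpu_conversion_factor = rpu_conversion_factor,
                 rpu_min = rpu_min, rpu_max = rpu_max),
            class = "sensor_calibration")
}

#' Convert fluorescence to RPU
#'
#' @param fluor measured fluorescence (a.u.), `>= background`.
#' @param background background fluorescence (a.u.).
#' @param cal a [sensor_calibration()].
#' @return `(fluor - background) * rpu_conversion_factor`, in RPU.
#' @export
rpu_from_fluorescence <- function(fluor, background,
                                  cal = sensor_calibration()) {
  stopifnot(inherits(cal, "sensor_calibration"))
  if (any(fluor < background))
    stop("fluor < background: miscalibrated measurement")
  (fluor - background) * cal$rpu_conversion_factor
}

#' Reference sensors with published response parameters
#'
#' Returns the three sensors with their reported half-maximum points and
#' fold changes: glucose (half-max 0.1% glucose, 18-fold), low oxygen
#' (half-max 36 umol/l dissolved oxygen, 25-fold, depletion-activating) and
#' acetate (half-max 13.8 mM, 250-fold). The absolute output scale is
#' arbitrary and normalized to `y_max = 1`, with `y_min = 1/fold`; the Hill
#' coefficient defaults to 1 (no published slope) and is always refittable.
#'
#' @return Named list of three [hill_sensor()] objects
#'   (`glucose`, `oxygen`, `acetate`).
#' @export
default_sensors <- function() {
  list(
    glucose = hill_sensor("glucose", y_min = 1 / 18, y_max = 1, ec50 = 0.1,
                          hill_n = 1, mode = "activating",
                          stimulus_units = "% glucose (g/g)"),
    oxygen = hill_sensor("oxygen", y_min = 1 / 25, y_max = 1, ec50 = 36,
                         hill_n = 1, mode = "depletion_activating",
                         stimulus_units = "umol/l DO"),
    acetate = hill_sensor("acetate", y_min = 1 / 250, y_max = 1, ec50 = 13.8,
                          hill_n = 1, mode = "activating",
                          stimulus_units = "mM acetate"))
}

#' Serialize sensors to and from YAML
#'
#' @param sensor a [hill_sensor()].
#' @param path file path.
#' @return `read_sensor_yaml` returns a [hill_sensor()];
#'   `write_sensor_yaml` returns `path` invisibly.
#' @export
write_sensor_yaml <- function(sensor, path) {
  stopifnot(inherits(sensor, "hill_sensor"))
  yaml::write_yaml(unclass(sensor), path)
  invisible(path)
}

#' @rdname write_sensor_yaml
#' @export
read_sensor_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("name", "mode", "y_min", "y_max", "ec50", "hill_n",
            "stimulus_units")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("sensor YAML missing keys: ", paste(missing, collapse = ", "))
  hill_sensor(x$name, y_min = x$y_min, y_max = x$y_max, ec50 = x$ec50,
              hill_n = x$hill_n, mode = x$mode,
              stimulus_units = x$stimulus_units)
}
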