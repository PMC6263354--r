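#' Gate parameter records
#'
#' Steady-state response parameters for the three gate families used in the
#' circuits:
#'
#' * **Repressor (NOT/NOR) gates** follow
#'   `y = y_min + (y_max - y_min) * K^n / (K^n + x^n)`, where `x` is the
#'   input promoter activity in RPU (for NOR, the sum of the two inputs).
#'   Repressor parameters depend on the repressor protein assigned to the
#'   gate; a neutral default (`y_min` 0.01, `y_max` 1.0, `K` 0.1, `n` 2) is
#'   shipped and user parameter sets can be supplied through netlist files.
#' * **AND gates** (activator/chaperone pair) follow
#'   `y = y_min + (y_max - y_min) * x1 * x2^2 / (K + x1 * x2^2)` with
#'   defaults `y_min` 0.001 RPU, `y_max` 0.3 RPU, `K` 1e-5 RPU^3.
#' * **ANDN (AND NOT) gates** pass input `x1` and are quenched by `x2`:
#'   `y = y_min + (x1 - y_min) * K / (K + x2)` with defaults `y_min` 0.001
#'   RPU and `K` 0.0025 RPU. When `x1 < y_min` the response is clamped at
#'   `y_min` (the formula would undershoot).
#'
#' @param y_min,y_max output extremes (RPU).
#' @param K response threshold (RPU for repressor/ANDN; RPU^3 for AND).
#' @param n Hill coefficient (repressor gates only).
#' @return A parameter record of class `repressor_gate_params`,
#'   `and_gate_params` or `andn_gate_params`.
#' @name gate_params
NULL

#' @rdname gate_params
#' @export
repressor_gate_params <- function(y_min = 0.01, y_max = 1.0, K = 0.1, n = 2) {
  if (!(y_max > y_min && y_min > 0)) stop("need y_max > y_min > 0")
  if (K <= 0 || n <= 0) stop("need K > 0 and n > 0")
  structure(list(y_min = y_min, y_max = y_max, K = K, n = n),
            class = "repressor_gate_params")
}

#' @rdname gate_params
#' @export
and_gate_params <- function(y_min = 0.001, y_max = 0.3, K = 1e-5) {
  if (!(y_max > y_min && y_min > 0)) stop("need y_max > y_min > 0")
  if (K <= 0) stop("need K > 0")
  structure(list(y_min = y_min, y_max = y_max, K = K),
            class = "and_gate_params")
}

#' @rdname gate_params
#' @export
andn_gate_params <- function(y_min = 0.001, K = 0.0025) {
  if (y_min <= 0) stop("need y_min > 0")
  if (K <= 0) stop("need K > 0")
  structure(list(y_min = y_min, K = K), class = "andn_gate_params")
}

#' Steady-state gate response functions
#'
#' `repressor_response` evaluates the repression Hill function (NOT gates;
#' NOR callers pass `x = x1 + x2`). `and_response` and `andn_response`
#' evaluate the AND and ANDN response surfaces. All are vectorized and
#' reject negative inputs.
#'
#' @param p a parameter record from [gate_params].
#' @param x,x1,x2 input promoter activities (RPU, >= 0). For ANDN, `x1` is
#'   the passed signal and `x2` the antagonist.
#' @return Output promoter activity (RPU).
#' @name gate_response
NULL

#' @rdname gate_response
#' @export
repressor_response <- function(p, x) {
  stopifnot(inherits(p, "repressor_gate_params"))
  if (any(x < 0)) stop("gate input must be >= 0")
  kn <- p$K^p$n
  p$y_min + (p$y_max - p$y_min) * kn / (kn + x^p$n)
}

#' @rdname gate_response
#' @export
and_response <- function(p, x1, x2) {
  stopifnot(inherits(p, "and_gate_params"))
  if (any(x1 < 0) || any(x2 < 0)) stop("gate input must be >= 0")
  u <- x1 * x2^2
  p$y_min + (p$y_max - p$y_min) * u / (p$K + u)
}

#' @rdname gate_response
#' @export
andn_response <- function(p, x1, x2) {
  stopifnot(inherits(p, "andn_gate_params"))
  if (any(x1 < 0) || any(x2 < 0)) stop("gate input must be >= 0")
  y <- p$y_min + (x1 - p$y_min) * p$K / (p$K + x2)
  pmax(y, p$y_min)  # clamp when x1 < y_min
}

# dispatch a gate's steady-state response on its kind
gate_response_ss <- function(gate, xs) {
  switch(gate$kind,
    NOT  = repressor_response(gate$params, xs[[1L]]),
    NOR  = repressor_response(gate$params, xs[[1L]] + xs[[2L]]),
    AND  = and_response(gate$params, xs[[1L]], xs[[2L]]),
    ANDN = andn_response(gate$params, xs[[1L]], xs[[2L]]),
    stop("unknown gate kind: ", gate$kind))
}

# x-dependent production part of the gate ODE (excludes y_min offset),
# i.e. the steady-state response minus y_min
gate_production <- function(gate, xs) {
  gate_response_ss(gate, xs) - gate$params$y_min
}

gate_arity <- function(kind) {
  switch(kind, NOT = 1L, NOR = 2L, AND = 2L, ANDN = 2L,
         stop("unknown gate kind: ", kind))
}

default_gate_params <- function(kind) {
  switch(kind,
    NOT = repressor_gate_params(),
    NOR = repressor_gate_params(),
    AND = and_gate_params(),
    ANDN = andn_gate_params())
}
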