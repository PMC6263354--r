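#' Define a gate within a circuit netlist
#'
#' @param id unique wire id of the gate's output.
#' @param kind gate kind: `"NOT"`, `"NOR"`, `"AND"` or `"ANDN"`. For ANDN
#'   gates the first input is the passed signal and the second the
#'   antagonist.
#' @param inputs character vector of input wire ids (length 1 for NOT,
#'   2 otherwise).
#' @param params matching parameter record from [gate_params]; defaults to
#'   the kind's default parameters.
#' @return An object of class `circuit_gate`.
#' @export
gate <- function(id, kind, inputs, params = default_gate_params(kind)) {
  kind <- match.arg(kind, c("NOT", "NOR", "AND", "ANDN"))
  if (length(inputs) != gate_arity(kind))
    stop(sprintf("gate '%s': kind %s takes %d input(s), got %d",
                 id, kind, gate_arity(kind), length(inputs)))
  want <- switch(kind, NOT = , NOR = "repressor_gate_params",
                 AND = "and_gate_params", ANDN = "andn_gate_params")
  if (!inherits(params, want))
    stop(sprintf("gate '%s': kind %s needs %s", id, kind, want))
  structure(list(id = id, kind = kind, inputs = as.character(inputs),
                 params = params),
            class = "circuit_gate")
}

#' Assemble and validate a circuit netlist
#'
#' A circuit is a directed acyclic netlist over named sensor input wires.
#' Construction validates that every gate input is either a sensor wire or
#' the output of another gate, that wire ids are unique, that the netlist
#' is acyclic, and that the declared outputs resolve. Gates are stored in
#' topological order, so evaluation order never depends on the order the
#' gates were supplied in.
#'
#' @param inputs character vector of sensor input wire ids.
#' @param gates list of [gate()] objects.
#' @param outputs character vector of output wire ids (default: the last
#'   gate's id).
#' @return An object of class `circuit`.
#' @export
circuit <- function(inputs, gates = list(), outputs = NULL) {
  inputs <- as.character(inputs)
  if (anyDuplicated(inputs)) stop("duplicate sensor wire ids")
  gate_ids <- vapply(gates, function(g) g$id, character(1))
  if (anyDuplicated(c(inputs, gate_ids))) stop("duplicate wire ids")
  for (g in gates) {
    unknown <- setdiff(g$inputs, c(inputs, gate_ids))
    if (length(unknown))
      stop(sprintf("gate '%s' references unknown wire(s): %s",
                   g$id, paste(unknown, collapse = ", ")))
  }
  gates <- toposort_gates(inputs, gates)
  if (is.null(outputs))
    outputs <- if (length(gates)) gates[[length(gates)]]$id else character(0)
  bad <- setdiff(outputs, c(inputs, gate_ids))
  if (length(bad))
    stop("circuit outputs do not resolve: ", paste(bad, collapse = ", "))
  structure(list(inputs = inputs, gates = gates,
                 outputs = as.character(outputs)),
            class = "circuit")
}

# Kahn's algorithm; errors on cycles
toposort_gates <- function(inputs, gates) {
  if (!length(gates)) return(gates)
  ids <- vapply(gates, function(g) g$id, character(1))
  resolved <- inputs
  ordered <- list()
  remaining <- gates
  while (length(remaining)) {
    ready <- vapply(remaining, function(g) all(g$inputs %in% resolved),
                    logical(1))
    if (!any(ready)) {
      stuck <- vapply(remaining, function(g) g$id, character(1))
      stop("cycle detected among gates: ", paste(stuck, collapse = ", "))
    }
    ordered <- c(ordered, remaining[ready])
    resolved <- c(resolved, vapply(remaining[ready], function(g) g$id,
                                   character(1)))
    remaining <- remaining[!ready]
  }
  ordered
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> %d input(s): %s\n", length(x$inputs),
              paste(x$inputs, collapse = ", ")))
  for (g in x$gates)
    cat(sprintf("  %s <- %s(%s)\n", g$id, g$kind,
                paste(g$inputs, collapse = ", ")))
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Steady-state propagation through a circuit
#'
#' Evaluates each gate's steady-state response function in topological
#' order, starting from fixed sensor wire activities. This is the
#' steady-state reference behavior against which the dynamic simulation
#' relaxes.
#'
#' @param circ a [circuit()].
#' @param sensor_values named numeric vector or list assigning an RPU value
#'   to every sensor input wire.
#' @return Named numeric vector of wire activities (sensors and gates).
#' @export
circuit_steady_state <- function(circ, sensor_values) {
  stopifnot(inherits(circ, "circuit"))
  sensor_values <- unlist(sensor_values)
  missing <- setdiff(circ$inputs, names(sensor_values))
  if (length(missing))
    stop("unassigned sensor wire(s): ", paste(missing, collapse = ", "))
  wires <- sensor_values[circ$inputs]
  for (g in circ$gates) {
    xs <- as.list(unname(wires[g$inputs]))
    wires[g$id] <- gate_response_ss(g, xs)
  }
  wires
}
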