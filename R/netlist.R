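#' Read and write circuit netlists (JSON or YAML)
#'
#' The netlist schema is
#' `{inputs: [..], gates: [{id, kind, inputs, params}], outputs: [..]}`.
#' Gate `params` carry the fields of the matching [gate_params] record
#' (`y_min`, `y_max`, `K`, `n` as applicable); omitted params fall back to
#' the kind's defaults. Round-trip serialization is lossless. The format is
#' chosen by file extension (`.json` vs `.yaml`/`.yml`).
#'
#' Reading validates the circuit fully (unknown wires, arity, parameter
#' types, acyclicity) and reports all schema violations it finds.
#'
#' @param path netlist file path.
#' @param circ a [circuit()].
#' @return `read_netlist` returns a validated [circuit()]; the writer
#'   returns `path` invisibly.
#' @export
read_netlist <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  errors <- character(0)
  if (is.null(x$inputs)) errors <- c(errors, "netlist missing 'inputs'")
  gates <- lapply(x$gates, function(gx) {
    if (is.null(gx$id) || is.null(gx$kind) || is.null(gx$inputs)) {
      errors <<- c(errors, "gate entry missing id/kind/inputs")
      return(NULL)
    }
    params <- tryCatch({
      if (is.null(gx$params)) default_gate_params(gx$kind)
      else params_from_list(gx$kind, gx$params)
    }, error = function(e) {
      errors <<- c(errors, sprintf("gate '%s': %s", gx$id,
                                   conditionMessage(e)))
      NULL
    })
    if (is.null(params)) return(NULL)
    tryCatch(gate(gx$id, gx$kind, unlist(gx$inputs), params),
             error = function(e) {
               errors <<- c(errors, conditionMessage(e))
               NULL
             })
  })
  if (length(errors)) stop("invalid netlist:\n  ",
                           paste(errors, collapse = "\n  "))
  circ <- tryCatch(
    circuit(unlist(x$inputs), gates, outputs = unlist(x$outputs)),
    error = function(e) stop("invalid netlist:\n  ", conditionMessage(e)))
  circ
}

params_from_list <- function(kind, p) {
  get_or <- function(nm, default) if (is.null(p[[nm]])) default else p[[nm]]
  switch(kind,
    NOT = ,
    NOR = repressor_gate_params(y_min = get_or("y_min", 0.01),
                                y_max = get_or("y_max", 1.0),
                                K = get_or("K", 0.1),
                                n = get_or("n", 2)),
    AND = and_gate_params(y_min = get_or("y_min", 0.001),
                          y_max = get_or("y_max", 0.3),
                          K = get_or("K", 1e-5)),
    ANDN = andn_gate_params(y_min = get_or("y_min", 0.001),
                            K = get_or("K", 0.0025)),
    stop("unknown gate kind: ", kind))
}

#' @rdname read_netlist
#' @export
write_netlist <- function(circ, path) {
  stopifnot(inherits(circ, "circuit"))
  x <- list(
    inputs = as.list(circ$inputs),
    gates = lapply(circ$gates, function(g)
      list(id = g$id, kind = g$kind, inputs = as.list(g$inputs),
           params = unclass(g$params))),
    outputs = as.list(circ$outputs))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' The pulse-generating three-input circuit
#'
#' The demonstration circuit that integrates all three sensors into
#' `(glucose AND acetate) AND NOT low-oxygen` logic: an AND gate over the
#' glucose and acetate wires feeding the passed input of an ANDN gate whose
#' antagonist is the low-oxygen wire. With default gate parameters and
#' batch-growth sensor trajectories its output promoter produces a temporal
#' pulse.
#'
#' @param input_wires names of the three sensor wires, in the order
#'   glucose, oxygen, acetate.
#' @return A [circuit()] with gates `g_and` and `g_out`.
#' @export
pulse_circuit <- function(input_wires = c("glucose", "oxygen", "acetate")) {
  circuit(
    inputs = input_wires,
    gates = list(
      gate("g_and", "AND", c(input_wires[1L], input_wires[3L])),
      gate("g_out", "ANDN", c("g_and", input_wires[2L]))),
    outputs = "g_out")
}
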