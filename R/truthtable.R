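#' Truth table over circuit inputs
#'
#' @param n_inputs number of circuit inputs.
#' @param bits logical vector of length `2^n_inputs`, in lexicographic
#'   corner order (0 before 1, first input most significant).
#' @param input_names optional input wire names.
#' @return An object of class `truth_table`.
#' @export
truth_table <- function(n_inputs, bits, input_names = NULL) {
  bits <- as.logical(bits)
  if (length(bits) != 2^n_inputs)
    stop("bits must have length 2^n_inputs")
  if (is.null(input_names)) input_names <- paste0("x", seq_len(n_inputs))
  structure(list(n_inputs = as.integer(n_inputs), bits = bits,
                 input_names = input_names),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table>", paste(as.integer(x$bits), collapse = ""), "\n")
  invisible(x)
}

#' @export
format.truth_table <- function(x, ...) {
  paste(as.integer(x$bits), collapse = "")
}

# corner matrix: 2^n rows of 0/1, lexicographic, first input most significant
corner_matrix <- function(n) {
  idx <- 0:(2^n - 1)
  m <- sapply(seq_len(n), function(j) bitwAnd(idx %/% 2^(n - j), 1L))
  matrix(m, ncol = n)
}

# resolve per-wire (low, high) levels for a circuit's inputs
resolve_levels <- function(circ, cal, levels) {
  if (!is.null(levels)) {
    missing <- setdiff(circ$inputs, names(levels))
    if (length(missing))
      stop("levels missing for wire(s): ", paste(missing, collapse = ", "))
    return(levels[circ$inputs])
  }
  stopifnot(inherits(cal, "sensor_calibration"))
  sens <- names(cal$rpu_min)
  if (all(circ$inputs %in% sens)) {
    idx <- circ$inputs
  } else if (length(circ$inputs) == length(sens)) {
    idx <- sens  # positional: x1, x2, x3 -> glucose, oxygen, acetate
  } else {
    stop("cannot map circuit inputs onto calibration sensors; ",
         "supply explicit levels")
  }
  lv <- lapply(seq_along(circ$inputs),
               function(i) c(cal$rpu_min[[idx[i]]], cal$rpu_max[[idx[i]]]))
  names(lv) <- circ$inputs
  lv
}

#' Digitize a circuit into truth tables
#'
#' Evaluates [circuit_steady_state()] at every input corner (each sensor
#' wire at its low or high RPU level) and thresholds each output at the
#' geometric mean of that output's own minimum and maximum over the
#' corners. An output that is degenerate -- its corner extremes differ by
#' less than a 10-fold factor, so it carries no logic transition -- is
#' flagged (attribute `constant`) and its bit is assigned by comparison
#' with the global geometric-mean threshold of the input levels.
#'
#' @param circ a [circuit()] with at most 3 inputs (8 corners).
#' @param cal a [sensor_calibration()] supplying per-sensor RPU extremes;
#'   input wires are matched to calibration sensors by name, or
#'   positionally when the counts agree.
#' @param levels optional named list of `c(low, high)` levels per input
#'   wire, overriding `cal`.
#' @return A [truth_table()] for a single-output circuit, otherwise a
#'   named list of truth tables (one per output).
#' @export
digitize <- function(circ, cal = sensor_calibration(), levels = NULL) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$inputs)
  if (2^n > 8) stop("digitize supports at most 8 input corners")
  lv <- resolve_levels(circ, cal, levels)
  corners <- corner_matrix(n)
  vals <- matrix(NA_real_, nrow = nrow(corners),
                 ncol = length(circ$outputs),
                 dimnames = list(NULL, circ$outputs))
  for (i in seq_len(nrow(corners))) {
    sv <- vapply(seq_len(n),
                 function(j) lv[[j]][corners[i, j] + 1L], numeric(1))
    names(sv) <- circ$inputs
    ss <- circuit_steady_state(circ, sv)
    vals[i, ] <- ss[circ$outputs]
  }
  global_thr <- exp(mean(log(unlist(lv))))
  tabs <- lapply(circ$outputs, function(out) {
    v <- vals[, out]
    # an output whose corner extremes differ by < 10x carries no logic
    # transition (true transitions span orders of magnitude); treat it as
    # constant and threshold against the global level midpoint instead
    if (max(v) < 10 * min(v)) {
      tt <- truth_table(n, v > global_thr, circ$inputs)
      attr(tt, "constant") <- TRUE
      return(tt)
    }
    thr <- sqrt(min(v) * max(v))
    tt <- truth_table(n, v > thr, circ$inputs)
    attr(tt, "constant") <- FALSE
    tt
  })
  names(tabs) <- circ$outputs
  if (length(tabs) == 1L) tabs[[1L]] else tabs
}

#' Ideal Boolean truth table of a circuit
#'
#' Evaluates the circuit with ideal gate logic (NOT, NOR, AND, AND NOT)
#' over all input corners, independent of any analog gate parameters.
#'
#' @param circ a [circuit()] (single output used).
#' @return A [truth_table()].
#' @export
boolean_truth_table <- function(circ) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$inputs)
  corners <- corner_matrix(n)
  out <- circ$outputs[[1L]]
  bits <- logical(nrow(corners))
  for (i in seq_len(nrow(corners))) {
    w <- as.logical(corners[i, ])
    names(w) <- circ$inputs
    for (g in circ$gates) {
      a <- w[[g$inputs[1L]]]
      b <- if (length(g$inputs) > 1L) w[[g$inputs[2L]]] else NA
      w[[g$id]] <- switch(g$kind,
        NOT = !a, NOR = !(a | b), AND = a && b, ANDN = a && !b)
    }
    bits[i] <- w[[out]]
  }
  truth_table(n, bits, circ$inputs)
}

#' Near-ideal gate parameters and wire levels for logic verification
#'
#' Parameter set under which analog digitization is expected to reproduce
#' ideal Boolean composition for layered circuits of depth <= 2:
#' vanishing basal output, large fold change and a steep repression
#' coefficient, with idealized sensor levels (low 1e-4, high 1).
#'
#' @return List with elements `params` (per-kind parameter records) and
#'   `levels_fun(circ)` returning idealized `c(low, high)` levels for each
#'   circuit input.
#' @export
ideal_gate_setup <- function() {
  params <- list(
    NOT = repressor_gate_params(y_min = 1e-4, y_max = 1, K = 0.03, n = 4),
    NOR = repressor_gate_params(y_min = 1e-4, y_max = 1, K = 0.03, n = 4),
    AND = and_gate_params(y_min = 1e-4, y_max = 1, K = 0.3),
    ANDN = andn_gate_params(y_min = 1e-4, K = 1e-3))
  levels_fun <- function(circ) {
    lv <- rep(list(c(1e-4, 1)), length(circ$inputs))
    names(lv) <- circ$inputs
    lv
  }
  list(params = params, levels_fun = levels_fun)
}

#' Enumerate layered circuits over three sensor inputs
#'
#' Generates all circuits of at most `max_depth` layered gates over three
#' sensor inputs using the allowed gate kinds, evaluates each circuit's
#' ideal Boolean truth table, and returns one representative circuit per
#' distinct table. Symmetric gates (NOR, AND) take unordered distinct input
#' pairs; ANDN takes ordered distinct pairs. At most 256 distinct 3-input
#' 1-output tables can exist.
#'
#' @param max_depth maximum number of gate layers (0 to 3). Depth 0 yields
#'   the three projection circuits.
#' @param kinds gate kinds allowed, subset of `c("NOT","NOR","AND","ANDN")`.
#' @param params optional named list of parameter records per kind used for
#'   the returned circuits (default: near-ideal parameters from
#'   [ideal_gate_setup()]).
#' @param guard maximum number of candidate circuits to evaluate before
#'   aborting with a count estimate.
#' @return List of entries, each `list(circuit =, table =)`, deduplicated
#'   by truth table; attribute `n_candidates` records how many circuits
#'   were evaluated.
#' @export
enumerate_circuits <- function(max_depth,
                               kinds = c("NOT", "NOR", "AND", "ANDN"),
                               params = NULL, guard = 100000L) {
  if (max_depth < 0 || max_depth > 3)
    stop("max_depth must be between 0 and 3")
  kinds <- match.arg(kinds, c("NOT", "NOR", "AND", "ANDN"),
                     several.ok = TRUE)
  if (is.null(params)) params <- ideal_gate_setup()$params

  sensors <- c("x1", "x2", "x3")
  # expression nodes: sensors are character; gates are list(kind, children)
  layers <- list(as.list(sensors))
  if (max_depth >= 1) {
    for (d in seq_len(max_depth)) {
      pool <- unlist(layers, recursive = FALSE)
      est <- length(kinds) * (length(pool)^2 + length(pool))
      if (est > guard)
        stop(sprintf(
          "enumeration guard exceeded: ~%d candidate circuits at depth %d",
          est, d))
      prev <- layers[[d]]  # require >= 1 child from the previous layer
      new <- list()
      for (k in kinds) {
        if (gate_arity(k) == 1L) {
          for (a in prev) new[[length(new) + 1L]] <- list(kind = k,
                                                          children = list(a))
        } else if (k == "ANDN") {
          for (a in pool) for (b in pool) {
            if (identical(a, b)) next
            if (!(node_in(a, prev) || node_in(b, prev))) next
            new[[length(new) + 1L]] <- list(kind = k, children = list(a, b))
          }
        } else {  # symmetric: unordered distinct pairs
          for (i in seq_along(pool)) for (j in seq_along(pool)) {
            if (j <= i) next
            a <- pool[[i]]; b <- pool[[j]]
            if (!(node_in(a, prev) || node_in(b, prev))) next
            new[[length(new) + 1L]] <- list(kind = k, children = list(a, b))
          }
        }
      }
      layers[[d + 1L]] <- new
    }
  }

  nodes <- unlist(layers, recursive = FALSE)
  seen <- new.env(parent = emptyenv())
  results <- list()
  for (nd in nodes) {
    circ <- node_to_circuit(nd, sensors, params)
    tt <- boolean_truth_table(circ)
    key <- format(tt)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    results[[length(results) + 1L]] <- list(circuit = circ, table = tt)
  }
  attr(results, "n_candidates") <- length(nodes)
  results
}

node_in <- function(node, set) {
  for (s in set) if (identical(s, node)) return(TRUE)
  FALSE
}

# flatten an expression node into a circuit object
node_to_circuit <- function(node, sensors, params) {
  gates <- list()
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  build <- function(nd) {
    if (is.character(nd)) return(nd)
    ins <- vapply(nd$children, build, character(1))
    counter$i <- counter$i + 1L
    id <- paste0("g", counter$i)
    gates[[length(gates) + 1L]] <<- gate(id, nd$kind, ins,
                                         params[[nd$kind]])
    id
  }
  out <- build(node)
  circuit(sensors, gates, outputs = out)
}

#' Export a truth table as CSV
#'
#' Writes one row per input corner with columns for each input and a final
#' `output_bit`, in lexicographic corner order (0 before 1, first input
#' most significant).
#'
#' @param tt a [truth_table()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_truth_table_csv <- function(tt, path) {
  stopifnot(inherits(tt, "truth_table"))
  corners <- corner_matrix(tt$n_inputs)
  df <- as.data.frame(corners)
  names(df) <- tt$input_names
  df$output_bit <- as.integer(tt$bits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
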