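# shared fixtures, all built in code

# the three-repressor example circuit: y1 = NOR(x1, x2), y2 = NOT(x3),
# y3 = NOR(y1, y2)
three_repressor_circuit <- function(params = repressor_gate_params()) {
  circuit(
    inputs = c("x1", "x2", "x3"),
    gates = list(
      gate("y1", "NOR", c("x1", "x2"), params),
      gate("y2", "NOT", "x3", params),
      gate("y3", "NOR", c("y1", "y2"), params)),
    outputs = "y3")
}

constant_tc <- function(value, name, t_end = 27) {
  time_course(c(0, t_end), c(value, value), name = name)
}

# independent fixed-point iteration oracle for steady states (Jacobi
# sweeps over all gates simultaneously, no topological ordering)
fixed_point_oracle <- function(circ, sensor_values, alpha = 1, gamma = 1,
                               tol = 1e-12, max_iter = 10000) {
  wires <- unlist(sensor_values)[circ$inputs]
  for (g in circ$gates) wires[g$id] <- 0
  for (iter in seq_len(max_iter)) {
    prev <- wires
    for (g in circ$gates) {
      xs <- as.list(unname(prev[g$inputs]))
      prod <- switch(g$kind,
        NOT = (g$params$y_max - g$params$y_min) * g$params$K^g$params$n /
          (g$params$K^g$params$n + xs[[1]]^g$params$n),
        NOR = (g$params$y_max - g$params$y_min) * g$params$K^g$params$n /
          (g$params$K^g$params$n + (xs[[1]] + xs[[2]])^g$params$n),
        AND = (g$params$y_max - g$params$y_min) * xs[[1]] * xs[[2]]^2 /
          (g$params$K + xs[[1]] * xs[[2]]^2),
        ANDN = max((xs[[1]] - g$params$y_min), 0) * g$params$K /
          (g$params$K + xs[[2]]))
      wires[g$id] <- g$params$y_min + (alpha / gamma) * prod
    }
    if (max(abs(wires - prev)) < tol) break
  }
  wires
}

# corner matrix in the package's lexicographic convention, rebuilt
# independently for oracle use
oracle_corners <- function(n) {
  out <- matrix(0L, nrow = 2^n, ncol = n)
  for (i in seq_len(2^n)) {
    v <- i - 1L
    for (j in n:1) {
      out[i, j] <- v %% 2L
      v <- v %/% 2L
    }
  }
  out
}
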