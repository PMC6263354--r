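#' Dose-response data container
#'
#' Holds replicate measurements of a sensor's output over an ascending
#' dose series. At least 4 distinct dose levels are required for fitting.
#'
#' @param doses non-negative, strictly ascending stimulus values.
#' @param responses numeric matrix with `length(doses)` rows, one column
#'   per replicate (a vector is taken as a single replicate).
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(doses, responses) {
  if (is.vector(responses)) responses <- matrix(responses, ncol = 1L)
  responses <- as.matrix(responses)
  if (any(doses < 0)) stop("doses must be non-negative")
  if (any(diff(doses) <= 0)) stop("doses must be strictly ascending")
  if (nrow(responses) != length(doses))
    stop("responses must have one row per dose")
  structure(list(doses = doses, responses = responses),
            class = "dose_response")
}

#' Read and write dose-response CSV
#'
#' The on-disk dialect has a mandatory header `dose,replicate,response`
#' with dot decimals.
#'
#' @param path CSV file path.
#' @param dr a [dose_response()].
#' @return `read_dose_response_csv` returns a [dose_response()];
#'   the writer returns `path` invisibly.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "replicate", "response")
  if (!all(need %in% names(df)))
    stop("dose-response CSV must have header dose,replicate,response")
  wide <- stats::reshape(df, idvar = "dose", timevar = "replicate",
                         direction = "wide")
  wide <- wide[order(wide$dose), , drop = FALSE]
  dose_response(wide$dose, as.matrix(wide[, -1, drop = FALSE]))
}

#' @rdname read_dose_response_csv
#' @export
write_dose_response_csv <- function(dr, path) {
  stopifnot(inherits(dr, "dose_response"))
  df <- data.frame(
    dose = rep(dr$doses, times = ncol(dr$responses)),
    replicate = rep(seq_len(ncol(dr$responses)), each = length(dr$doses)),
    response = as.vector(dr$responses))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a Hill transfer function to dose-response data
#'
#' Least-squares estimation of `y_min`, `y_max`, `ec50` and `hill_n` by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) with positivity bounds on
#' all parameters. Initialization: `y_min = min(data)`, `y_max = max(data)`,
#' `ec50 =` dose whose mean response is nearest the midpoint, `n = 1`.
#'
#' By default residuals are taken on the log scale
#' (`log(y) - log(mu)`), the maximum-likelihood choice under
#' multiplicative constant-CV measurement noise; promoter outputs span
#' orders of magnitude and absolute residuals would leave the off state
#' (hence the dynamic range) essentially unconstrained. Set
#' `log_residuals = FALSE` for absolute least squares.
#'
#' The fit is flagged as poor (`poor_fit = TRUE`) when the optimizer fails
#' to converge or when the fitted curve explains less than half of the
#' response variance (R^2 < 0.5), e.g. when monotone-decreasing data are
#' fitted with `mode = "activating"`. There is no silent fallback: the
#' report always carries the flag.
#'
#' @param data a [dose_response()] with >= 4 distinct doses and positive
#'   responses.
#' @param mode `"activating"` or `"depletion_activating"`.
#' @param name name given to the fitted sensor.
#' @param stimulus_units stimulus units recorded on the fitted sensor.
#' @param log_residuals minimize log-scale residuals (default) rather than
#'   absolute residuals.
#' @param fix_n optional fixed Hill coefficient. The default (`NULL`)
#'   co-estimates the slope; pass `fix_n = 1` when fitting data known to
#'   come from a unit-slope model (the package's sensor default), which
#'   substantially tightens the `ec50` and dynamic-range estimates.
#' @return A list of class `hill_fit` with elements `sensor` (the fitted
#'   [hill_sensor()]), `estimates` (named vector), `residual_norm`,
#'   `r_squared`, `converged` and `poor_fit`.
#' @export
fit_hill <- function(data, mode = c("activating", "depletion_activating"),
                     name = "fitted", stimulus_units = "",
                     log_residuals = TRUE, fix_n = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "dose_response"))
  if (length(unique(data$doses)) < 4L)
    stop("need >= 4 distinct doses to fit a Hill function")
  if (any(data$responses <= 0)) stop("responses must be positive")

  s <- rep(data$doses, times = ncol(data$responses))
  y <- as.vector(data$responses)
  mean_resp <- rowMeans(data$responses)

  y0 <- min(y)
  y1 <- max(y)
  mid <- (y0 + y1) / 2
  ec0 <- data$doses[which.min(abs(mean_resp - mid))]
  if (ec0 <= 0) ec0 <- min(data$doses[data$doses > 0])

  hill_mu <- if (mode == "activating") {
    function(par) par[1] + (par[2] - par[1]) * s^par[4] /
      (par[3]^par[4] + s^par[4])
  } else {
    function(par) par[1] + (par[2] - par[1]) * par[3]^par[4] /
      (par[3]^par[4] + s^par[4])
  }
  eps <- .Machine$double.eps
  free_n <- is.null(fix_n)
  expand <- function(par) if (free_n) par else c(par, fix_n)
  resid_fn <- if (log_residuals) {
    function(par) log(y) - log(pmax(hill_mu(expand(par)), eps))
  } else {
    function(par) y - hill_mu(expand(par))
  }
  # multi-start over the weakly identified floor and the midpoint guess:
  # a single Levenberg-Marquardt run can stall on the y_min bound when the
  # off state is only reached asymptotically (depletion sensors)
  fit <- NULL
  err <- NULL
  for (ym0 in y0 * c(1, 1 / 4, 1 / 20)) {
    for (ec00 in ec0 * c(1, 1 / 3, 3)) {
      start <- if (free_n) c(ymin = ym0, ymax = y1, ec50 = ec00, n = 1)
               else c(ymin = ym0, ymax = y1, ec50 = ec00)
      cand <- tryCatch(
        minpack.lm::nls.lm(
          par = start,
          lower = rep(eps, length(start)),
          fn = resid_fn,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
      if (inherits(cand, "error")) {
        if (is.null(err)) err <- cand
        next
      }
      if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
    }
  }
  if (is.null(fit)) fit <- err

  if (inherits(fit, "error")) {
    return(structure(list(
      sensor = NULL,
      estimates = c(y_min = NA_real_, y_max = NA_real_,
                    ec50 = NA_real_, hill_n = NA_real_),
      residual_norm = NA_real_, r_squared = NA_real_,
      converged = FALSE, poor_fit = TRUE,
      message = conditionMessage(fit)), class = "hill_fit"))
  }

  cf <- stats::setNames(expand(fit$par), c("ymin", "ymax", "ec50", "n"))
  rss <- sum(fit$fvec^2)
  yy <- if (log_residuals) log(y) else y
  tss <- sum((yy - mean(yy))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  converged <- fit$info %in% c(1L, 2L, 3L)
  sensor <- tryCatch(
    hill_sensor(name, y_min = cf[["ymin"]], y_max = cf[["ymax"]],
                ec50 = cf[["ec50"]], hill_n = cf[["n"]], mode = mode,
                stimulus_units = stimulus_units),
    error = function(e) NULL)
  structure(list(
    sensor = sensor,
    estimates = c(y_min = cf[["ymin"]], y_max = cf[["ymax"]],
                  ec50 = cf[["ec50"]], hill_n = cf[["n"]]),
    residual_norm = sqrt(rss),
    r_squared = r2,
    converged = converged,
    poor_fit = !converged || is.null(sensor) || r2 < 0.5,
    message = NULL), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", if (x$poor_fit) "[POOR FIT]" else "", "\n")
  print(x$estimates)
  cat(sprintf("  residual norm %.4g  R^2 %.4f  converged %s\n",
              x$residual_norm, x$r_squared, x$converged))
  invisible(x)
}
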