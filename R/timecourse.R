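#' Sampled trajectory with linear interpolation semantics
#'
#' Sensor outputs are measured at discrete time points (hours); values in
#' between samples are linearly interpolated and the terminal values are
#' held constant beyond either end of the sampled range.
#'
#' @param times sample times in hours, strictly ascending, length >= 2.
#' @param values sampled values (stimulus units or RPU), same length.
#' @param name series name.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, values, name = "") {
  if (length(times) != length(values) || length(times) < 2L)
    stop("need matching times/values of length >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 name = name),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s: %d samples over [%.3g, %.3g] h\n",
              x$name, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Interpolate a time course
#'
#' Piecewise-linear interpolation that returns exact node values at sample
#' times and holds the terminal value beyond either end (clamped
#' extrapolation).
#'
#' @param tc a [time_course()].
#' @param t query time(s) in hours.
#' @return Interpolated value(s).
#' @export
tc_interpolate <- function(tc, t) {
  stopifnot(inherits(tc, "time_course"))
  stats::approx(tc$times, tc$values, xout = t, method = "linear",
                rule = 2)$y
}

#' Read and write time-course CSV
#'
#' The dialect is `time_h,series,value` with a mandatory header, UTF-8,
#' dot decimals and hours as the only time unit. One file can hold several
#' interleaved series; each series must have strictly ascending,
#' duplicate-free times.
#'
#' @param path CSV file path.
#' @param tcs named list of [time_course()] objects.
#' @return `read_timecourse_csv` returns a named list of time courses;
#'   the writer returns `path` invisibly.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "series", "value") %in% names(df)))
    stop("time-course CSV must have header time_h,series,value")
  if (nrow(df) == 0L) stop("empty time-course file: ", path)
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  out <- list()
  for (s in unique(df$series)) {
    sub <- df[df$series == s, , drop = FALSE]
    dup <- duplicated(sub$time_h)
    if (any(dup))
      stop(sprintf("series '%s': duplicate time at line %d", s,
                   sub$.line[which(dup)[1L]]))
    if (is.unsorted(sub$time_h, strictly = TRUE))
      stop(sprintf("series '%s': unsorted times near line %d", s,
                   sub$.line[which(diff(sub$time_h) <= 0)[1L] + 1L]))
    out[[s]] <- time_course(sub$time_h, sub$value, name = s)
  }
  out
}

#' @rdname read_timecourse_csv
#' @export
write_timecourse_csv <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- stats::setNames(list(tcs),
                                                           tcs$name)
  df <- do.call(rbind, lapply(tcs, function(tc)
    data.frame(time_h = tc$times, series = tc$name, value = tc$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
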