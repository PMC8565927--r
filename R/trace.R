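#' Uniformly sampled signal trace
#'
#' @param samples Numeric vector of sample values (all finite).
#' @param dt Sampling interval, ms.
#' @param t0 Time of the first sample, ms.
#' @param unit One of `"mV"`, `"pA"`, `"nA"`, `"uS"`.
#' @return An `sc_trace` object.
#' @export
new_trace <- function(samples, dt, t0 = 0, unit = c("pA", "mV", "nA", "uS")) {
  unit <- match.arg(unit)
  if (dt <= 0) rlang::abort("dt must be positive")
  if (!all(is.finite(samples))) rlang::abort("trace samples must all be finite")
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0, unit = unit),
            class = "sc_trace")
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt %g ms (%.3g ms), unit %s\n",
              length(x$samples), x$dt, length(x$samples) * x$dt, x$unit))
  invisible(x)
}

trace_times <- function(tr) tr$t0 + (seq_along(tr$samples) - 1) * tr$dt

# Subset a trace to [t_lo, t_hi] by index arithmetic (clamped to the trace).
trace_window <- function(tr, t_lo, t_hi) {
  n <- length(tr$samples)
  i_lo <- max(1L, floor((t_lo - tr$t0) / tr$dt) + 1L)
  i_hi <- min(n, ceiling((t_hi - tr$t0) / tr$dt) + 1L)
  if (i_lo == 1L && i_hi == n) return(tr)
  new_trace(tr$samples[i_lo:i_hi], dt = tr$dt,
            t0 = tr$t0 + (i_lo - 1L) * tr$dt, unit = tr$unit)
}

#' @method as_tibble sc_trace
#' @export
as_tibble.sc_trace <- function(x, ...) {
  tibble::tibble(time_ms = trace_times(x), value = x$samples)
}

#' Read / write a trace as two-column delimited text
#'
#' Columns `time_ms` and `value`; sampling must be uniform.
#'
#' @param path File path.
#' @param unit Unit recorded in the returned trace.
#' @return `read_trace`: an `sc_trace`. `write_trace`: `path`, invisibly.
#' @export
read_trace <- function(path, unit = "pA") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  t <- d[[1]]
  dts <- diff(t)
  if (length(dts) < 1 || diff(range(dts)) > 1e-6 * max(abs(dts))) {
    rlang::abort("trace file is not uniformly sampled")
  }
  new_trace(d[[2]], dt = dts[1], t0 = t[1], unit = unit)
}

#' @rdname read_trace
#' @param tr An `sc_trace`.
#' @export
write_trace <- function(tr, path) {
  d <- as_tibble(tr)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Linear interpolation of the time at which the segment between consecutive
# samples crosses `level`, scanning from index i0 in direction dir.
crossing_time <- function(t, y, level, i0, dir = 1L) {
  n <- length(y)
  i <- i0
  while (i + dir >= 1 && i + dir <= n) {
    a <- y[i]; b <- y[i + dir]
    if ((a <= level && b >= level) || (a >= level && b <= level)) {
      if (a == b) return(t[i])
      frac <- (level - a) / (b - a)
      return(t[i] + frac * (t[i + dir] - t[i]))
    }
    i <- i + dir
  }
  NA_real_
}
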