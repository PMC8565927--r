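#' Detect synaptic events in a current trace by threshold crossing
#'
#' The trace is baseline-subtracted (median), lightly smoothed with a boxcar
#' of width `smooth_ms`, and events are flagged where the smoothed deflection
#' in the stated direction stays above `threshold_sd` times a robust noise SD
#' (median absolute deviation of the smoothed trace) for at least
#' `min_above_ms`; the run requirement suppresses isolated noise excursions
#' that any single-sample threshold would pick up on long recordings. After
#' each onset a dead time of `min_interval` suppresses re-triggering on the
#' same event.
#'
#' @param trace An [new_trace()] current trace.
#' @param threshold_sd Detection threshold in robust noise SDs.
#' @param min_interval Dead time after each detected onset, ms.
#' @param direction Deflection direction of events: `"negative"` (inward
#'   synaptic currents, default), `"positive"`, or `"both"`.
#' @param smooth_ms Boxcar smoothing width, ms.
#' @param min_above_ms Minimum time the smoothed deflection must stay above
#'   threshold, ms.
#' @return A tibble with column `onset_ms` (threshold-crossing times).
#' @export
detect_events <- function(trace, threshold_sd = 4, min_interval = 2,
                          direction = c("negative", "positive", "both"),
                          smooth_ms = 0.1, min_above_ms = 0.2) {
  stopifnot(inherits(trace, "sc_trace"))
  direction <- match.arg(direction)
  y <- trace$samples
  if (length(y) < 10) rlang::abort("trace too short for event detection")
  w <- max(1L, round(smooth_ms / trace$dt))
  ys <- if (w > 1) stats::filter(y, rep(1 / w, w), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  base <- stats::median(ys)
  noise <- stats::mad(ys)
  if (noise == 0) noise <- stats::sd(ys)
  if (is.na(noise) || noise == 0) return(tibble::tibble(onset_ms = numeric(0)))
  defl <- switch(direction,
    negative = base - ys,
    positive = ys - base,
    both = abs(ys - base)
  )
  above <- defl > threshold_sd * noise
  need <- max(1L, round(min_above_ms / trace$dt))
  t <- trace_times(trace)
  onsets <- numeric(0)
  i <- 1L
  n <- length(y)
  dead <- max(1L, ceiling(min_interval / trace$dt))
  while (i <= n - need + 1L) {
    if (above[i] && all(above[i:(i + need - 1L)])) {
      onsets <- c(onsets, t[i])
      i <- i + dead
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(onset_ms = onsets)
}

#' Measure amplitude and kinetics of one synaptic event
#'
#' Conventions: baseline is the mean over the 1 ms window preceding the
#' onset; the amplitude is the absolute difference between the baseline and
#' the mean over a 100 us window centered on the peak; the 10-90% rise time
#' and the width at half amplitude use linear interpolation between samples.
#'
#' @param trace A current (or voltage) trace.
#' @param onset Event onset time, ms.
#' @param baseline_window Baseline averaging window before onset, ms.
#' @param peak_window Window after onset searched for the peak, ms.
#' @param peak_avg_window Averaging window centered on the peak, ms.
#' @param decay_window Integration window for the weighted decay constant, ms.
#' @return One-row tibble: `onset_ms`, `amplitude`, `rise_10_90`,
#'   `half_width`, `tau_decay`, `peak_time` (amplitude in trace units, times
#'   in ms).
#' @export
measure_event <- function(trace, onset, baseline_window = 1, peak_window = 5,
                          peak_avg_window = 0.1, decay_window = 10) {
  stopifnot(inherits(trace, "sc_trace"))
  # restrict to a local window so long recordings measure in O(window)
  trace <- trace_window(trace, onset - baseline_window - 1,
                        onset + peak_window + decay_window + 1)
  t <- trace_times(trace)
  y <- trace$samples
  dt <- trace$dt
  i_on <- which(t >= onset - 1e-9)[1]
  if (is.na(i_on)) rlang::abort("onset beyond end of trace")
  i_base <- which(t >= onset - baseline_window & t < onset)
  # traces starting at the event are taken as already baseline-subtracted
  base <- if (length(i_base) > 0) mean(y[i_base]) else 0
  i_win <- which(t >= onset & t <= onset + peak_window)
  if (length(i_win) < 3) rlang::abort("event not fully contained in trace")
  defl <- y[i_win] - base
  i_pk_rel <- which.max(abs(defl))
  # center within a flat peak plateau so the averaging window sits inside it
  plateau <- abs(defl) >= max(abs(defl)) * (1 - 1e-12)
  run_end <- i_pk_rel
  while (run_end < length(i_win) && plateau[run_end + 1]) run_end <- run_end + 1
  i_pk_rel <- (i_pk_rel + run_end) %/% 2
  if (i_pk_rel == length(i_win)) rlang::abort("peak at trace boundary; extend the trace")
  i_pk <- i_win[i_pk_rel]
  sgn <- sign(defl[i_pk_rel])
  peak_time <- t[i_pk]
  half_avg <- peak_avg_window / 2
  i_avg <- which(t >= peak_time - half_avg - 1e-9 & t <= peak_time + half_avg + 1e-9)
  amplitude <- abs(mean(y[i_avg]) - base)
  # signed deflection oriented positive toward the peak
  u <- sgn * (y - base)
  t10 <- crossing_time(t, u, 0.1 * amplitude, i_pk, dir = -1L)
  t90 <- crossing_time(t, u, 0.9 * amplitude, i_pk, dir = -1L)
  rise <- if (anyNA(c(t10, t90))) NA_real_ else t90 - t10
  h1 <- crossing_time(t, u, 0.5 * amplitude, i_pk, dir = -1L)
  h2 <- crossing_time(t, u, 0.5 * amplitude, i_pk, dir = 1L)
  half_width <- if (anyNA(c(h1, h2))) NA_real_ else h2 - h1
  tau <- tau_decay_weighted(trace, onset,
                            baseline_window = baseline_window,
                            peak_window = peak_window,
                            decay_window = decay_window)
  tibble::tibble(onset_ms = onset, amplitude = amplitude, rise_10_90 = rise,
                 half_width = half_width, tau_decay = tau,
                 peak_time = peak_time)
}

#' Average aligned event waveform
#'
#' Aligns events at their onsets and averages them pointwise, the standard
#' way population mean miniature-event kinetics are measured (per-event
#' threshold crossings are noise-biased at realistic signal-to-noise).
#' Events too close to the trace edges are dropped.
#'
#' @param trace A current trace.
#' @param onsets Event onset times, ms (e.g. from [detect_events()]).
#' @param pre_ms Baseline time included before each onset, ms.
#' @param post_ms Time included after each onset, ms.
#' @return A trace of the mean waveform whose time origin is `pre_ms` before
#'   the aligned onset (so `measure_event(avg, onset = pre_ms)` applies).
#' @export
average_event_waveform <- function(trace, onsets, pre_ms = 1, post_ms = 8) {
  stopifnot(inherits(trace, "sc_trace"))
  if (length(onsets) == 0) rlang::abort("no onsets to average")
  y <- trace$samples
  dt <- trace$dt
  pre <- round(pre_ms / dt)
  post <- round(post_ms / dt)
  segs <- lapply(onsets, function(on) {
    i0 <- round((on - trace$t0) / dt) + 1
    if (i0 - pre < 1 || i0 + post > length(y)) return(NULL)
    y[(i0 - pre):(i0 + post)]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) rlang::abort("no event fully contained in the trace")
  avg <- Reduce(`+`, segs) / length(segs)
  new_trace(avg, dt = dt, t0 = 0, unit = trace$unit)
}

#' Weighted decay time constant of an event
#'
#' `tau_decay` is the integral of the baseline-subtracted current from the
#' peak to the return to baseline, divided by the peak amplitude. The end of
#' the integral is the first post-peak baseline crossing, or `decay_window`
#' after the peak if the signal never returns within it.
#'
#' @inheritParams measure_event
#' @return Weighted decay constant, ms.
#' @export
tau_decay_weighted <- function(trace, onset = 0, baseline_window = 1,
                               peak_window = 5, decay_window = 10) {
  stopifnot(inherits(trace, "sc_trace"))
  trace <- trace_window(trace, onset - baseline_window - 1,
                        onset + peak_window + decay_window + 1)
  t <- trace_times(trace)
  y <- trace$samples
  i_base <- which(t >= onset - baseline_window & t < onset)
  base <- if (length(i_base) > 0) mean(y[i_base]) else 0
  i_win <- which(t >= onset & t <= onset + peak_window)
  defl <- y[i_win] - base
  i_pk <- i_win[which.max(abs(defl))]
  sgn <- sign(y[i_pk] - base)
  i_peak_val <- abs(y[i_pk] - base)
  if (i_peak_val <= 0) rlang::abort("nonpositive peak amplitude")
  u <- sgn * (y - base)
  i_end <- length(y)
  lim <- which(t > t[i_pk] + decay_window)
  if (length(lim) > 0) i_end <- lim[1]
  cross <- which(u[(i_pk + 1):i_end] <= 0)
  if (length(cross) > 0) i_end <- i_pk + cross[1]
  idx <- i_pk:i_end
  integ <- sum(diff(t[idx]) * (u[idx][-1] + u[idx][-length(idx)]) / 2)
  integ / i_peak_val
}

#' Summarize event statistics per cell and per group
#'
#' Takes a table of per-event measurements (as produced by [measure_event()],
#' one row per event) with a `cell_id` column and optionally a `group`
#' column; computes per-cell means of each statistic, then group mean and
#' SEM, with an optional two-sample Wilcoxon rank comparison between two
#' groups.
#'
#' @param events Tibble of per-event stats with `cell_id` and optionally
#'   `group` columns.
#' @param compare If `TRUE` and exactly two groups are present, adds a
#'   Wilcoxon rank-sum comparison of the per-cell means per statistic.
#' @return A list with `cells` (per-cell means), `groups` (group mean and
#'   SEM), and `tests` (or `NULL`).
#' @export
summarize_population <- function(events, compare = FALSE) {
  events <- tibble::as_tibble(events)
  if (!"cell_id" %in% names(events)) rlang::abort("events must have a cell_id column")
  stat_cols <- intersect(
    c("amplitude", "rise_10_90", "half_width", "tau_decay"), names(events))
  grp <- "group" %in% names(events)
  keys <- if (grp) c("cell_id", "group") else "cell_id"
  cells <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(stat_cols),
                                   \(x) mean(x, na.rm = TRUE)),
                     n_events = dplyr::n(), .groups = "drop")
  gkey <- if (grp) "group" else character(0)
  groups <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gkey))) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(stat_cols),
      list(mean = \(x) mean(x, na.rm = TRUE),
           sem = \(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))),
      n_cells = dplyr::n(), .groups = "drop")
  tests <- NULL
  if (compare && grp && dplyr::n_distinct(cells$group) == 2) {
    gs <- unique(cells$group)
    tests <- purrr::map_dfr(stat_cols, function(sc) {
      a <- cells[[sc]][cells$group == gs[1]]
      b <- cells[[sc]][cells$group == gs[2]]
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      tibble::tibble(statistic = sc, group_a = as.character(gs[1]),
                     group_b = as.character(gs[2]),
                     mean_a = mean(a), mean_b = mean(b),
                     p_value = wt$p.value)
    })
  }
  list(cells = cells, groups = groups, tests = tests)
}
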