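#' Paced force recording of a myocardial slice
#'
#' @param time_s strictly increasing, uniformly sampled time (s).
#' @param force_mN force (mN), same length.
#' @param sampling_hz sampling rate; inferred from `time_s` if absent.
#' @param protocol optional data.frame `(frequency_hz, duration_s)` of the
#'   pacing staircase; durations must fit in the trace span.
#' @param stimulus_times_s optional stimulus times (s).
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time_s, force_mN, sampling_hz = NULL,
                        protocol = NULL, stimulus_times_s = NULL) {
  stopifnot(length(time_s) == length(force_mN), length(time_s) >= 2L)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("time_s must be uniformly sampled (1e-6 relative tolerance)")
  if (is.null(sampling_hz)) sampling_hz <- 1 / mean(dt)
  if (!is.null(protocol)) {
    stopifnot(all(c("frequency_hz", "duration_s") %in% names(protocol)))
    span <- time_s[length(time_s)] - time_s[1] + mean(dt)
    if (sum(protocol$duration_s) > span * (1 + 1e-9))
      stop("protocol durations exceed the trace span")
  }
  structure(list(time_s = as.numeric(time_s),
                 force_mN = as.numeric(force_mN),
                 sampling_hz = sampling_hz, protocol = protocol,
                 stimulus_times_s = stimulus_times_s),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %.1f s at %g Hz sampling, %s\n",
              diff(range(x$time_s)), x$sampling_hz,
              if (is.null(x$protocol)) "no protocol"
              else paste0(nrow(x$protocol), "-interval protocol")))
  invisible(x)
}

#' Slice geometry and cross-sectional area
#'
#' The default reproduces the standard preparation: 5 mm wide slices of
#' 300 um nominal thickness with 50 um of damaged surface layers, giving
#' a cross-sectional area of 5 mm x 0.25 mm = 1.25 mm^2.
#'
#' @param width_mm slice width (mm).
#' @param nominal_thickness_mm cut thickness (mm).
#' @param damaged_margin_mm thickness of the damaged top+bottom cell
#'   layers excluded from the load-bearing cross-section (mm).
#' @return An object of class `slice_geometry` with `area_mm2`.
#' @export
slice_geometry <- function(width_mm = 5, nominal_thickness_mm = 0.3,
                           damaged_margin_mm = 0.05) {
  area <- width_mm * (nominal_thickness_mm - damaged_margin_mm)
  if (!is.finite(area) || area <= 0)
    stop("invalid geometry: cross-sectional area must be positive")
  structure(list(width_mm = width_mm,
                 nominal_thickness_mm = nominal_thickness_mm,
                 damaged_margin_mm = damaged_margin_mm,
                 area_mm2 = area),
            class = "slice_geometry")
}

#' Wall tension from force and slice geometry
#'
#' `T = F / A` in mN/mm^2.
#'
#' @param f_mN force (mN), vectorized.
#' @param geometry a [slice_geometry()].
#' @return Tension (mN/mm^2).
#' @export
wall_tension <- function(f_mN, geometry = slice_geometry()) {
  stopifnot(inherits(geometry, "slice_geometry"))
  f_mN / geometry$area_mm2
}

#' Split a trace into per-stimulus twitch windows
#'
#' One window per stimulus, from the stimulus to the next one (the last
#' window is capped at full relaxation, 5 s).  Without stimulus times,
#' onsets are detected as upward crossings of baseline + 20% of the trace
#' amplitude.
#'
#' @param trace a [force_trace()].
#' @param baseline_mN baseline force; default the 10th percentile.
#' @return data.frame `(stim_s, start_s, end_s)`; empty (with a warning)
#'   if no twitches are found.
#' @export
detect_twitches <- function(trace, baseline_mN = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  f <- trace$force_mN; t <- trace$time_s
  if (is.null(baseline_mN)) baseline_mN <- quantile(f, 0.1, names = FALSE)
  stim <- trace$stimulus_times_s
  if (is.null(stim)) {
    amp <- max(f) - baseline_mN
    if (amp <= 0 || !any(f > baseline_mN + 0.5 * amp)) {
      warning("no twitches found")
      return(data.frame(stim_s = numeric(0), start_s = numeric(0),
                        end_s = numeric(0)))
    }
    th <- baseline_mN + 0.2 * amp
    up <- which(f[-1] > th & f[-length(f)] <= th)
    if (length(up) == 0L) {
      warning("no twitches found")
      return(data.frame(stim_s = numeric(0), start_s = numeric(0),
                        end_s = numeric(0)))
    }
    stim <- t[up]
    # debounce: drop crossings closer than 100 ms
    stim <- stim[c(TRUE, diff(stim) > 0.1)]
  }
  stim <- sort(stim)
  ends <- c(stim[-1], min(stim[length(stim)] + 5, t[length(t)]))
  data.frame(stim_s = stim, start_s = stim, end_s = ends)
}

# Centred moving-average smoother; edge samples keep their raw values.
smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Kinetic parameters of a single twitch
#'
#' Peak active force above baseline, time to peak (onset to peak), time
#' to relaxation (peak to 90% decay of the peak active force) and 90%
#' contraction duration (onset to 90% decay, so `CD90 = TTP + TTR`).
#' Threshold crossings are linearly interpolated between samples.  For
#' fused twitches (force at the window start clearly above baseline) the
#' pre-peak minimum serves as the local baseline and the result is
#' flagged.
#'
#' @param trace a [force_trace()].
#' @param window one row of [detect_twitches()] (or a list with `start_s`,
#'   `end_s` and optionally `stim_s`).
#' @param baseline_mN resting force level.
#' @param onset `"stimulus"` (default when a stimulus time is available)
#'   or `"threshold"`: crossing of baseline + 5% of the twitch amplitude.
#' @param smooth_ms width (ms) of the centred moving average applied
#'   before peak and threshold detection; suppresses the selection bias
#'   of the raw maximum under measurement noise while shifting the peak
#'   of a smooth twitch by far less than a sample interval.
#' @return data.frame row with `f_max_mN`, `ttp_s`, `ttr_s`, `cd90_s`,
#'   `onset_time_s`, `truncated`, `fused`.
#' @export
twitch_params <- function(trace, window, baseline_mN = NULL,
                          onset = c("stimulus", "threshold"),
                          smooth_ms = 5) {
  stopifnot(inherits(trace, "force_trace"))
  onset <- match.arg(onset)
  t <- trace$time_s; f <- trace$force_mN
  sel <- which(t >= window$start_s & t < window$end_s)
  if (length(sel) < 3L) stop("twitch window contains too few samples")
  tw <- t[sel]
  k <- max(1L, round(smooth_ms / 1000 * trace$sampling_hz))
  fw <- smooth_ma(f[sel], k)
  if (is.null(baseline_mN))
    baseline_mN <- quantile(smooth_ma(f, k), 0.1, names = FALSE)
  ipk <- which.max(fw)
  truncated <- ipk == 1L || ipk == length(fw)
  pre_min <- min(fw[seq_len(ipk)])
  amp0 <- max(fw) - baseline_mN
  fused <- (fw[1] - baseline_mN) > 0.2 * amp0
  local_base <- if (fused) pre_min else baseline_mN
  f_max <- fw[ipk] - local_base
  if (f_max <= 0) stop("window contains no force above baseline")

  onset_t <- if (onset == "stimulus" && !is.null(window$stim_s) &&
                 !is.na(window$stim_s)) {
    window$stim_s
  } else {
    th <- local_base + 0.05 * f_max
    ic <- which(fw[seq_len(ipk)] >= th)[1]
    if (is.na(ic)) tw[1]
    else if (ic == 1L) tw[1]
    else {
      # linear interpolation of the upward threshold crossing
      tw[ic - 1L] + (th - fw[ic - 1L]) / (fw[ic] - fw[ic - 1L]) *
        (tw[ic] - tw[ic - 1L])
    }
  }
  ttp <- tw[ipk] - onset_t

  th90 <- local_base + 0.1 * f_max
  post <- seq(ipk, length(fw))
  below <- which(fw[post] <= th90)
  if (length(below) == 0L) {
    ttr <- NA_real_; cd90 <- NA_real_; truncated <- TRUE
  } else {
    ib <- post[below[1]]
    t90 <- if (ib == ipk) tw[ipk]
    else tw[ib - 1L] + (fw[ib - 1L] - th90) / (fw[ib - 1L] - fw[ib]) *
      (tw[ib] - tw[ib - 1L])
    ttr <- t90 - tw[ipk]
    cd90 <- t90 - onset_t
  }
  data.frame(f_max_mN = f_max, ttp_s = ttp, ttr_s = ttr, cd90_s = cd90,
             onset_time_s = onset_t, truncated = truncated, fused = fused)
}

#' Per-frequency twitch averages over the analysis window
#'
#' For each protocol interval, twitches whose stimulus falls in the final
#' `window_s` seconds (default 30 s) are analyzed individually and their
#' parameters averaged.  Intervals shorter than the window are used in
#' full, with a warning.
#'
#' @param trace a [force_trace()] with a protocol (or one supplied here).
#' @param protocol optional override of `trace$protocol`.
#' @param window_s analysis window at the end of each interval (s).
#' @param geometry optional [slice_geometry()]; adds wall tension.
#' @return An object of class `frequency_response` with a `table`
#'   data.frame: `frequency_hz`, `n_twitches`, `f_max_mN`, `ttp_s`,
#'   `ttr_s`, `cd90_s` and `tension_mN_mm2` when geometry is given.
#' @export
interval_average <- function(trace, protocol = NULL, window_s = 30,
                             geometry = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  protocol <- protocol %||% trace$protocol
  if (is.null(protocol)) stop("no pacing protocol available")
  tw <- detect_twitches(trace)
  t0 <- cumsum(c(0, protocol$duration_s)) + trace$time_s[1]
  rows <- lapply(seq_len(nrow(protocol)), function(k) {
    dur <- protocol$duration_s[k]
    win <- window_s
    if (dur < window_s) {
      warning(sprintf("interval %d shorter than %g s; using it in full",
                      k, window_s))
      win <- dur
    }
    a0 <- t0[k + 1] - win; a1 <- t0[k + 1]
    idx <- which(tw$stim_s >= a0 - 1e-9 & tw$stim_s < a1 - 1e-9)
    if (length(idx) == 0L)
      return(data.frame(frequency_hz = protocol$frequency_hz[k],
                        n_twitches = 0L, f_max_mN = NA_real_,
                        ttp_s = NA_real_, ttr_s = NA_real_,
                        cd90_s = NA_real_))
    ksm <- max(1L, round(0.005 * trace$sampling_hz))
    base_k <- quantile(smooth_ma(
      trace$force_mN[trace$time_s >= t0[k] & trace$time_s < t0[k + 1]],
      ksm), 0.1, names = FALSE)
    pars <- do.call(rbind, lapply(idx, function(i)
      twitch_params(trace, tw[i, ], baseline_mN = base_k)))
    data.frame(frequency_hz = protocol$frequency_hz[k],
               n_twitches = nrow(pars),
               f_max_mN = mean(pars$f_max_mN),
               ttp_s = mean(pars$ttp_s),
               ttr_s = mean(pars$ttr_s, na.rm = TRUE),
               cd90_s = mean(pars$cd90_s, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(geometry))
    tab$tension_mN_mm2 <- wall_tension(tab$f_max_mN, geometry)
  structure(list(table = tab, geometry = geometry, window_s = window_s),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat("frequency_response:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Force-frequency ratios
#'
#' Ratios of the mean peak forces at 1 vs 0.5 Hz and 2 vs 0.5 Hz; values
#' above or below 1 indicate a positive or negative force-frequency
#' relationship.  A missing frequency yields a flagged `NA` ratio.
#'
#' @param fr a [interval_average()] result.
#' @return Named list `ffr_1_0p5`, `ffr_2_0p5`.
#' @export
ffr_ratios <- function(fr) {
  stopifnot(inherits(fr, "frequency_response"))
  tab <- fr$table
  fmax_at <- function(f) {
    i <- which(abs(tab$frequency_hz - f) < 1e-9)
    if (length(i) != 1L || is.na(tab$f_max_mN[i])) NA_real_
    else tab$f_max_mN[i]
  }
  denom <- fmax_at(0.5)
  if (is.na(denom) || denom <= 0) {
    warning("0.5 Hz reference force missing; ratios undefined")
    return(list(ffr_1_0p5 = NA_real_, ffr_2_0p5 = NA_real_))
  }
  r1 <- fmax_at(1) / denom
  r2 <- fmax_at(2) / denom
  if (is.na(r1) || is.na(r2))
    warning("a protocol frequency is missing; the affected ratio is NA")
  list(ffr_1_0p5 = r1, ffr_2_0p5 = r2)
}

#' Median aggregation of neighboring slices
#'
#' Contractile parameters measured in several neighboring slices of one
#' sample are combined by the component-wise median per frequency.
#'
#' @param per_slice list of `frequency_response` objects over a common
#'   protocol.
#' @return A `frequency_response` with the per-frequency medians.
#' @export
aggregate_slices <- function(per_slice) {
  if (length(per_slice) == 0L) stop("no slices to aggregate")
  stopifnot(all(vapply(per_slice, inherits, logical(1),
                       "frequency_response")))
  tabs <- lapply(per_slice, `[[`, "table")
  freqs <- tabs[[1]]$frequency_hz
  for (tb in tabs)
    if (!isTRUE(all.equal(tb$frequency_hz, freqs)))
      stop("slices must share one protocol")
  med_tab <- tabs[[1]]
  num_cols <- setdiff(names(med_tab), c("frequency_hz", "n_twitches"))
  for (cc in num_cols)
    med_tab[[cc]] <- apply(sapply(tabs, `[[`, cc), 1L, median)
  med_tab$n_twitches <- apply(sapply(tabs, `[[`, "n_twitches"), 1L, min)
  structure(list(table = med_tab, geometry = per_slice[[1]]$geometry,
                 n_slices = length(per_slice)),
            class = "frequency_response")
}
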