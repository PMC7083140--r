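#' Closed-form twitch kinetics of the double-exponential model
#'
#' The synthetic twitch is `F(t) = A * (exp(-t / tau_d) - exp(-t / tau_r))`
#' with decay constant `tau_d` greater than rise constant `tau_r`.  The
#' time to peak is `tau_r * tau_d * log(tau_d / tau_r) / (tau_d - tau_r)`,
#' and the peak amplitude factor (peak force for `A = 1`) follows by
#' substitution.
#'
#' @param tau_r,tau_d rise and decay time constants (s), `tau_d > tau_r`.
#' @return `twitch_ttp()`: time to peak (s); `twitch_peak_factor()`: peak
#'   of the unit-amplitude twitch; `twitch_force()`: force at time `t`
#'   after onset for a twitch scaled to peak force `f_max`.
#' @export
twitch_ttp <- function(tau_r, tau_d) {
  if (any(tau_d <= tau_r)) stop("tau_d must exceed tau_r")
  tau_r * tau_d * log(tau_d / tau_r) / (tau_d - tau_r)
}

#' @rdname twitch_ttp
#' @export
twitch_peak_factor <- function(tau_r, tau_d) {
  if (any(tau_d <= tau_r)) stop("tau_d must exceed tau_r")
  r <- tau_r / tau_d
  r^(tau_r / (tau_d - tau_r)) - r^(tau_d / (tau_d - tau_r))
}

#' @rdname twitch_ttp
#' @param t time after onset (s), vectorized.
#' @param f_max peak force of the twitch.
#' @export
twitch_force <- function(t, tau_r, tau_d, f_max = 1) {
  a <- f_max / twitch_peak_factor(tau_r, tau_d)
  ifelse(t >= 0, a * (exp(-t / tau_d) - exp(-t / tau_r)), 0)
}

# Numerically solved relaxation landmarks of the unit twitch: time from
# onset to decay to `level` of peak (on the falling limb).
twitch_decay_time <- function(tau_r, tau_d, level = 0.1) {
  ttp <- twitch_ttp(tau_r, tau_d)
  f <- function(t) twitch_force(t, tau_r, tau_d, 1) - level
  uniroot(f, c(ttp, ttp + 20 * tau_d), tol = 1e-10)$root
}

#' Default staircase pacing protocol
#'
#' Four intervals of 120 s at 0.2, 0.5, 1 and 2 Hz.
#' @return data.frame with `frequency_hz`, `duration_s`.
#' @export
default_protocol <- function() {
  data.frame(frequency_hz = c(0.2, 0.5, 1, 2), duration_s = 120)
}

#' Generate a paced force trace with known twitch kinetics
#'
#' Builds a force recording following a pacing staircase: at each
#' stimulus one double-exponential twitch is added (tails superpose).
#' Twitch shape and peak amplitude are programmable per frequency; ground
#' truth stores the closed-form time to peak and the numerically solved
#' relaxation landmarks of each shape, plus the programmed
#' force-frequency ratios.
#'
#' @param protocol data.frame `(frequency_hz, duration_s)`; default the
#'   0.2/0.5/1/2 Hz staircase of 120 s intervals.
#' @param twitch_shape data.frame `(frequency_hz, tau_r_s, tau_d_s)`; the
#'   default accelerates kinetics with frequency so twitches relax within
#'   the pacing period.
#' @param amplitude_mN named numeric (names = frequency) or vector in
#'   protocol order: peak active force per frequency.
#' @param baseline_mN resting (passive) force.
#' @param noise_sd Gaussian noise SD (mN).
#' @param sampling_hz sampling rate.
#' @param rng_seed integer seed.
#' @return List with `trace` (a [force_trace()]) and `truth` (class
#'   `synthetic_ground_truth`: per-frequency `f_max_mN`, `ttp_s`, `ttr_s`,
#'   `cd90_s`, programmed FFR ratios, `rng_seed`).
#' @export
gen_force_trace <- function(protocol = default_protocol(),
                            twitch_shape = NULL,
                            amplitude_mN = NULL,
                            baseline_mN = 0.1,
                            noise_sd = 0,
                            sampling_hz = 1000,
                            rng_seed = 1L) {
  stopifnot(is.data.frame(protocol),
            all(c("frequency_hz", "duration_s") %in% names(protocol)))
  nf <- nrow(protocol)
  if (is.null(twitch_shape)) {
    shapes <- data.frame(frequency_hz = c(0.2, 0.5, 1, 2),
                         tau_r_s = c(0.05, 0.05, 0.035, 0.02),
                         tau_d_s = c(0.15, 0.15, 0.10, 0.055))
    twitch_shape <- shapes[match(protocol$frequency_hz,
                                 shapes$frequency_hz), ]
    if (any(is.na(twitch_shape$tau_r_s)))
      stop("no default twitch shape for this frequency; supply twitch_shape")
  }
  if (any(twitch_shape$tau_d_s <= twitch_shape$tau_r_s))
    stop("tau_d must exceed tau_r for every frequency")
  if (is.null(amplitude_mN)) {
    amps <- c(`0.2` = 0.9, `0.5` = 1, `1` = 1.08, `2` = 1.05)
    amplitude_mN <- amps[as.character(protocol$frequency_hz)]
    if (any(is.na(amplitude_mN)))
      stop("no default amplitude for this frequency; supply amplitude_mN")
  } else if (!is.null(names(amplitude_mN))) {
    amplitude_mN <- amplitude_mN[as.character(protocol$frequency_hz)]
  }
  amplitude_mN <- as.numeric(amplitude_mN)
  # twitches should relax within the pacing period (no full fusion)
  per <- 1 / protocol$frequency_hz
  cd <- mapply(twitch_decay_time, twitch_shape$tau_r_s,
               twitch_shape$tau_d_s, 0.1)
  if (any(cd > per))
    warning("twitch duration exceeds the pacing period at some frequency; ",
            "twitches will fuse")

  dt <- 1 / sampling_hz
  total_s <- sum(protocol$duration_s)
  n <- round(total_s * sampling_hz)
  time_s <- (seq_len(n) - 1L) * dt
  force <- rep(baseline_mN, n)
  t0 <- cumsum(c(0, protocol$duration_s))
  stim_all <- numeric(0)
  for (k in seq_len(nf)) {
    stim <- seq(t0[k], t0[k + 1] - 1e-9, by = per[k])
    stim_all <- c(stim_all, stim)
    a <- amplitude_mN[k] / twitch_peak_factor(twitch_shape$tau_r_s[k],
                                              twitch_shape$tau_d_s[k])
    span <- min(ceiling(20 * twitch_shape$tau_d_s[k] * sampling_hz), n)
    for (s in stim) {
      i0 <- floor(s * sampling_hz) + 1L
      i1 <- min(i0 + span, n)
      tt <- time_s[i0:i1] - s
      add <- a * (exp(-tt / twitch_shape$tau_d_s[k]) -
                  exp(-tt / twitch_shape$tau_r_s[k]))
      add[tt < 0] <- 0
      force[i0:i1] <- force[i0:i1] + add
    }
  }
  if (noise_sd > 0)
    force <- with_seed(rng_seed, force + rnorm(n, 0, noise_sd))

  ttp <- twitch_ttp(twitch_shape$tau_r_s, twitch_shape$tau_d_s)
  cd90 <- mapply(twitch_decay_time, twitch_shape$tau_r_s,
                 twitch_shape$tau_d_s, 0.1)
  per_freq <- data.frame(
    frequency_hz = protocol$frequency_hz,
    f_max_mN = amplitude_mN,
    tau_r_s = twitch_shape$tau_r_s, tau_d_s = twitch_shape$tau_d_s,
    ttp_s = ttp, ttr_s = cd90 - ttp, cd90_s = cd90)
  amp_of <- function(f) {
    i <- match(f, protocol$frequency_hz)
    if (is.na(i)) NA_real_ else amplitude_mN[i]
  }
  truth <- structure(list(
    per_frequency = per_freq,
    ffr_1_0p5 = amp_of(1) / amp_of(0.5),
    ffr_2_0p5 = amp_of(2) / amp_of(0.5),
    baseline_mN = baseline_mN, rng_seed = rng_seed),
    class = "synthetic_ground_truth")
  trace <- force_trace(time_s, force, sampling_hz = sampling_hz,
                       protocol = protocol, stimulus_times_s = stim_all)
  list(trace = trace, truth = truth)
}

#' Generate a synthetic study cohort table
#'
#' Draws per-sample t-tubule distances, Ca-handling protein levels and
#' contractile read-outs from programmed relationships: the relaxation
#' time follows the no-intercept interaction model
#' `TTR = b1 * (dTT - ratio * NCX1 * dTT)` plus Gaussian noise, the FFR
#' ratios fall linearly with dTT (crossing 1 at the dichotomization
#' point), and wall tension at 1 and 2 Hz declines with dTT while the low
#' frequencies are dTT-independent.
#'
#' @param n_samples number of samples (>= 3).
#' @param coef_ttr numeric `c(b1, ratio)`: leading coefficient and
#'   interaction ratio of the TTR model.
#' @param dtt_range,ncx1_range uniform sampling ranges for dTT (um) and
#'   NCX1 (normalized units).
#' @param ffr_slope decline of the FFR ratios per um of dTT.
#' @param noise_sds named list: `ttr` (s), `ffr`, `tension` (mN/mm2),
#'   `ttp` (s).
#' @param rng_seed integer seed.
#' @return List with `samples` (data.frame, one row per sample) and
#'   `truth` (generating coefficients, class `synthetic_ground_truth`).
#' @export
gen_cohort <- function(n_samples = 13,
                       coef_ttr = c(b1 = 0.36, ratio = 0.069),
                       dtt_range = c(0.8, 1.5),
                       ncx1_range = c(0.2, 3.0),
                       ffr_slope = -0.8,
                       noise_sds = list(ttr = 0.005, ffr = 0.05,
                                        tension = 0.3, ttp = 0.005),
                       rng_seed = 1L) {
  if (n_samples < 3) stop("n_samples must be at least 3")
  if (any(unlist(noise_sds) < 0)) stop("noise SDs must be non-negative")
  b1 <- coef_ttr[[1]]; ratio <- coef_ttr[[2]]
  samples <- with_seed(rng_seed, {
    dtt <- runif(n_samples, dtt_range[1], dtt_range[2])
    ncx1 <- runif(n_samples, ncx1_range[1], ncx1_range[2])
    serca2 <- runif(n_samples, 0.5, 1.5)
    plb <- runif(n_samples, 0.5, 1.5)
    plb_ps16 <- plb * runif(n_samples, 0.3, 1.2)
    plb_pt17 <- plb * runif(n_samples, 0.3, 1.2)
    ttr <- b1 * (dtt - ratio * ncx1 * dtt) + rnorm(n_samples, 0,
                                                   noise_sds$ttr)
    ttp <- 0.18 - 0.02 * serca2 / plb + rnorm(n_samples, 0, noise_sds$ttp)
    ffr1 <- 1 + ffr_slope * (dtt - 1.05) + rnorm(n_samples, 0,
                                                 noise_sds$ffr)
    ffr2 <- 1 + ffr_slope * (dtt - 1.05) + rnorm(n_samples, 0,
                                                 1.6 * noise_sds$ffr)
    tension <- function(base, slope) {
      pmax(base + slope * (dtt - 1.05) + rnorm(n_samples, 0,
                                               noise_sds$tension), 0.05)
    }
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      delta_tt_um = dtt, ncx1 = ncx1, serca2 = serca2, plb = plb,
      plb_ps16 = plb_ps16, plb_pt17 = plb_pt17,
      serca2_plb = serca2 / plb, plb_pt17_plb = plb_pt17 / plb,
      ttr_s = ttr, ttp_s = ttp, cd90_s = ttp + ttr,
      ffr_1_0p5 = ffr1, ffr_2_0p5 = ffr2,
      tension_0.2hz = tension(1.0, 0),
      tension_0.5hz = tension(1.1, 0),
      tension_1hz = tension(1.2, -1.9),
      tension_2hz = tension(1.15, -1.9))
  })
  truth <- structure(list(
    generating_coefficients = list(
      ttr = c(b1 = b1, ratio = ratio, b2 = -b1 * ratio),
      ffr = c(intercept_at_threshold = 1, slope = ffr_slope,
              threshold_um = 1.05)),
    noise_sds = noise_sds, rng_seed = rng_seed),
    class = "synthetic_ground_truth")
  list(samples = samples, truth = truth)
}
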