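#' Closed-loop controller configuration
#'
#' Configuration of the phase-amplitude-coupled cerebellar stimulation
#' controller: the instantaneous phase of the infra-slow (0.01-0.10 Hz)
#' oxyhemoglobin oscillation at the phase-source region, estimated with a
#' Hilbert transform over a trailing 60 s window, drives the amplitude of a
#' 4 Hz stimulation carrier saturated at `a_max`.
#'
#' @param phase_region Region supplying the phase signal; default
#'   `"left-PFC"`.
#' @param band_lo,band_hi Infra-slow band edges (Hz); defaults 0.01 / 0.10.
#' @param window_s Sliding-window length (s); default 60. Must cover at
#'   least one period of the upper band edge.
#' @param carrier_hz Stimulation carrier frequency (Hz); default 4.
#' @param a_max Maximum stimulation amplitude (mA); default 2.
#' @param update_s Amplitude update interval (s); default 1.
#' @param command_fs Sample rate of the synthesized command (Hz); default
#'   100.
#' @param phase_lag Optional phase offset (rad) added before the
#'   phase-to-amplitude map; default 0.
#' @param amp_floor Analytic amplitude (fraction of the window's RMS) below
#'   which the phase is treated as undefined and the controller holds the
#'   mapping midpoint `a_max / 2`; default 0.1.
#' @return A `controller_config` list.
#' @export
controller_config <- function(phase_region = "left-PFC", band_lo = 0.01,
                              band_hi = 0.10, window_s = 60, carrier_hz = 4,
                              a_max = 2, update_s = 1, command_fs = 100,
                              phase_lag = 0, amp_floor = 0.1) {
  if (a_max <= 0) abort("a_max must be positive", class = "cctcsim_input_error")
  if (window_s < 1 / band_hi) {
    abort("window must cover at least one period of the upper band edge",
          class = "cctcsim_input_error")
  }
  if (command_fs <= 2 * carrier_hz) {
    abort("command sample rate must exceed twice the carrier frequency",
          class = "cctcsim_nyquist_error")
  }
  structure(list(phase_region = phase_region, band_lo = band_lo,
                 band_hi = band_hi, window_s = window_s,
                 carrier_hz = carrier_hz, a_max = a_max,
                 update_s = update_s, command_fs = command_fs,
                 phase_lag = phase_lag, amp_floor = amp_floor),
            class = "controller_config")
}

# Trailing-edge phase/amplitude of one window by narrowband regression:
# w(t) ~ A cos(2 pi f t + phi) + intercept + linear trend, with f chosen by a
# coarse-to-fine least-squares search over the band. Phase is referenced to
# the window's trailing edge (t = 0 there), matching the analytic-signal
# convention for in-band tones.
fit_edge_phase <- function(w, fs, lo, hi) {
  n <- length(w)
  tt <- (seq_len(n) - n) / fs
  base <- cbind(1, tt)
  eval_f <- function(f0) {
    X <- cbind(cos(2 * pi * f0 * tt), sin(2 * pi * f0 * tt), base)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, w)),
                   error = function(e) NULL)
    if (is.null(cf)) return(list(ss = Inf))
    list(ss = sum((w - X %*% cf)^2), a = cf[1], b = cf[2])
  }
  search <- function(grid) {
    best <- list(ss = Inf, f = NA_real_)
    for (f0 in grid) {
      r <- eval_f(f0)
      if (r$ss < best$ss) best <- c(r, f = f0)
    }
    best
  }
  coarse <- search(seq(lo, hi, length.out = 40))
  df <- (hi - lo) / 39
  fine <- search(seq(max(lo, coarse$f - df), min(hi, coarse$f + df),
                     length.out = 21))
  z <- complex(real = fine$a, imaginary = -fine$b)
  list(phase = Arg(z), amplitude = Mod(z), freq = fine$f)
}

#' Causal sliding-window instantaneous phase
#'
#' For each sample from the first full window onward, the instantaneous
#' phase of the infra-slow oscillation at the trailing edge of the most
#' recent `window_s` seconds is estimated. The estimate is causal: it never
#' uses samples beyond the current time; earlier samples are in the warm-up
#' state.
#'
#' Two estimators are available. The default, `"fit"`, regresses the window
#' on a single narrowband sinusoid (frequency chosen by least squares inside
#' the band) plus a linear trend, and reads phase and amplitude analytically
#' at the edge; it agrees with the analytic-signal convention on in-band
#' tones while avoiding the endpoint bias of a windowed Hilbert transform
#' when the window does not hold an integer number of cycles. `"hilbert"`
#' takes the argument of the raw windowed analytic signal at the trailing
#' edge.
#'
#' @param x Band-limited series (e.g. infra-slow HbO).
#' @param fs Sample rate (Hz).
#' @param window_s Window length (s); default 60.
#' @param step Evaluate the phase every `step` samples (default 1).
#' @param method `"fit"` (default) or `"hilbert"`.
#' @param band Frequency band searched by the `"fit"` estimator (Hz);
#'   default `c(0.008, 0.11)`, slightly wider than the infra-slow band.
#' @return A tibble with columns `index`, `time`, `phase` (rad, in
#'   `(-pi, pi]`) and `amplitude` (estimated component amplitude at the
#'   trailing edge).
#' @export
sliding_window_phase <- function(x, fs, window_s = 60, step = 1L,
                                 method = c("fit", "hilbert"),
                                 band = c(0.008, 0.11)) {
  method <- match.arg(method)
  n <- length(x)
  wlen <- round(window_s * fs)
  if (n < wlen) {
    abort("record shorter than one window: controller stays in warm-up",
          class = "cctcsim_warmup_error")
  }
  idx <- seq(wlen, n, by = step)
  ph <- rep(NA_real_, length(idx))
  am <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    w <- x[(idx[k] - wlen + 1):idx[k]]
    if (method == "fit") {
      r <- fit_edge_phase(w, fs, band[1], band[2])
      ph[k] <- r$phase
      am[k] <- r$amplitude
    } else {
      a <- analytic_signal(w - mean(w))
      z <- a[length(a)]
      ph[k] <- Arg(z)
      am[k] <- Mod(z)
    }
  }
  tibble(index = idx, time = (idx - 1) / fs, phase = ph, amplitude = am)
}

#' Raised-cosine phase-to-amplitude map
#'
#' `A(phi) = a_max (1 + cos(phi + lag)) / 2`: continuous, 2 pi-periodic,
#' bounded in `[0, a_max]`, peaking at phase `-lag` (zero phase by default,
#' i.e. at the crest of the infra-slow oscillation).
#'
#' @param phase Phase (rad); vectorized. Non-finite phases map to the
#'   midpoint `a_max / 2` (degenerate-input fallback).
#' @param config A [controller_config()].
#' @return Amplitudes (mA), same length as `phase`.
#' @export
#' @examples
#' cfg <- controller_config()
#' phase_to_amplitude(0, cfg)    # a_max
#' phase_to_amplitude(pi, cfg)   # 0
phase_to_amplitude <- function(phase, config = controller_config()) {
  out <- config$a_max * (1 + cos(phase + config$phase_lag)) / 2
  out[!is.finite(phase)] <- config$a_max / 2
  out
}

#' Synthesize the stimulation command from an amplitude envelope
#'
#' `command(t) = envelope(t) * sin(2 pi carrier t)`, with the envelope held
#' piecewise constant between its samples (zero-order hold).
#'
#' @param envelope A tibble with columns `time` (s) and `amplitude` (mA,
#'   non-negative).
#' @param carrier_hz Carrier frequency (Hz); default 4.
#' @param fs Command sample rate (Hz); must exceed `2 * carrier_hz`.
#' @return A tibble with columns `time` (s), `amplitude` (held envelope) and
#'   `current_mA` (instantaneous command).
#' @export
synthesize_command <- function(envelope, carrier_hz = 4, fs = 100) {
  if (fs <= 2 * carrier_hz) {
    abort("command sample rate must exceed twice the carrier frequency",
          class = "cctcsim_nyquist_error")
  }
  if (any(envelope$amplitude < 0, na.rm = TRUE)) {
    abort("envelope amplitudes must be non-negative",
          class = "cctcsim_input_error")
  }
  t0 <- min(envelope$time)
  t1 <- max(envelope$time)
  tgrid <- seq(t0, t1, by = 1 / fs)
  amp <- approx(envelope$time, envelope$amplitude, xout = tgrid,
                method = "constant", rule = 2)$y
  tibble(time = tgrid, amplitude = amp,
         current_mA = amp * sin(2 * pi * carrier_hz * tgrid))
}

#' Run the closed-loop phase-amplitude-coupled controller
#'
#' Streaming composition of causal band-pass filtering, trailing-window
#' Hilbert phase estimation, the raised-cosine phase-to-amplitude map, and
#' carrier synthesis. The amplitude is updated every `update_s` seconds once
#' one full window of history is available (warm-up emits no stimulation);
#' gaps in the input stream (`NA` samples) hold the last amplitude and are
#' logged. The run is deterministic given the stream and configuration, and
#' the commanded current never exceeds `a_max` in magnitude.
#'
#' @param hbo Oxyhemoglobin stream: numeric vector, or tibble with columns
#'   `time` and `hbo`.
#' @param fs Stream sample rate (Hz); >= 1 Hz recommended.
#' @param config A [controller_config()].
#' @param prefiltered Set TRUE when `hbo` is already band-limited to the
#'   infra-slow band; otherwise a causal (forward-only) 2nd-order
#'   Butterworth band-pass is applied first.
#' @return A `closed_loop_log`: list with `commands` (time, amplitude,
#'   current_mA), `phase_log` (update times, phase, analytic amplitude,
#'   low_confidence flag), `gaps` (indices of held updates), and `config`.
#' @export
run_closed_loop <- function(hbo, fs, config = controller_config(),
                            prefiltered = FALSE) {
  if (is.data.frame(hbo)) hbo <- hbo$hbo
  n <- length(hbo)
  gaps <- which(!is.finite(hbo))
  x <- hbo
  if (length(gaps) > 0) {
    if (sum(is.finite(hbo)) < 2) {
      abort("stream contains too few valid samples", class = "cctcsim_input_error")
    }
    # causal fill: carry the last valid sample forward; leading gaps -> 0
    last <- 0
    for (i in seq_len(n)) {
      if (is.finite(x[i])) last <- x[i] else x[i] <- last
    }
  }
  if (!prefiltered) {
    bf <- signal::butter(2, c(config$band_lo, config$band_hi) / (fs / 2),
                         type = "pass")
    x <- as.numeric(signal::filter(bf, x))   # forward-only: causal
  }
  wlen <- round(config$window_s * fs)
  step <- max(1L, round(config$update_s * fs))
  if (n < wlen + step) {
    abort("stream shorter than warm-up window: no commands emitted",
          class = "cctcsim_warmup_error")
  }
  ph <- sliding_window_phase(x, fs, config$window_s, step = step,
                             band = c(0.8 * config$band_lo,
                                      1.1 * config$band_hi))
  # low-confidence (near-zero analytic amplitude) -> undefined phase
  win_rms <- vapply(ph$index, function(i) {
    w <- x[(i - wlen + 1):i]
    sqrt(mean((w - mean(w))^2))
  }, numeric(1))
  low_conf <- ph$amplitude < config$amp_floor * pmax(win_rms, .Machine$double.eps) |
    win_rms < .Machine$double.eps
  phase_eff <- ph$phase
  phase_eff[low_conf] <- NA_real_
  amp <- phase_to_amplitude(phase_eff, config)
  # gap handling: hold the previous amplitude across updates inside a gap
  gap_updates <- which(ph$index %in% unique(
    unlist(lapply(gaps, function(g) ph$index[ph$index >= g][1]))))
  if (length(gap_updates) > 0) {
    for (k in gap_updates) if (k > 1) amp[k] <- amp[k - 1]
  }
  amp <- pmin(pmax(amp, 0), config$a_max)
  envelope <- tibble(time = ph$time, amplitude = amp)
  commands <- synthesize_command(envelope, config$carrier_hz,
                                 config$command_fs)
  structure(list(commands = commands,
                 phase_log = tibble(time = ph$time, phase = ph$phase,
                                    analytic_amplitude = ph$amplitude,
                                    low_confidence = low_conf,
                                    amplitude = amp),
                 gaps = gaps, config = config),
            class = "closed_loop_log")
}

#' @export
print.closed_loop_log <- function(x, ...) {
  cat(sprintf("<closed_loop_log> %d amplitude updates, %d command samples, peak |current| = %.3g mA (a_max = %g)\n",
              nrow(x$phase_log), nrow(x$commands),
              max(abs(x$commands$current_mA)), x$config$a_max))
  if (length(x$gaps) > 0) cat("  stream gaps at", length(x$gaps), "samples\n")
  invisible(x)
}
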