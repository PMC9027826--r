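new_waveform <- function(time, current, fs, kind) {
  structure(tibble(time = time, current_mA = current),
            class = c("stim_waveform", class(tibble())),
            fs = fs, kind = kind)
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> kind = %s, fs = %g Hz, %d samples (%.3g s)\n",
              attr(x, "kind"), attr(x, "fs"), nrow(x), nrow(x) / attr(x, "fs")))
  NextMethod()
}

check_wave_args <- function(duration, fs, fmax = 0) {
  if (!is.finite(duration) || duration <= 0) {
    abort("duration must be positive", class = "cctcsim_input_error")
  }
  if (!is.finite(fs) || fs <= 0) {
    abort("sample rate must be positive", class = "cctcsim_input_error")
  }
  if (fs <= 2 * fmax) {
    abort(sprintf("sample rate %g Hz violates Nyquist for %g Hz content", fs, fmax),
          class = "cctcsim_nyquist_error")
  }
}

wave_time <- function(duration, fs) seq(0, round(duration * fs) - 1) / fs

#' Constant-current (tDCS) stimulation waveform
#'
#' @param amplitude Current (mA), >= 0.
#' @param duration Length (s).
#' @param fs Sample rate (Hz).
#' @return A `stim_waveform` tibble with columns `time` (s) and
#'   `current_mA`.
#' @export
#' @examples
#' w <- stim_tdcs(2, duration = 10, fs = 1000)
#' mean(w$current_mA)
stim_tdcs <- function(amplitude, duration, fs = 1000) {
  if (!is.finite(amplitude) || amplitude < 0) {
    abort("amplitude must be non-negative", class = "cctcsim_input_error")
  }
  check_wave_args(duration, fs)
  t <- wave_time(duration, fs)
  new_waveform(t, rep(amplitude, length(t)), fs, "tdcs")
}

#' Sinusoidal (tACS) stimulation waveform
#'
#' @param amplitude Peak current (mA), >= 0.
#' @param freq Stimulation frequency (Hz).
#' @param duration Length (s).
#' @param fs Sample rate (Hz); must exceed `2 * freq`.
#' @return A `stim_waveform` tibble.
#' @export
stim_tacs <- function(amplitude, freq, duration, fs = 1000) {
  if (!is.finite(amplitude) || amplitude < 0) {
    abort("amplitude must be non-negative", class = "cctcsim_input_error")
  }
  check_wave_args(duration, fs, fmax = freq)
  t <- wave_time(duration, fs)
  new_waveform(t, amplitude * sin(2 * pi * freq * t), fs, "tacs")
}

#' Temporal-interference (tTIS) two-carrier waveform
#'
#' Sum of two kHz sinusoidal carriers, `a1 sin(2 pi f1 t) + a2 sin(2 pi f2
#' t)`. For nearby carrier frequencies the summed field is amplitude
#' modulated at the beat (difference) frequency `|f2 - f1|`; with the
#' default 1 kHz / 1.063 kHz pair the beat is 63 Hz.
#'
#' @param a1,a2 Carrier amplitudes (mA), >= 0.
#' @param f1,f2 Carrier frequencies (Hz).
#' @param duration Length (s).
#' @param fs Sample rate (Hz); must exceed `2 * max(f1, f2)`. Default 100 kHz.
#' @return A `stim_waveform` tibble.
#' @export
#' @examples
#' w <- stim_ttis(1, 1000, 1, 1063, duration = 0.5)
stim_ttis <- function(a1, f1 = 1000, a2 = a1, f2 = 1063, duration,
                      fs = 1e5) {
  if (any(!is.finite(c(a1, a2))) || a1 < 0 || a2 < 0) {
    abort("carrier amplitudes must be non-negative", class = "cctcsim_input_error")
  }
  check_wave_args(duration, fs, fmax = max(f1, f2))
  if (f1 == f2) {
    warn("f1 equals f2: the carriers sum coherently and there is no beat")
  }
  t <- wave_time(duration, fs)
  new_waveform(t, a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t),
               fs, "ttis")
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of the analytic signal `x + i H(x)`; its modulus is the
#' instantaneous amplitude (envelope) and its argument the instantaneous
#' phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (any(!is.finite(x))) {
    abort("non-finite samples in analytic_signal()", class = "cctcsim_input_error")
  }
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a stimulation waveform
#'
#' Magnitude of the analytic signal. For a tTIS carrier pair with equal
#' amplitudes `A` the envelope follows `|2 A cos(pi (f2 - f1) t)|`, i.e. it
#' oscillates at the beat frequency.
#'
#' @param w A `stim_waveform` (or a tibble with `time` and `current_mA`).
#' @return A `stim_waveform`-like tibble with columns `time` and
#'   `current_mA` holding the non-negative envelope.
#' @export
extract_envelope <- function(w) {
  if (nrow(w) < 16) {
    abort("waveform too short for envelope extraction (need >= 16 samples)",
          class = "cctcsim_input_error")
  }
  env <- Mod(analytic_signal(w$current_mA))
  new_waveform(w$time, env, attr(w, "fs") %||% (1 / mean(diff(w$time))),
               paste0(attr(w, "kind") %||% "unknown", "_envelope"))
}

#' Effective stimulation drive delivered to the DCN
#'
#' Maps a stimulation current waveform onto the model-input drive of the deep
#' cerebellar nuclei. In `"direct"` mode the drive is `gain * current`,
#' appropriate for tDCS and low-frequency tACS that the population can follow.
#' In `"demodulated"` mode the kHz carriers are first reduced to their
#' mean-removed amplitude envelope (`gain * (envelope - mean(envelope))`),
#' modelling the neural mass as a low-pass demodulator that responds to the
#' beat-frequency amplitude modulation rather than the carriers themselves.
#' 5% of samples are trimmed at each edge of the envelope (and replaced by
#' the nearest interior value) before use, to suppress analytic-signal edge
#' artifacts.
#'
#' @param w A `stim_waveform`.
#' @param gain Model-input units per mA, > 0. Defaults to the parameter
#'   file's `dcn_gain_per_mA` when `params` is supplied.
#' @param mode `"direct"` or `"demodulated"`.
#' @param params Optional [cctc_parameters()] supplying the default gain.
#' @return A tibble with columns `time` (s) and `drive` (model-input units),
#'   suitable as the `drive` argument of [cctc_simulate()].
#' @export
#' @examples
#' w <- stim_ttis(1, 1000, 1, 1063, duration = 0.5)
#' d <- dcn_drive(w, gain = 10, mode = "demodulated")
dcn_drive <- function(w, gain = NULL, mode = c("direct", "demodulated"),
                      params = NULL) {
  mode <- match.arg(mode)
  if (is.null(gain)) {
    if (is.null(params)) {
      abort("supply `gain` or `params`", class = "cctcsim_input_error")
    }
    gain <- params$stimulation$dcn_gain_per_mA
  }
  if (!is.finite(gain) || gain <= 0) {
    abort("gain must be positive", class = "cctcsim_input_error")
  }
  if (mode == "direct") {
    return(tibble(time = w$time, drive = gain * w$current_mA))
  }
  fs <- attr(w, "fs") %||% (1 / mean(diff(w$time)))
  # warn when demodulation is pointless (no kHz-range content)
  spec <- welch_psd(w$current_mA - mean(w$current_mA), fs = fs,
                    segment_s = min(1, nrow(w) / fs / 2))
  hi <- spec$power[spec$frequency > 100]
  if (length(hi) == 0 || sum(hi) < 1e-6 * sum(spec$power)) {
    warn("demodulated mode on a waveform without super-100 Hz content; direct mode would be equivalent")
  }
  env <- extract_envelope(w)$current_mA
  n <- length(env)
  trim <- max(1, floor(0.05 * n))
  env[seq_len(trim)] <- env[trim + 1]
  env[(n - trim + 1):n] <- env[n - trim]
  tibble(time = w$time, drive = gain * (env - mean(env)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export or import a waveform as two-column CSV
#'
#' @param w A `stim_waveform`.
#' @param file Path to write to / read from.
#' @return `write_waveform_csv()` returns `file` invisibly;
#'   `read_waveform_csv()` returns a `stim_waveform`.
#' @export
write_waveform_csv <- function(w, file) {
  write.csv(as.data.frame(w), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(file) {
  d <- read.csv(file)
  fs <- 1 / mean(diff(d$time))
  new_waveform(d$time, d$current_mA, fs, "imported")
}
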