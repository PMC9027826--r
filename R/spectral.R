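#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-windowed, overlapping segments. The
#' spectrum is one-sided and scaled as a density so that the integral of the
#' PSD over frequency approximates the signal variance (Parseval).
#'
#' @param x Numeric sample sequence.
#' @param fs Sample rate (Hz).
#' @param segment_s Segment length (s); frequency resolution is
#'   `1 / segment_s`. Default 2 s.
#' @param overlap Overlap fraction between segments, in `[0, 1)`; default 0.5.
#' @param detrend Remove each segment's mean before windowing (default TRUE).
#' @return A `power_spectrum` tibble with columns `frequency` (Hz) and
#'   `power` (input-units^2 / Hz).
#' @export
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 40 * seq(0, 4, by = 1 / fs))
#' ps <- welch_psd(x, fs)
#' dominant_frequency(ps)
welch_psd <- function(x, fs, segment_s = 2, overlap = 0.5, detrend = TRUE) {
  if (any(!is.finite(x))) {
    abort("non-finite samples in welch_psd()", class = "cctcsim_input_error")
  }
  nseg <- round(segment_s * fs)
  if (nseg < 8) {
    abort("segment too short; increase segment_s or fs",
          class = "cctcsim_input_error")
  }
  if (length(x) < 2 * nseg) {
    abort(sprintf("series of %d samples is shorter than two %d-sample segments",
                  length(x), nseg), class = "cctcsim_input_error")
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  u <- sum(win^2)
  hop <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    if (detrend) seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * win))^2
  }
  acc <- acc / length(starts) / (fs * u)
  nf <- floor(nseg / 2) + 1
  pw <- acc[seq_len(nf)]
  # fold two-sided density into one-sided (all but DC and Nyquist doubled)
  if (nseg %% 2 == 0) {
    if (nf > 2) pw[2:(nf - 1)] <- 2 * pw[2:(nf - 1)]
  } else {
    if (nf > 1) pw[2:nf] <- 2 * pw[2:nf]
  }
  structure(tibble(frequency = (seq_len(nf) - 1) * fs / nseg, power = pw),
            class = c("power_spectrum", class(tibble())),
            fs = fs, resolution = fs / nseg)
}

#' PSD of one population of a simulated trajectory
#'
#' Discards a burn-in window, optionally decimates the trace to a target rate
#' (anti-aliased, via [signal::decimate()]), and applies [welch_psd()].
#'
#' @param traj A `cctc_trajectory` from [cctc_simulate()].
#' @param population One of [cctc_populations()]; default `"CTX"`.
#' @param burn_in Discarded initial transient (s); default 2.
#' @param target_fs Analysis sample rate (Hz); the trajectory is decimated by
#'   an integer factor to (approximately) this rate. Default 1000.
#' @param ... Passed to [welch_psd()].
#' @return A `power_spectrum` tibble.
#' @export
trajectory_psd <- function(traj, population = "CTX", burn_in = 2,
                           target_fs = 1000, ...) {
  if (!population %in% cctc_populations()) {
    abort(sprintf("unknown population '%s'", population),
          class = "cctcsim_input_error")
  }
  fs <- 1 / attr(traj, "dt")
  x <- traj[[population]][traj$time >= burn_in]
  q <- max(1, floor(fs / target_fs))
  if (q > 1) {
    x <- signal::decimate(x, q)
    fs <- fs / q
  }
  welch_psd(x, fs, ...)
}

#' Dominant frequency of a power spectrum
#'
#' Frequency of the maximum-power bin above a DC-exclusion threshold.
#'
#' @param ps A `power_spectrum` from [welch_psd()].
#' @param exclude_below Ignore bins below this frequency (Hz); default 1, to
#'   skip DC and slow drift.
#' @return The dominant frequency (Hz), or `NA_real_` (with a warning) when
#'   the spectrum carries no power above the threshold.
#' @export
dominant_frequency <- function(ps, exclude_below = 1) {
  keep <- ps$frequency >= exclude_below
  if (!any(keep)) {
    abort("spectrum empty above the exclusion frequency",
          class = "cctcsim_input_error")
  }
  pw <- ps$power[keep]
  if (all(pw <= 0) || sum(pw) == 0) {
    warn("no oscillation: spectrum carries no power above the exclusion frequency")
    return(NA_real_)
  }
  ps$frequency[keep][which.max(pw)]
}

#' Oscillation band definitions
#'
#' The conventional EEG rhythm bands used for classification, as half-open
#' intervals `(lower, upper]`: delta (0, 4], theta (4, 8], alpha (8, 13],
#' beta (13, 30], gamma (30, 100]. Gamma is strictly above 30 Hz; exactly
#' 30 Hz classifies as beta.
#'
#' @return A tibble with columns `band`, `lower`, `upper`.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         lower = c(0, 4, 8, 13, 30),
         upper = c(4, 8, 13, 30, 100))
}

#' Classify a frequency into an oscillation band
#'
#' @param f Frequency (Hz); vectorized.
#' @param bands Band table as from [eeg_bands()]; intervals are `(lower,
#'   upper]`.
#' @return Character vector of band names; `"out-of-range"` for frequencies
#'   outside every band.
#' @export
#' @examples
#' classify_band(c(20, 30, 40))
classify_band <- function(f, bands = eeg_bands()) {
  vapply(f, function(fi) {
    if (!is.finite(fi)) return(NA_character_)
    hit <- which(fi > bands$lower & fi <= bands$upper)
    if (length(hit) == 0) "out-of-range" else bands$band[hit[1]]
  }, character(1))
}

#' Detect an oscillation-band shift between two simulations
#'
#' Computes the dominant frequency of the chosen population in each
#' trajectory and reports whether the band label changed, in particular the
#' gamma-to-beta transition expected when a constant DCN drive is replaced by
#' a 63 Hz amplitude-modulated one.
#'
#' @param traj_a,traj_b `cctc_trajectory` objects (e.g. constant-drive and
#'   AM-drive runs).
#' @param population Population to analyse; default `"CTX"`.
#' @param burn_in Discarded transient (s); default 2. Both trajectories must
#'   retain at least 8 s after burn-in.
#' @param bands Band table; default [eeg_bands()].
#' @param ... Passed to [trajectory_psd()].
#' @return A one-row tibble: `freq_a`, `freq_b` (Hz), `from_band`,
#'   `to_band`, `shifted` (band changed at all) and `gamma_to_beta`.
#' @export
detect_band_shift <- function(traj_a, traj_b, population = "CTX",
                              burn_in = 2, bands = eeg_bands(), ...) {
  for (tr in list(traj_a, traj_b)) {
    if (!population %in% names(tr)) {
      abort(sprintf("trajectory lacks population '%s'", population),
            class = "cctcsim_input_error")
    }
    if (max(tr$time) - burn_in < 8) {
      abort("need >= 8 s of post-burn-in data in each trajectory",
            class = "cctcsim_input_error")
    }
  }
  fa <- dominant_frequency(trajectory_psd(traj_a, population, burn_in, ...))
  fb <- dominant_frequency(trajectory_psd(traj_b, population, burn_in, ...))
  ba <- classify_band(fa, bands)
  bb <- classify_band(fb, bands)
  tibble(population = population, freq_a = fa, freq_b = fb,
         from_band = ba, to_band = bb,
         shifted = !identical(ba, bb),
         gamma_to_beta = identical(ba, "gamma") && identical(bb, "beta"))
}

#' Export a spectrum as CSV
#'
#' @param ps A `power_spectrum`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_spectrum_csv <- function(ps, file) {
  write.csv(as.data.frame(ps), file, row.names = FALSE)
  invisible(file)
}
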