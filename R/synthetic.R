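#' Canonical double-gamma hemodynamic response shape
#'
#' Peak-normalized double-gamma function used as the ground-truth response of
#' the synthetic-session generator.
#'
#' @param t Time since onset (s).
#' @param peak_s Time-to-peak of the positive lobe (s); default 6.
#' @param under_s Time-to-peak of the undershoot (s); default 16.
#' @param ratio Undershoot amplitude ratio; default 1/6.
#' @return Response values, max 1.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, under_s = 16, ratio = 1 / 6) {
  a1 <- peak_s; a2 <- under_s
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    ratio * stats::dgamma(t, shape = a2, rate = 1)
  h[t < 0] <- 0
  h / max(h)
}

#' Default synthetic optode layout
#'
#' Ten long-separation channels (3.5 cm) spread over left/right prefrontal
#' cortex, sensorimotor cortex and left/right cerebellum, plus one
#' short-separation channel (0.8 cm) per optode group; every long channel
#' points at its nearest short channel for superficial regression.
#'
#' @return A channel tibble with columns `channel`, `region`,
#'   `separation_cm`, `type`, `short_partner`.
#' @export
default_channels <- function() {
  long <- tibble(
    channel = c("L-PFC-1", "L-PFC-2", "R-PFC-1", "R-PFC-2",
                "SMC-1", "SMC-2",
                "L-CER-1", "L-CER-2", "R-CER-1", "R-CER-2"),
    region = c("left-PFC", "left-PFC", "right-PFC", "right-PFC",
               "SMC", "SMC", "left-CER", "left-CER",
               "right-CER", "right-CER"),
    separation_cm = 3.5, type = "long",
    short_partner = c("S-PFC", "S-PFC", "S-PFC", "S-PFC",
                      "S-SMC", "S-SMC", "S-CER", "S-CER", "S-CER", "S-CER"))
  short <- tibble(
    channel = c("S-PFC", "S-SMC", "S-CER"),
    region = c("left-PFC", "SMC", "left-CER"),
    separation_cm = 0.8, type = "short",
    short_partner = NA_character_)
  dplyr::bind_rows(long, short)
}

#' Specification of a synthetic fNIRS session
#'
#' Collects every knob of the seeded generator: the block design (defaults to
#' 2.5 min baseline, 5 min stimulation, 2.5 min post), per-region
#' hemodynamic-response amplitude, infra-slow oscillation frequency and
#' amplitude, the shared superficial/systemic component, measurement noise,
#' and optional motion artifacts. The seed fixes the session bit-for-bit.
#'
#' @param seed Integer RNG seed.
#' @param fs Sample rate (Hz); default 10.
#' @param design Block design list `(baseline_s, stim_s, post_s)`; default
#'   150 / 300 / 150 s.
#' @param channels Channel table; default [default_channels()] (10 long
#'   channels at 3.5 cm over left/right PFC, SMC and left/right cerebellum,
#'   plus 3 short channels at 0.8 cm).
#' @param hrf_amplitude Peak ground-truth HbO response (M); a single value or
#'   a named vector per region. Default 5e-6 (constant-current-like).
#' @param hrf_peak_s,hrf_under_s Double-gamma shape parameters (s).
#' @param infraslow_freq Infra-slow oscillation frequency (Hz); must lie in
#'   `[0.01, 0.10]`. Default 0.05.
#' @param infraslow_amp Infra-slow HbO amplitude (M); default 1e-6.
#' @param superficial_amp Superficial/systemic component SD (M); default
#'   2e-6. The component is 0.01-0.5 Hz colored noise shared between
#'   co-located short and long channels. The session's signal-to-noise
#'   ratio is defined against this physiological interference as
#'   `snr = hrf_amplitude / (superficial_weight * superficial_amp)`; an
#'   SNR-1 session has superficial contamination in the long channels whose
#'   SD equals the response peak.
#' @param superficial_weight Weight of the superficial component in long
#'   channels; default 0.5.
#' @param noise_sd Per-sample white instrument noise SD in concentration
#'   units (M); default 2e-7.
#' @param motion_rate Motion artifacts per minute; default 0.
#' @param motion_magnitude Artifact amplitude in OD units; default 0.05.
#' @param hbr_ratio Ground-truth HbR = `-hbr_ratio * HbO`; default 0.3.
#' @return A `synth_session_spec` list.
#' @export
synth_session_spec <- function(seed = 1, fs = 10,
                               design = list(baseline_s = 150, stim_s = 300,
                                             post_s = 150),
                               channels = default_channels(),
                               hrf_amplitude = 5e-6,
                               hrf_peak_s = 6, hrf_under_s = 16,
                               infraslow_freq = 0.05, infraslow_amp = 1e-6,
                               superficial_amp = 2e-6,
                               superficial_weight = 0.5,
                               noise_sd = 2e-7,
                               motion_rate = 0, motion_magnitude = 0.05,
                               hbr_ratio = 0.3) {
  if (infraslow_freq < 0.01 || infraslow_freq > 0.10) {
    abort("infra-slow frequency must lie within 0.01-0.10 Hz",
          class = "cctcsim_input_error")
  }
  amps <- c(hrf_amplitude, infraslow_amp, superficial_amp, noise_sd,
            motion_magnitude)
  if (any(amps < 0)) {
    abort("amplitudes must be non-negative", class = "cctcsim_input_error")
  }
  if (nrow(channels) == 0) {
    abort("channel list must not be empty", class = "cctcsim_input_error")
  }
  structure(as.list(environment()), class = "synth_session_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic infra-slow oxyhemoglobin series
#'
#' A sinusoid (or narrow-band noise) at the configured infra-slow frequency
#' plus white measurement noise; the spectral peak lies inside 0.01-0.10 Hz.
#'
#' @param spec A [synth_session_spec()].
#' @param duration Length (s); defaults to the spec's total block length.
#' @param mode `"sinusoid"` (default) or `"narrowband"` (band-passed noise).
#' @return A tibble with columns `time`, `hbo`, `hbr` (M), with `fs`
#'   attribute.
#' @export
generate_infraslow_hbo <- function(spec = synth_session_spec(),
                                   duration = NULL,
                                   mode = c("sinusoid", "narrowband")) {
  mode <- match.arg(mode)
  duration <- duration %||%
    with(spec$design, baseline_s + stim_s + post_s)
  fs <- spec$fs
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  with_seed(spec$seed, {
    base <- if (mode == "sinusoid") {
      spec$infraslow_amp * sin(2 * pi * spec$infraslow_freq * t +
                                 stats::runif(1, 0, 2 * pi))
    } else {
      lo <- max(0.01, spec$infraslow_freq * 0.7)
      hi <- min(0.10, spec$infraslow_freq * 1.3)
      bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
      z <- as.numeric(signal::filtfilt(bf, stats::rnorm(length(t))))
      spec$infraslow_amp * z / stats::sd(z)
    }
    hbo <- base + stats::rnorm(length(t), 0, spec$noise_sd)
    structure(tibble(time = t, hbo = hbo, hbr = -spec$hbr_ratio * hbo),
              fs = fs, infraslow_freq = spec$infraslow_freq)
  })
}

region_amp <- function(spec, region) {
  a <- spec$hrf_amplitude
  if (is.null(names(a))) a[1] else if (region %in% names(a)) a[[region]] else 0
}

superficial_component <- function(n, fs, amp) {
  hi <- min(0.5, 0.45 * fs)
  bf <- signal::butter(2, c(0.01, hi) / (fs / 2), type = "pass")
  z <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
  amp * z / stats::sd(z)
}

#' Generate a complete synthetic two-wavelength fNIRS session
#'
#' Forward-models ground-truth hemoglobin concentrations through the modified
#' Beer-Lambert law into two-wavelength raw intensities. Long channels carry
#' a block-onset-locked hemodynamic response, a per-channel infra-slow
#' oscillation, a weighted copy of the superficial/systemic component shared
#' with their co-located short channel, and white noise; short channels carry
#' the superficial component and noise only. Optional motion artifacts are
#' injected in optical-density units. Ground truth is stored alongside for
#' recovery tests.
#'
#' @param spec A [synth_session_spec()].
#' @param constants [mbll_constants()] used for the forward model.
#' @return An `fnirs_session`: list with `channels`, `wavelengths`, `fs`,
#'   `design`, `intensity` (long tibble: time, channel, wavelength,
#'   intensity) and `truth` (list with per-channel concentration tibble,
#'   the ground-truth HRF, and the superficial components).
#' @export
generate_raw_session <- function(spec = synth_session_spec(),
                                 constants = mbll_constants()) {
  fs <- spec$fs
  design <- spec$design
  total <- design$baseline_s + design$stim_s + design$post_s
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  n <- length(t)
  channels <- spec$channels
  onset <- design$baseline_s
  hrf_shape <- hrf_double_gamma(t - onset, spec$hrf_peak_s, spec$hrf_under_s)

  with_seed(spec$seed, {
    sup_groups <- unique(stats::na.omit(channels$short_partner))
    sup <- stats::setNames(lapply(sup_groups, function(g) {
      superficial_component(n, fs, spec$superficial_amp)
    }), sup_groups)

    truth <- list(); rows <- list()
    for (i in seq_len(nrow(channels))) {
      ch <- channels$channel[i]
      is_long <- channels$type[i] == "long"
      amp <- region_amp(spec, channels$region[i])
      neural <- if (is_long) amp * hrf_shape else 0
      phase <- stats::runif(1, 0, 2 * pi)
      infra <- if (is_long) {
        spec$infraslow_amp * sin(2 * pi * spec$infraslow_freq * t + phase)
      } else 0
      sup_g <- if (is_long) {
        g <- channels$short_partner[i]
        if (!is.na(g)) spec$superficial_weight * sup[[g]] else 0
      } else {
        sup[[ch]] %||% superficial_component(n, fs, spec$superficial_amp)
      }
      hbo <- neural + infra + sup_g + stats::rnorm(n, 0, spec$noise_sd)
      hbr <- -spec$hbr_ratio * hbo
      od <- mbll_forward(hbo, hbr, channels$separation_cm[i], constants)
      # motion artifacts: brief square steps in OD, both wavelengths
      if (spec$motion_rate > 0) {
        n_ev <- stats::rpois(1, spec$motion_rate * total / 60)
        if (n_ev > 0) {
          starts <- sample.int(n - round(fs), n_ev, replace = TRUE)
          for (s0 in starts) {
            span <- s0:min(n, s0 + round(stats::runif(1, 0.2, 1) * fs))
            od[span, ] <- od[span, ] +
              spec$motion_magnitude * sample(c(-1, 1), 1)
          }
        }
      }
      i0 <- stats::runif(1, 0.5, 2)   # arbitrary source intensity
      for (w in seq_along(constants$wavelengths)) {
        rows[[paste(ch, w)]] <- tibble(
          time = t, channel = ch,
          wavelength = constants$wavelengths[w],
          intensity = i0 * 10^(-od[, w]))
      }
      truth[[ch]] <- tibble(time = t, channel = ch, hbo = hbo, hbr = hbr,
                            neural = neural, superficial = sup_g + 0 * t)
    }
    structure(list(channels = channels,
                   wavelengths = constants$wavelengths, fs = fs,
                   design = design,
                   intensity = dplyr::bind_rows(rows),
                   truth = list(concentrations = dplyr::bind_rows(truth),
                                hrf = tibble(
                                  time = seq(0, 20, by = 1 / fs),
                                  response = hrf_double_gamma(
                                    seq(0, 20, by = 1 / fs),
                                    spec$hrf_peak_s, spec$hrf_under_s)),
                                superficial = sup),
                   spec = spec),
              class = "fnirs_session")
  })
}

#' @export
print.fnirs_session <- function(x, ...) {
  cat(sprintf("<fnirs_session> %d channels (%d long, %d short), %g Hz, %g + %g + %g s blocks, wavelengths %s nm\n",
              nrow(x$channels), sum(x$channels$type == "long"),
              sum(x$channels$type == "short"), x$fs,
              x$design$baseline_s, x$design$stim_s, x$design$post_s,
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

#' Generate a session with hemisphere-specific post-intervention shifts
#'
#' Like [generate_raw_session()], but additionally injects a sustained mean
#' HbO shift over the post-intervention segment: `left_shift` in left-
#' hemisphere regions, `right_shift` in right-hemisphere regions, and their
#' mean in midline regions. Used to exercise the region-change statistic
#' under known null (equal shifts) and alternative (unequal) conditions.
#'
#' @param spec A [synth_session_spec()].
#' @param left_shift,right_shift Post-segment HbO shifts (M).
#' @param constants [mbll_constants()].
#' @return An `fnirs_session`.
#' @export
generate_region_contrast_session <- function(spec = synth_session_spec(),
                                             left_shift = 0,
                                             right_shift = 0,
                                             constants = mbll_constants()) {
  if (!all(is.finite(c(left_shift, right_shift)))) {
    abort("shifts must be finite", class = "cctcsim_input_error")
  }
  session <- generate_raw_session(spec, constants)
  design <- session$design
  onset_post <- design$baseline_s + design$stim_s
  shift_for <- function(region) {
    if (grepl("^left", region)) left_shift
    else if (grepl("^right", region)) right_shift
    else mean(c(left_shift, right_shift))
  }
  # apply the shift in concentration space and re-run the forward model
  intensity <- session$intensity
  for (i in seq_len(nrow(session$channels))) {
    if (session$channels$type[i] != "long") next
    ch <- session$channels$channel[i]
    sh <- shift_for(session$channels$region[i])
    if (sh == 0) next
    tt <- session$truth$concentrations
    rows <- tt$channel == ch
    post <- tt$time[rows] >= onset_post
    dhbo <- ifelse(post, sh, 0)
    session$truth$concentrations$hbo[rows] <-
      tt$hbo[rows] + dhbo
    session$truth$concentrations$hbr[rows] <-
      tt$hbr[rows] - spec$hbr_ratio * dhbo
    dod <- mbll_forward(dhbo, -spec$hbr_ratio * dhbo,
                        session$channels$separation_cm[i], constants)
    for (w in seq_along(session$wavelengths)) {
      sel <- intensity$channel == ch &
        intensity$wavelength == session$wavelengths[w]
      intensity$intensity[sel] <- intensity$intensity[sel] * 10^(-dod[, w])
    }
  }
  session$intensity <- intensity
  session
}
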