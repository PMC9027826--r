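#' Modified Beer-Lambert constants
#'
#' Loads the tabulated extinction coefficients (1/(M cm)) for oxy- and
#' deoxyhemoglobin at the requested wavelengths and combines them with the
#' differential pathlength factors. The shipped table covers the 760/850 nm
#' pair used by common continuous-wave devices.
#'
#' @param wavelengths Two wavelengths (nm); default `c(760, 850)`.
#' @param dpf Differential pathlength factor per wavelength; default 6.0 for
#'   both.
#' @param file Optional CSV with columns `wavelength_nm`, `hbo`, `hbr`;
#'   defaults to the shipped table.
#' @return An object of class `mbll_constants`: list with `wavelengths`,
#'   `dpf`, and the 2 x 2 extinction matrix `epsilon` (rows = wavelengths,
#'   columns = HbO, HbR).
#' @export
#' @examples
#' mbll_constants()$epsilon
mbll_constants <- function(wavelengths = c(760, 850), dpf = c(6, 6),
                           file = NULL) {
  if (length(wavelengths) != 2 || length(dpf) != 2) {
    abort("exactly two wavelengths (and DPFs) are required",
          class = "cctcsim_input_error")
  }
  if (any(dpf <= 0)) {
    abort("DPF must be positive", class = "cctcsim_input_error")
  }
  if (is.null(file)) {
    file <- system.file("extdata", "extinction_coefficients.csv",
                        package = "cctcsim", mustWork = TRUE)
  }
  tab <- read.csv(file)
  idx <- match(wavelengths, tab$wavelength_nm)
  if (any(is.na(idx))) {
    abort(sprintf("no extinction coefficients tabulated for %s nm",
                  paste(wavelengths[is.na(idx)], collapse = ", ")),
          class = "cctcsim_config_error")
  }
  eps <- as.matrix(tab[idx, c("hbo", "hbr")])
  dimnames(eps) <- list(paste0(wavelengths, "nm"), c("hbo", "hbr"))
  if (abs(det(eps)) < .Machine$double.eps * max(abs(eps))^2 ||
      kappa(eps) > 100) {
    abort("extinction matrix is singular or too ill-conditioned (condition number > 100)",
          class = "cctcsim_config_error")
  }
  structure(list(wavelengths = wavelengths, dpf = dpf, epsilon = eps),
            class = "mbll_constants")
}

od_attrs <- function(x, session) {
  structure(x, fs = attr(session, "fs") %||% session$fs,
            channels = session$channels, design = session$design,
            wavelengths = session$wavelengths)
}

#' Convert raw fNIRS intensities to optical density
#'
#' `OD(t) = -log10(I(t) / mean(I))` per channel and wavelength, so each OD
#' trace is mean-referenced (mean approximately 0) and invariant to uniform
#' intensity scaling.
#'
#' @param session An `fnirs_session` (see [generate_raw_session()] or
#'   [read_fnirs_csv()]).
#' @return A long tibble with columns `time`, `channel`, `wavelength`, `od`,
#'   carrying the session's channel table, design and sample rate as
#'   attributes.
#' @export
intensity_to_od <- function(session) {
  d <- session$intensity
  bad <- which(!is.finite(d$intensity) | d$intensity <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive intensity at channel %s, sample index %d",
                  d$channel[bad[1]], bad[1]),
          class = "cctcsim_input_error")
  }
  out <- d |>
    dplyr::group_by(.data$channel, .data$wavelength) |>
    dplyr::mutate(od = -log10(.data$intensity / mean(.data$intensity))) |>
    dplyr::ungroup() |>
    dplyr::select("time", "channel", "wavelength", "od")
  od_attrs(out, session)
}

flag_motion <- function(x, fs, amp_thresh, grad_thresh, window_s) {
  n <- length(x)
  sd_x <- sd(x)
  if (sd_x == 0) return(logical(n))
  dx <- c(0, diff(x))
  sd_d <- sd(dx)
  flags <- (abs(x - median(x)) > amp_thresh * sd_x) |
    (sd_d > 0 & abs(dx) > grad_thresh * sd_d * sqrt(max(1, window_s * fs)))
  if (!any(flags)) return(flags)
  # dilate flagged samples by the detection window
  half <- max(1, round(window_s * fs / 2))
  idx <- which(flags)
  for (i in idx) flags[max(1, i - half):min(n, i + half)] <- TRUE
  flags
}

motion_correct_series <- function(x, fs, amp_thresh, grad_thresh, window_s,
                                  sg_order, sg_window_s) {
  n <- length(x)
  nwin <- round(sg_window_s * fs)
  if (nwin %% 2 == 0) nwin <- nwin + 1
  if (nwin <= sg_order + 1) nwin <- sg_order + 3 - (sg_order %% 2)
  if (nwin >= n) {
    abort("smoothing window longer than the record",
          class = "cctcsim_input_error")
  }
  flags <- flag_motion(x, fs, amp_thresh, grad_thresh, window_s)
  if (any(flags) && sum(!flags) > 4) {
    good <- which(!flags)
    x[flags] <- spline(good, x[good], xout = which(flags), method = "natural")$y
  }
  signal::sgolayfilt(x, p = sg_order, n = nwin)
}

#' Motion-artifact correction of optical-density traces
#'
#' Hybrid spline / Savitzky-Golay scheme: samples whose amplitude exceeds
#' `amp_thresh` robust SDs, or whose sample-to-sample change exceeds
#' `grad_thresh` SDs of the differenced signal (scaled to the detection
#' window), are flagged as motion, replaced by natural-spline interpolation
#' from the surrounding clean samples, and the whole trace is then smoothed
#' with a Savitzky-Golay filter. Artifact-free traces pass through nearly
#' unchanged.
#'
#' @param od Long OD tibble from [intensity_to_od()], or a numeric vector
#'   (then `fs` is required).
#' @param fs Sample rate (Hz); taken from the attribute when `od` is the
#'   pipeline tibble.
#' @param amp_thresh Amplitude threshold (SD units); default 5.
#' @param grad_thresh Gradient threshold (SD units per detection window);
#'   default 3.
#' @param window_s Detection window (s); default 0.5.
#' @param sg_order Savitzky-Golay polynomial order; default 3.
#' @param sg_window_s Savitzky-Golay frame length (s); default 2.
#' @return Same shape as the input, with corrected OD.
#' @export
motion_correct <- function(od, fs = NULL, amp_thresh = 5, grad_thresh = 3,
                           window_s = 0.5, sg_order = 3, sg_window_s = 2) {
  if (is.numeric(od)) {
    if (is.null(fs)) abort("fs is required for a bare numeric series",
                           class = "cctcsim_input_error")
    return(motion_correct_series(od, fs, amp_thresh, grad_thresh, window_s,
                                 sg_order, sg_window_s))
  }
  fs <- fs %||% attr(od, "fs")
  out <- od |>
    dplyr::group_by(.data$channel, .data$wavelength) |>
    dplyr::mutate(od = motion_correct_series(.data$od, fs, amp_thresh,
                                             grad_thresh, window_s,
                                             sg_order, sg_window_s)) |>
    dplyr::ungroup()
  attributes(out)[c("fs", "channels", "design", "wavelengths")] <-
    attributes(od)[c("fs", "channels", "design", "wavelengths")]
  out
}

#' Zero-phase infra-slow band-pass filter
#'
#' Forward-backward (zero-phase) 2nd-order Butterworth band-pass, passing the
#' infra-slow hemodynamic band 0.01-0.10 Hz by default. DC and frequencies
#' twice above the upper edge are attenuated by more than 20 dB.
#'
#' @param x Numeric series.
#' @param fs Sample rate (Hz); must exceed `2 * hi`.
#' @param lo,hi Band edges (Hz); defaults 0.01 and 0.10.
#' @return Filtered series, same length.
#' @export
#' @examples
#' fs <- 5
#' t <- seq(0, 600, by = 1 / fs)
#' y <- bandpass_infraslow(sin(2 * pi * 0.05 * t), fs)
bandpass_infraslow <- function(x, fs, lo = 0.01, hi = 0.10) {
  if (fs <= 2 * hi) {
    abort("sample rate must exceed twice the upper band edge",
          class = "cctcsim_nyquist_error")
  }
  if (lo <= 0 || hi <= lo) {
    abort("need 0 < lo < hi", class = "cctcsim_input_error")
  }
  if (length(x) < 3 * fs / lo) {
    abort(sprintf("record of %d samples is shorter than three filter lengths (%d samples)",
                  length(x), ceiling(3 * fs / lo)),
          class = "cctcsim_input_error")
  }
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Band-pass the optical-density pipeline tibble
#'
#' Applies [bandpass_infraslow()] to every channel/wavelength trace.
#'
#' @param od Long OD tibble from [intensity_to_od()].
#' @inheritParams bandpass_infraslow
#' @return Same shape, filtered.
#' @export
bandpass_od <- function(od, lo = 0.01, hi = 0.10) {
  fs <- attr(od, "fs")
  out <- od |>
    dplyr::group_by(.data$channel, .data$wavelength) |>
    dplyr::mutate(od = bandpass_infraslow(.data$od, fs, lo, hi)) |>
    dplyr::ungroup()
  attributes(out)[c("fs", "channels", "design", "wavelengths")] <-
    attributes(od)[c("fs", "channels", "design", "wavelengths")]
  out
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to optical density at each
#' wavelength: `OD_lambda = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF_lambda`.
#' The exact inverse of [od_to_hemoglobin()].
#'
#' @param hbo,hbr Concentration-change series (M).
#' @param separation_cm Source-detector distance (cm).
#' @param constants An [mbll_constants()] object.
#' @return A matrix with one column per wavelength.
#' @export
mbll_forward <- function(hbo, hbr, separation_cm, constants = mbll_constants()) {
  eps <- constants$epsilon
  od <- cbind(hbo, hbr) %*% t(eps)       # columns = wavelengths
  sweep(od, 2, separation_cm * constants$dpf, `*`)
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel:
#' `[dHbO; dHbR] = eps^-1 [OD_l1 / (d DPF_1); OD_l2 / (d DPF_2)]`.
#'
#' @param od Long OD tibble from [intensity_to_od()] (optionally
#'   motion-corrected / band-passed).
#' @param constants An [mbll_constants()] object; its wavelengths must match
#'   the session's.
#' @return A `hemoglobin_series`: long tibble with columns `time`,
#'   `channel`, `region`, `type` (long/short), `hbo`, `hbr` (M), carrying
#'   `fs`, `channels` and `design` attributes.
#' @export
od_to_hemoglobin <- function(od, constants = mbll_constants()) {
  channels <- attr(od, "channels")
  wl <- attr(od, "wavelengths") %||% constants$wavelengths
  if (!setequal(wl, constants$wavelengths)) {
    abort("session wavelengths do not match the extinction table",
          class = "cctcsim_config_error")
  }
  eps_inv <- solve(constants$epsilon)
  wide <- od |>
    tidyr::pivot_wider(names_from = "wavelength", values_from = "od",
                       names_prefix = "wl")
  wlcols <- paste0("wl", constants$wavelengths)
  if (!all(wlcols %in% names(wide))) {
    abort("each channel needs OD at exactly the two configured wavelengths",
          class = "cctcsim_input_error")
  }
  wide <- dplyr::left_join(wide,
                           channels[, c("channel", "region", "type",
                                        "separation_cm")],
                           by = "channel")
  scaled <- cbind(wide[[wlcols[1]]] / (wide$separation_cm * constants$dpf[1]),
                  wide[[wlcols[2]]] / (wide$separation_cm * constants$dpf[2]))
  conc <- scaled %*% t(eps_inv)
  out <- tibble(time = wide$time, channel = wide$channel,
                region = wide$region, type = wide$type,
                hbo = conc[, 1], hbr = conc[, 2])
  structure(out, class = c("hemoglobin_series", class(out)),
            fs = attr(od, "fs"), channels = channels,
            design = attr(od, "design"))
}

gaussian_basis <- function(tgrid, onset, window_s, basis_sd, basis_step) {
  centers <- seq(0, window_s, by = basis_step)
  B <- vapply(centers, function(ck) {
    exp(-((tgrid - onset - ck)^2) / (2 * basis_sd^2))
  }, numeric(length(tgrid)))
  colnames(B) <- sprintf("gauss_%04.1fs", centers)
  list(B = B, centers = centers)
}

fit_one_channel <- function(y, B, drift, ss, label) {
  X <- cbind(B, drift)
  nms <- c(colnames(B), colnames(drift))
  if (!is.null(ss)) {
    ss_std <- if (stats::sd(ss) > 0) as.numeric(scale(ss)) else ss * 0
    X <- cbind(X, short_sep = ss_std)
    nms <- c(nms, "short_sep")
  }
  colnames(X) <- nms
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- nms[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient GLM design for channel %s; collinear columns: %s",
                  label, paste(dropped, collapse = ", ")),
          class = "cctcsim_glm_error")
  }
  fit <- lm.fit(X, y)
  list(beta = stats::setNames(fit$coefficients, nms),
       sigma2 = sum(fit$residuals^2) / (length(y) - ncol(X)),
       XtXinv_diag = diag(chol2inv(qr.R(qrX))))
}

#' Fit the block-design GLM with a Gaussian basis
#'
#' Ordinary-least-squares deconvolution of the hemodynamic response from the
#' stimulation-block onset, per long channel and chromophore, using a
#' consecutive sequence of Gaussian basis functions (default sd 0.5 s,
#' spacing 0.5 s over a 0-20 s response window), polynomial drift regressors,
#' and the nearest short-separation channel of the same chromophore as a
#' superficial-signal nuisance regressor.
#'
#' @param hb A `hemoglobin_series` from [od_to_hemoglobin()] (or a generator).
#' @param design Block design list `(baseline_s, stim_s, post_s)`; defaults
#'   to the series' design attribute.
#' @param basis_sd Gaussian sd (s); default 0.5.
#' @param basis_step Gaussian spacing (s); default 0.5.
#' @param window_s Response window after onset (s); default 20.
#' @param drift_order Polynomial drift order; default 3.
#' @param short_regression Include the nearest short-separation channel as a
#'   nuisance regressor (default TRUE).
#' @return A `cctc_glm` object: list with `hrf` (tibble: channel,
#'   chromophore, time, response), `coefficients` (tibble), `residual_var`,
#'   and the design description. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
glm_hrf <- function(hb, design = NULL, basis_sd = 0.5, basis_step = 0.5,
                    window_s = 20, drift_order = 3, short_regression = TRUE) {
  design <- design %||% attr(hb, "design")
  channels <- attr(hb, "channels")
  fs <- attr(hb, "fs")
  if (is.null(design) || is.null(fs)) {
    abort("hb must carry design and fs attributes (or pass design explicitly)",
          class = "cctcsim_input_error")
  }
  if (basis_step <= 0 || basis_sd <= 0 || window_s / basis_step > 1e3) {
    abort("basis_step and basis_sd must be positive and yield at most 1000 basis functions",
          class = "cctcsim_input_error")
  }
  onset <- design$baseline_s
  total <- design$baseline_s + design$stim_s + design$post_s
  if (onset + window_s > total) {
    abort("response window does not fit within the record",
          class = "cctcsim_input_error")
  }
  long_ch <- channels$channel[channels$type == "long"]
  tgrid <- sort(unique(hb$time))
  bas <- gaussian_basis(tgrid, onset, window_s, basis_sd, basis_step)
  drift <- cbind(intercept = rep(1, length(tgrid)),
                 stats::poly(tgrid, drift_order))
  colnames(drift) <- c("intercept", paste0("drift_", seq_len(drift_order)))
  hrf_grid <- seq(0, window_s, by = 1 / fs)
  Bh <- vapply(bas$centers, function(ck) {
    exp(-((hrf_grid - ck)^2) / (2 * basis_sd^2))
  }, numeric(length(hrf_grid)))

  wide <- hb |> dplyr::arrange(.data$channel, .data$time)
  res_hrf <- list(); res_coef <- list(); res_var <- list()
  for (ch in long_ch) {
    sub <- wide[wide$channel == ch, ]
    partner <- channels$short_partner[channels$channel == ch]
    ss_sub <- if (short_regression && !is.na(partner) && length(partner) == 1) {
      wide[wide$channel == partner, ]
    } else NULL
    for (chrom in c("hbo", "hbr")) {
      y <- sub[[chrom]]
      ss <- if (!is.null(ss_sub)) ss_sub[[chrom]] else NULL
      fit <- fit_one_channel(y, bas$B, drift, ss, label = ch)
      nb <- ncol(bas$B)
      hrf_est <- drop(Bh %*% fit$beta[seq_len(nb)])
      res_hrf[[paste(ch, chrom)]] <-
        tibble(channel = ch, chromophore = chrom, time = hrf_grid,
               response = hrf_est)
      res_coef[[paste(ch, chrom)]] <-
        tibble(channel = ch, chromophore = chrom,
               term = names(fit$beta), estimate = unname(fit$beta),
               std.error = sqrt(fit$sigma2 * fit$XtXinv_diag))
      res_var[[paste(ch, chrom)]] <-
        tibble(channel = ch, chromophore = chrom, sigma2 = fit$sigma2)
    }
  }
  structure(list(hrf = dplyr::bind_rows(res_hrf),
                 coefficients = dplyr::bind_rows(res_coef),
                 residual_var = dplyr::bind_rows(res_var),
                 design = list(block = design, basis_sd = basis_sd,
                               basis_step = basis_step, window_s = window_s,
                               drift_order = drift_order,
                               n_basis = length(bas$centers),
                               short_regression = short_regression),
                 fs = fs),
            class = "cctc_glm")
}

#' @export
print.cctc_glm <- function(x, ...) {
  cat(sprintf("<cctc_glm> %d channels x 2 chromophores, %d Gaussian basis functions (sd %.2g s, step %.2g s), drift order %d, short-separation regression: %s\n",
              length(unique(x$hrf$channel)), x$design$n_basis,
              x$design$basis_sd, x$design$basis_step, x$design$drift_order,
              x$design$short_regression))
  invisible(x)
}

#' Region-wise post- vs pre-intervention hemoglobin change
#'
#' For each long channel, the change statistic is the mean oxyhemoglobin
#' concentration over the post-intervention segment minus the mean over the
#' pre-intervention baseline. Channel values are averaged into regions for
#' reporting, and the left- vs right-hemisphere channel values are compared
#' with a two-sample Welch test at level `alpha`.
#'
#' @param hb A `hemoglobin_series`.
#' @param design Block design `(baseline_s, stim_s, post_s)`; both baseline
#'   and post segments must be at least 60 s.
#' @param alpha Significance level; default 0.01.
#' @param chromophore `"hbo"` (default) or `"hbr"`.
#' @return A `region_change` object: list with `channels` (per-channel
#'   change), `regions` (region means), `test` (the `htest`), `alpha`, and
#'   `significant`.
#' @export
post_pre_change <- function(hb, design = NULL, alpha = 0.01,
                            chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  design <- design %||% attr(hb, "design")
  if (is.null(design)) {
    abort("design required", class = "cctcsim_input_error")
  }
  if (design$baseline_s < 60 || design$post_s < 60) {
    abort("baseline and post segments must each be at least 60 s",
          class = "cctcsim_input_error")
  }
  onset_post <- design$baseline_s + design$stim_s
  pre <- hb$time < design$baseline_s
  post <- hb$time >= onset_post
  if (!any(pre) || !any(post)) {
    abort("empty pre or post segment", class = "cctcsim_input_error")
  }
  long <- hb[hb$type == "long", ]
  per_channel <- long |>
    dplyr::group_by(.data$channel, .data$region) |>
    dplyr::summarise(
      change = mean(.data[[chromophore]][.data$time >= onset_post]) -
        mean(.data[[chromophore]][.data$time < design$baseline_s]),
      .groups = "drop")
  regions <- per_channel |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(change = mean(.data$change), n_channels = dplyr::n(),
                     .groups = "drop")
  left <- per_channel$change[grepl("^left", per_channel$region)]
  right <- per_channel$change[grepl("^right", per_channel$region)]
  test <- if (length(left) >= 2 && length(right) >= 2) {
    # degenerate (constant) data cannot be tested; report no decision
    tryCatch(t.test(left, right), error = function(e) NULL)
  } else NULL
  structure(list(channels = per_channel, regions = regions, test = test,
                 alpha = alpha,
                 significant = if (!is.null(test)) test$p.value < alpha else NA,
                 chromophore = chromophore),
            class = "region_change")
}

#' @export
print.region_change <- function(x, ...) {
  cat(sprintf("<region_change> %s, post - pre change by region:\n", x$chromophore))
  print(x$regions)
  if (!is.null(x$test)) {
    cat(sprintf("left vs right hemisphere: Welch t = %.3g, p = %.3g (alpha = %g) -> %s\n",
                x$test$statistic, x$test$p.value, x$alpha,
                if (x$significant) "different" else "not different"))
  }
  invisible(x)
}

#' One-call fNIRS preprocessing chain
#'
#' Intensity to optical density, motion correction, optional infra-slow
#' band-pass, and conversion to hemoglobin concentration changes.
#'
#' @param session An `fnirs_session`.
#' @param bandpass Apply the 0.01-0.10 Hz band-pass (default FALSE; sustained
#'   post-intervention shifts would be removed by it, so the change analysis
#'   runs on unfiltered concentrations).
#' @param motion Apply motion correction (default TRUE).
#' @param constants [mbll_constants()].
#' @param ... Passed to [motion_correct()].
#' @return A `hemoglobin_series`.
#' @export
fnirs_preprocess <- function(session, bandpass = FALSE, motion = TRUE,
                             constants = mbll_constants(), ...) {
  od <- intensity_to_od(session)
  if (motion) od <- motion_correct(od, ...)
  if (bandpass) od <- bandpass_od(od)
  od_to_hemoglobin(od, constants)
}
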