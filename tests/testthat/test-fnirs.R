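tiny_session <- function(intensity_fun, fs = 10, dur = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  channels <- tibble::tibble(channel = "A", region = "left-PFC",
                             separation_cm = 3.5, type = "long",
                             short_partner = NA_character_)
  rows <- dplyr::bind_rows(lapply(c(760, 850), function(wl) {
    tibble::tibble(time = t, channel = "A", wavelength = wl,
                   intensity = intensity_fun(t, wl))
  }))
  structure(list(channels = channels, wavelengths = c(760, 850), fs = fs,
                 design = list(baseline_s = 2, stim_s = 5, post_s = 3),
                 intensity = rows, truth = NULL),
            class = "fnirs_session")
}

test_that("optical density conversion is mean-referenced and scale-invariant", {
  ses <- tiny_session(function(t, wl) rep(1.7, length(t)))
  od <- intensity_to_od(ses)
  expect_equal(od$od, rep(0, nrow(od)))
  # halving the intensity at one sample gives OD log10(2) there
  ses2 <- tiny_session(function(t, wl) c(rep(1, 50), 0.5, rep(1, 49)))
  od2 <- intensity_to_od(ses2)
  x <- od2$od[od2$wavelength == 760]
  ref <- -log10(1 / mean(c(rep(1, 50), 0.5, rep(1, 49))))
  expect_equal(x[51] - ref, log10(2), tolerance = 1e-12)
  # uniform scaling leaves OD unchanged
  ses3 <- tiny_session(function(t, wl) 2 * c(rep(1, 50), 0.5, rep(1, 49)))
  expect_equal(intensity_to_od(ses3)$od, od2$od, tolerance = 1e-12)
  ses_bad <- tiny_session(function(t, wl) c(rep(1, 99), 0))
  expect_error(intensity_to_od(ses_bad), class = "cctcsim_input_error",
               regexp = "channel A")
})

test_that("motion correction passes clean data and suppresses step artifacts", {
  fs <- 5
  t <- seq(0, 120, by = 1 / fs)
  clean <- sin(2 * pi * 0.1 * t)
  out <- motion_correct(clean, fs = fs)
  expect_lt(sqrt(mean((out - clean)^2)), 0.01 * sd(clean))
  # no samples flagged on constant input (output is constant too)
  const_out <- motion_correct(rep(3, length(t)), fs = fs)
  expect_equal(const_out, rep(3, length(t)), tolerance = 1e-9)
  # a 10-SD step artifact is strongly attenuated
  artifact <- clean
  span <- 300:305
  artifact[span] <- artifact[span] + 10 * sd(clean)
  corrected <- motion_correct(artifact, fs = fs)
  before <- max(abs(artifact - clean))
  after <- max(abs(corrected - clean))
  expect_gt(before / after, 5)
  expect_error(motion_correct(rnorm(5), fs = 5, sg_window_s = 10),
               class = "cctcsim_input_error")
})

test_that("the infra-slow band-pass has the specified transfer and is linear", {
  fs <- 5
  t <- seq(0, 900, by = 1 / fs)
  gain_at <- function(f) {
    y <- bandpass_infraslow(sin(2 * pi * f * t), fs)
    m <- length(y) %/% 2
    sd(y[(m - 1000):(m + 1000)]) / sd(sin(2 * pi * f * t))
  }
  g_center <- gain_at(0.05)
  expect_gt(g_center, 0.89)
  expect_lt(g_center, 1.12)
  expect_lt(gain_at(1), 10^(-20 / 20))        # > 20 dB down
  expect_lt(gain_at(0.005), 10^(-20 / 20))    # 0.5x lower edge
  expect_lt(gain_at(0.2), 10^(-20 / 20))      # 2x upper edge
  dc <- bandpass_infraslow(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[2000:2500])), 0.05)
  # linearity
  set.seed(4)
  x <- rnorm(length(t)); y <- rnorm(length(t))
  lhs <- bandpass_infraslow(2 * x + 3 * y, fs)
  rhs <- 2 * bandpass_infraslow(x, fs) + 3 * bandpass_infraslow(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(bandpass_infraslow(rnorm(100), fs = 5),
               class = "cctcsim_input_error")
  expect_error(bandpass_infraslow(rnorm(10000), fs = 0.15),
               class = "cctcsim_nyquist_error")
})

test_that("the modified Beer-Lambert law round-trips exactly", {
  const <- mbll_constants()
  hbo <- c(5e-6, 2e-6, 0)
  hbr <- c(-1e-6, 0.5e-6, 0)
  od <- mbll_forward(hbo, hbr, 3.5, const)
  # rebuild the pipeline tibble and invert
  odt <- dplyr::bind_rows(lapply(1:2, function(w) {
    tibble::tibble(time = seq_along(hbo), channel = "A",
                   wavelength = const$wavelengths[w], od = od[, w])
  }))
  channels <- tibble::tibble(channel = "A", region = "left-PFC",
                             separation_cm = 3.5, type = "long",
                             short_partner = NA_character_)
  odt <- structure(odt, fs = 1, channels = channels,
                   design = NULL, wavelengths = const$wavelengths)
  hb <- od_to_hemoglobin(odt, const)
  expect_equal(hb$hbo, hbo, tolerance = 1e-12)
  expect_equal(hb$hbr, hbr, tolerance = 1e-12)
  # zero OD maps to zero concentrations
  odt0 <- odt; odt0$od <- 0
  hb0 <- od_to_hemoglobin(odt0, const)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))
  # swapping wavelength order with consistently swapped rows changes nothing
  const_sw <- const
  const_sw$wavelengths <- rev(const$wavelengths)
  const_sw$dpf <- rev(const$dpf)
  const_sw$epsilon <- const$epsilon[2:1, ]
  hb_sw <- od_to_hemoglobin(odt, const_sw)
  expect_equal(hb_sw$hbo, hb$hbo, tolerance = 1e-12)
  # a singular extinction matrix is a configuration error
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = c(760, 850),
                       hbo = c(1000, 1000), hbr = c(2000, 2000)),
            f, row.names = FALSE)
  expect_error(mbll_constants(file = f), class = "cctcsim_config_error")
})

test_that("the GLM recovers an injected HRF and short-separation regression helps", {
  r <- hrf_recovery_cor(seed = 101)
  expect_gt(r, 0.95)
  # zero-signal channels give coefficients indistinguishable from zero
  spec0 <- synth_session_spec(seed = 5, fs = 5, hrf_amplitude = 0,
                              superficial_amp = 0, infraslow_amp = 0,
                              noise_sd = 1e-7)
  hb0 <- fnirs_preprocess(generate_raw_session(spec0), motion = FALSE)
  fit0 <- glm_hrf(hb0)
  co <- tidy(fit0)
  basis <- co[grepl("^gauss", co$term) & co$chromophore == "hbo", ]
  expect_gt(mean(abs(basis$estimate) < 3 * basis$std.error), 0.95)
  # short-separation regression reduces HRF error on contaminated data
  spec <- synth_session_spec(seed = 6, fs = 5, hrf_amplitude = 5e-6,
                             superficial_amp = 1e-5, infraslow_amp = 0,
                             noise_sd = 2e-7)
  ses <- generate_raw_session(spec)
  hb <- fnirs_preprocess(ses, motion = FALSE)
  truth <- ses$truth$hrf
  rmse_of <- function(fit) {
    d <- fit$hrf[fit$hrf$chromophore == "hbo", ]
    tr <- 5e-6 * truth$response[match(round(d$time, 6), round(truth$time, 6))]
    sqrt(mean((d$response - tr)^2))
  }
  expect_lt(rmse_of(glm_hrf(hb)),
            rmse_of(glm_hrf(hb, short_regression = FALSE)))
  # a degenerate (constant-zero) short channel makes the design rank
  # deficient, reported with the offending column
  spec_z <- synth_session_spec(seed = 7, fs = 5, hrf_amplitude = 5e-6,
                               superficial_amp = 0, infraslow_amp = 0,
                               noise_sd = 0)
  hb_z <- fnirs_preprocess(generate_raw_session(spec_z), motion = FALSE)
  expect_error(glm_hrf(hb_z), class = "cctcsim_glm_error",
               regexp = "short_sep")
  expect_error(glm_hrf(hb, basis_step = -1), class = "cctcsim_input_error")
})

test_that("post-pre change statistics behave under null and alternative shifts", {
  # identical pre/post: change is (nearly) zero without noise
  spec0 <- synth_session_spec(seed = 9, fs = 2, hrf_amplitude = 0,
                              superficial_amp = 0, infraslow_amp = 0,
                              noise_sd = 0)
  hb0 <- fnirs_preprocess(generate_raw_session(spec0), motion = FALSE)
  pp0 <- post_pre_change(hb0, attr(hb0, "design"))
  expect_equal(pp0$channels$change, rep(0, nrow(pp0$channels)),
               tolerance = 1e-12)
  # equal bilateral shifts: no left/right difference
  spec <- synth_session_spec(seed = 10, fs = 2, hrf_amplitude = 0)
  ses_null <- generate_region_contrast_session(spec, 5e-6, 5e-6)
  hb_null <- fnirs_preprocess(ses_null, motion = FALSE)
  pp_null <- post_pre_change(hb_null)
  expect_false(pp_null$significant)
  expect_equal(mean(pp_null$channels$change), 5e-6, tolerance = 0.02)
  # unequal shifts with an adequate channel count are detected
  many <- dplyr::bind_rows(lapply(1:8, function(i) {
    tibble::tibble(
      channel = c(sprintf("L%d", i), sprintf("R%d", i)),
      region = c("left-PFC", "right-PFC"),
      separation_cm = 3.5, type = "long", short_partner = NA_character_)
  }))
  spec_alt <- synth_session_spec(seed = 11, fs = 2, hrf_amplitude = 0,
                                 channels = many, superficial_amp = 0)
  ses_alt <- generate_region_contrast_session(spec_alt, 1e-7, 3e-7)
  hb_alt <- fnirs_preprocess(ses_alt, motion = FALSE)
  pp_alt <- post_pre_change(hb_alt)
  expect_true(pp_alt$significant)
  expect_error(post_pre_change(hb_alt, design = list(baseline_s = 30,
                                                     stim_s = 300,
                                                     post_s = 30)),
               class = "cctcsim_input_error")
})

test_that("fNIRS sessions round-trip through the CSV + YAML fallback format", {
  spec <- synth_session_spec(seed = 12, fs = 2)
  ses <- generate_raw_session(spec)
  prefix <- withr::local_tempfile()
  write_fnirs_csv(ses, prefix)
  back <- read_fnirs_csv(prefix)
  expect_equal(back$fs, ses$fs)
  expect_equal(back$design$stim_s, ses$design$stim_s)
  expect_equal(sort(back$channels$channel), sort(ses$channels$channel))
  expect_equal(back$intensity$intensity, ses$intensity$intensity,
               tolerance = 1e-12)
})
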