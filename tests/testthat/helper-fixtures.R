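# Shared fixtures, memoized so expensive simulations run once per session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

default_params <- function() memo("params", cctc_parameters())

# 12 s constant-drive (tDCS-like) run at the reference operating point
gamma_run <- function() {
  memo("gamma_run", {
    p <- default_params()
    drive <- p$stimulation$dcn_gain_per_mA * p$stimulation$tdcs_reference_mA
    cctc_simulate(p, drive = drive, duration = 12)
  })
}

# 12 s run driven by the demodulated 63 Hz tTIS beat envelope
beta_run <- function() {
  memo("beta_run", {
    p <- default_params()
    w <- stim_ttis(1, 1000, 1, 1063, duration = 12, fs = 2e4)
    d <- dcn_drive(w, gain = p$stimulation$dcn_gain_per_mA,
                   mode = "demodulated")
    cctc_simulate(p, drive = d, duration = 12)
  })
}

# wrap a plain numeric series as a trajectory-like object for spectral tests
fake_trajectory <- function(x, fs, population = "CTX") {
  d <- tibble::tibble(time = seq_along(x) / fs, !!population := x)
  structure(d, class = c("cctc_trajectory", class(tibble::tibble())),
            dt = 1 / fs, method = "synthetic", drive_label = "synthetic")
}

# circular correlation (Fisher-Lee) between two phase sequences
circular_cor <- function(a, b) {
  mu_a <- Arg(sum(exp(1i * a)))
  mu_b <- Arg(sum(exp(1i * b)))
  num <- sum(sin(a - mu_a) * sin(b - mu_b))
  num / sqrt(sum(sin(a - mu_a)^2) * sum(sin(b - mu_b)^2))
}

# median HbO HRF recovery correlation for one seeded SNR-1 session
hrf_recovery_cor <- function(seed, fs = 5) {
  spec <- synth_session_spec(seed = seed, fs = fs, hrf_amplitude = 5e-6,
                             superficial_amp = 1e-5, superficial_weight = 0.5,
                             infraslow_amp = 0, noise_sd = 2e-7)
  ses <- generate_raw_session(spec)
  hb <- fnirs_preprocess(ses, motion = FALSE)
  fit <- glm_hrf(hb)
  truth <- ses$truth$hrf
  hbo <- fit$hrf[fit$hrf$chromophore == "hbo", ]
  cors <- vapply(split(hbo, hbo$channel), function(d) {
    stats::cor(d$response,
               truth$response[match(round(d$time, 6), round(truth$time, 6))])
  }, numeric(1))
  stats::median(cors)
}
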