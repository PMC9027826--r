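#' Logistic rate transfer function
#'
#' Converts net synaptic drive into a population firing rate through the
#' logistic sigmoid `max_rate / (1 + exp(-slope * (x - threshold)))`. The
#' output is strictly between 0 and `max_rate` and monotone in the input.
#'
#' @param x Net drive (model-input units); any numeric vector.
#' @param max_rate Saturation rate (spikes/s), > 0.
#' @param slope Sigmoid slope, > 0.
#' @param threshold Half-activation input; the output at `x = threshold` is
#'   `max_rate / 2`.
#' @return Firing rates, same length as `x`.
#' @export
#' @examples
#' sigmoid_rate(0, max_rate = 100, slope = 0.1, threshold = 0)  # 50
sigmoid_rate <- function(x, max_rate, slope, threshold = 0) {
  if (any(!is.finite(x))) {
    abort("non-finite input to sigmoid_rate()", class = "cctcsim_input_error")
  }
  if (max_rate <= 0 || slope <= 0) {
    abort("max_rate and slope must be positive", class = "cctcsim_input_error")
  }
  max_rate / (1 + exp(-slope * (x - threshold)))
}

state_vector <- function(state) {
  pops <- cctc_populations()
  if (is.null(names(state))) {
    if (length(state) != 7) {
      abort("state must have 7 elements", class = "cctcsim_input_error")
    }
    stats::setNames(as.numeric(state), pops)
  } else {
    if (!setequal(names(state), pops)) {
      abort("state names must be the 7 population labels",
            class = "cctcsim_input_error")
    }
    as.numeric(state[pops]) |> stats::setNames(pops)
  }
}

#' Time derivatives of the seven-population CCTC model
#'
#' Evaluates `d r_j / dt = (-r_j + S_j(sum_i W[i,j] r_i + background_j +
#' drive_j)) / tau_j`, where the external stimulation drive enters at the DCN
#' only.
#'
#' @param state Named (or canonically ordered) numeric vector of 7 firing
#'   rates (spikes/s).
#' @param params A [cctc_parameters()] object.
#' @param dcn_drive External drive to the DCN, in model-input units.
#' @return Named numeric vector of derivatives (spikes/s per s).
#' @export
cctc_derivatives <- function(state, params, dcn_drive = 0) {
  validate_cctc_parameters(params)
  r <- state_vector(state)
  tab <- params$populations
  if (any(r < 0) || any(r > tab$max_rate)) {
    abort("rates must lie within [0, max_rate] for every population",
          class = "cctcsim_input_error")
  }
  x <- drop(crossprod(params$W, r)) + params$background
  x["DCN"] <- x["DCN"] + dcn_drive
  s <- vapply(seq_len(7), function(j) {
    sigmoid_rate(x[j], tab$max_rate[j], tab$slope[j], tab$threshold[j])
  }, numeric(1))
  stats::setNames((-r + s) / tab$tau, tab$population)
}

#' Decoupled fixed point of the model
#'
#' The state each population would relax to if all connections were removed:
#' `S_j(background_j)`. Used as the default, seed-independent initial state.
#'
#' @param params A [cctc_parameters()] object.
#' @return Named numeric vector of 7 rates.
#' @export
decoupled_fixed_point <- function(params) {
  tab <- params$populations
  stats::setNames(vapply(seq_len(7), function(j) {
    sigmoid_rate(tab$background[j], tab$max_rate[j], tab$slope[j],
                 tab$threshold[j])
  }, numeric(1)), tab$population)
}

resolve_drive <- function(drive, n_steps, dt, gain = 1) {
  tgrid <- seq(0, n_steps) * dt
  if (is.function(drive)) {
    v <- drive(tgrid)
    if (length(v) == 1) v <- rep(v, length(tgrid))
  } else if (is.data.frame(drive)) {
    cols <- intersect(c("drive", "current_mA"), names(drive))
    if (!"time" %in% names(drive) || length(cols) == 0) {
      abort("a drive data frame needs columns `time` and `drive` (or `current_mA`)",
            class = "cctcsim_input_error")
    }
    if (max(drive$time) < tgrid[length(tgrid)] - dt / 2) {
      abort("drive sampling does not cover the full integration window",
            class = "cctcsim_input_error")
    }
    v <- approx(drive$time, drive[[cols[1]]] * gain, xout = tgrid,
                rule = 2)$y
  } else if (is.numeric(drive) && length(drive) == 1) {
    v <- rep(drive, length(tgrid))
  } else if (is.numeric(drive) && length(drive) == n_steps + 1) {
    v <- as.numeric(drive)
  } else {
    abort("drive must be a scalar, a function of time, a sampled vector on the step grid, or a (time, drive) data frame",
          class = "cctcsim_input_error")
  }
  if (any(!is.finite(v))) {
    abort("drive contains non-finite values", class = "cctcsim_input_error")
  }
  v
}

#' Integrate the CCTC loop model
#'
#' Fixed-step integration (4th-order Runge-Kutta by default) of the
#' seven-population rate model under an external DCN drive. The run is fully
#' deterministic given `(params, drive, dt, init)`.
#'
#' @param params A [cctc_parameters()] object.
#' @param drive External DCN drive in model-input units: a scalar, a
#'   function of time, a numeric vector sampled on the step grid, or a data
#'   frame with columns `time` and `drive` (e.g. from [dcn_drive()]), which is
#'   linearly interpolated onto the step grid.
#' @param duration Simulated time (s).
#' @param dt Integration step (s); default 1e-4 (0.1 ms).
#' @param init Initial state; defaults to the decoupled fixed point.
#' @param method `"rk4"` (default) or `"euler"`.
#' @return A `cctc_trajectory`: a tibble with a `time` column and one rate
#'   column per population, plus attributes `dt`, `method` and `drive_label`.
#' @export
#' @examples
#' p <- cctc_parameters()
#' traj <- cctc_simulate(p, drive = 20, duration = 0.5)
#' head(traj)
cctc_simulate <- function(params, drive = 0, duration, dt = 1e-4,
                          init = NULL, method = c("rk4", "euler")) {
  method <- match.arg(method)
  validate_cctc_parameters(params)
  if (!is.finite(duration) || duration <= 0) {
    abort("duration must be positive", class = "cctcsim_input_error")
  }
  if (!is.finite(dt) || dt <= 0) {
    abort("dt must be positive", class = "cctcsim_input_error")
  }
  n_steps <- round(duration / dt)
  if (is.null(init)) init <- decoupled_fixed_point(params)
  r0 <- state_vector(init)
  dvec <- resolve_drive(drive, n_steps, dt)
  tab <- params$populations
  mat <- cctc_integrate_cpp(r0, params$W, tab$tau, tab$max_rate, tab$slope,
                            tab$threshold, tab$background, dvec, dt,
                            dcn_index = which(tab$population == "DCN") - 1L,
                            method = if (method == "euler") 1L else 0L)
  colnames(mat) <- tab$population
  out <- as_tibble(as.data.frame(mat))
  out <- tibble(time = seq(0, n_steps) * dt, !!!out)
  structure(out,
            class = c("cctc_trajectory", class(out)),
            dt = dt, method = method,
            drive = dvec,
            drive_label = if (is.numeric(drive) && length(drive) == 1) {
              sprintf("constant %.3g", drive)
            } else "sampled")
}

#' @export
print.cctc_trajectory <- function(x, ...) {
  cat(sprintf("<cctc_trajectory> %d samples, dt = %g s, %s drive, method %s\n",
              nrow(x), attr(x, "dt"), attr(x, "drive_label"),
              attr(x, "method")))
  NextMethod()
}

#' Baseline operating state of the model
#'
#' Integrates the unforced model from the decoupled fixed point, discards a
#' burn-in window, and reports either the fixed point it converged to (when
#' the post-burn-in derivative norm falls below `tol`) or, for oscillatory
#' regimes, the time-averaged state over the post-burn-in window.
#'
#' @param params A [cctc_parameters()] object.
#' @param duration Total integration time (s); default 12.
#' @param dt Step (s); default 1e-4.
#' @param burn_in Discarded transient (s); default 2.
#' @param tol Derivative residual norm below which the final state is
#'   declared a fixed point; default 1e-9.
#' @return A list with `state` (named rates), `type` (`"fixed_point"` or
#'   `"oscillatory"`), and `residual` (final derivative norm, spikes/s per s).
#' @export
#' @examples
#' b <- cctc_baseline(cctc_parameters(), duration = 4)
#' b$type
#' b$state[["DCN"]]
cctc_baseline <- function(params, duration = 12, dt = 1e-4, burn_in = 2,
                          tol = 1e-9) {
  if (burn_in >= duration) {
    abort("burn_in must be shorter than duration", class = "cctcsim_input_error")
  }
  traj <- cctc_simulate(params, drive = 0, duration = duration, dt = dt)
  keep <- traj$time >= burn_in
  pops <- cctc_populations()
  final <- stats::setNames(as.numeric(traj[nrow(traj), pops]), pops)
  resid <- sqrt(sum(cctc_derivatives(final, params, 0)^2))
  if (resid < tol) {
    list(state = final, type = "fixed_point", residual = resid)
  } else {
    avg <- stats::setNames(vapply(pops, function(p) mean(traj[[p]][keep]),
                                  numeric(1)), pops)
    list(state = avg, type = "oscillatory", residual = resid)
  }
}
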