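test_that("sigmoid transfer matches its closed form and limits", {
  expect_equal(sigmoid_rate(3, max_rate = 80, slope = 0.2, threshold = 3), 40)
  expect_lt(sigmoid_rate(-1e4, 100, 0.1), 1e-300)
  expect_equal(sigmoid_rate(1e4, 100, 0.1), 100)
  # closed-form oracle on a grid
  x <- seq(-50, 50, by = 2.5)
  expect_equal(sigmoid_rate(x, 100, 0.1, 5),
               100 / (1 + exp(-0.1 * (x - 5))), tolerance = 1e-12)
  # monotone non-decreasing
  expect_true(all(diff(sigmoid_rate(x, 100, 0.1, 5)) >= 0))
  expect_error(sigmoid_rate(NaN, 100, 0.1), class = "cctcsim_input_error")
  expect_error(sigmoid_rate(0, -1, 0.1), class = "cctcsim_input_error")
})

newton_fixed_point <- function(p, drive = 0, r0 = decoupled_fixed_point(p)) {
  tab <- p$populations
  r <- unname(r0)
  for (i in 1:200) {
    x <- drop(crossprod(p$W, r)) + p$background
    x[4] <- x[4] + drive
    s <- tab$max_rate / (1 + exp(-tab$slope * (x - tab$threshold)))
    f <- s - r
    sp <- tab$slope * s * (1 - s / tab$max_rate)
    r <- r + solve(diag(sp) %*% t(p$W) - diag(7), -f)
    if (max(abs(f)) < 1e-13) break
  }
  stats::setNames(pmin(pmax(r, 1e-9), tab$max_rate - 1e-9),
                  cctc_populations())
}

# weakly coupled variant: loop gains are subcritical, so the operating
# point is a stable focus and trajectories are smooth and contractive --
# the right setting for measuring integrator truncation error
weak_params <- function() {
  p <- default_params()
  p$W <- p$W * 0.2
  p
}

test_that("derivatives vanish at a fixed point and respect connection signs", {
  # root-residual oracle: Newton root of the autonomous system (weakly
  # coupled configuration, whose operating point is a stable root)
  pw <- weak_params()
  r <- newton_fixed_point(pw)
  expect_equal(unname(cctc_derivatives(r, pw, 0)), rep(0, 7),
               tolerance = 1e-6)
  p <- default_params()
  # raising an inhibitory source never increases its target's derivative
  state <- decoupled_fixed_point(p)
  d0 <- cctc_derivatives(state, p, 0)
  up <- state; up[["GPI"]] <- up[["GPI"]] + 5
  d1 <- cctc_derivatives(up, p, 0)
  expect_lte(d1[["VIM"]], d0[["VIM"]])
  up2 <- state; up2[["NRT"]] <- up2[["NRT"]] + 5
  expect_lte(cctc_derivatives(up2, p, 0)[["VIM"]], d0[["VIM"]])
  # and an excitatory source never decreases it
  up3 <- state; up3[["DCN"]] <- up3[["DCN"]] + 5
  expect_gte(cctc_derivatives(up3, p, 0)[["VIM"]], d0[["VIM"]])
})

test_that("central finite differences of a trajectory match the derivatives", {
  p <- default_params()
  dt <- 1e-4
  traj <- cctc_simulate(p, drive = 10, duration = 0.05, dt = dt)
  pops <- cctc_populations()
  idx <- seq(50, 450, by = 50)
  for (i in idx) {
    state <- unlist(traj[i, pops])
    d_model <- cctc_derivatives(state, p, 10)
    d_fd <- (unlist(traj[i + 1, pops]) - unlist(traj[i - 1, pops])) / (2 * dt)
    expect_equal(unname(d_fd), unname(d_model), tolerance = 1e-3)
  }
  # the agreement tightens as O(dt^2): refining dt by 4 shrinks the
  # finite-difference residual by ~16
  fd_err <- function(dt) {
    tr <- cctc_simulate(p, drive = 10, duration = 0.02, dt = dt)
    i <- round(0.01 / dt)
    st <- unlist(tr[i, pops])
    max(abs((unlist(tr[i + 1, pops]) - unlist(tr[i - 1, pops])) / (2 * dt) -
              cctc_derivatives(st, p, 10)))
  }
  expect_gt(fd_err(4e-4) / fd_err(1e-4), 8)
})

test_that("decoupled populations relax monotonically to their isolated fixed points", {
  p <- default_params()
  p$W[] <- 0
  init <- decoupled_fixed_point(p) + 10
  init <- pmin(init, p$populations$max_rate - 1)
  traj <- cctc_simulate(p, drive = 0, duration = 0.5, init = init)
  target <- decoupled_fixed_point(p)
  for (pop in cctc_populations()) {
    x <- traj[[pop]]
    expect_true(all(diff(x) <= 1e-9), label = paste(pop, "monotone"))
    expect_equal(x[length(x)], target[[pop]], tolerance = 1e-6)
  }
})

test_that("RK4 agrees with a fine-step Euler oracle to 1e-3 spikes/s over 1 s", {
  p <- weak_params()
  rk <- cctc_simulate(p, drive = 20, duration = 1, dt = 1e-4)
  eu <- cctc_simulate(p, drive = 20, duration = 1, dt = 1e-6,
                      method = "euler")
  pops <- cctc_populations()
  rk_end <- as.matrix(rk[, pops])
  eu_end <- as.matrix(eu[seq(1, nrow(eu), by = 100), pops])
  expect_lt(max(abs(rk_end - eu_end)), 1e-3)
})

test_that("halving dt reduces the RK4 error by at least 8x on a smooth stretch", {
  p <- weak_params()
  horizon <- 0.1
  ref <- cctc_simulate(p, drive = 15, duration = horizon, dt = 1e-6)
  pops <- cctc_populations()
  end_err <- function(dt) {
    tr <- cctc_simulate(p, drive = 15, duration = horizon, dt = dt)
    max(abs(unlist(tr[nrow(tr), pops]) - unlist(ref[nrow(ref), pops])))
  }
  e1 <- end_err(4e-4)
  e2 <- end_err(2e-4)
  expect_gt(e1 / e2, 8)
})

test_that("trajectories are deterministic and bounded for varied drives", {
  p <- default_params()
  a <- cctc_simulate(p, drive = 20, duration = 0.5)
  b <- cctc_simulate(p, drive = 20, duration = 0.5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  drives <- list(0, 20,
                 function(t) 10 * sin(2 * pi * 5 * t),
                 function(t) 10 * abs(cos(pi * 63 * t)))
  for (dr in drives) {
    tr <- cctc_simulate(p, drive = dr, duration = 1)
    for (j in seq_along(cctc_populations())) {
      pop <- cctc_populations()[j]
      expect_true(all(tr[[pop]] >= 0 & tr[[pop]] <= p$populations$max_rate[j]))
    }
  }
})

test_that("RK4 cross-checks against an independent adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  tab <- p$populations
  rhs <- function(t, y, parms) {
    x <- drop(crossprod(p$W, y)) + p$background
    x[4] <- x[4] + 20
    s <- tab$max_rate / (1 + exp(-tab$slope * (x - tab$threshold)))
    list((-y + s) / tab$tau)
  }
  y0 <- decoupled_fixed_point(p)
  times <- seq(0, 0.5, by = 0.01)
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  rk <- cctc_simulate(p, drive = 20, duration = 0.5, dt = 1e-4)
  idx <- match(round(times, 8), round(rk$time, 8))
  for (j in seq_along(cctc_populations())) {
    expect_equal(unname(sol[, j + 1]),
                 rk[[cctc_populations()[j]]][idx], tolerance = 1e-4)
  }
})

test_that("a too-coarse step fails with an explicit integration error", {
  p <- default_params()
  expect_error(cctc_simulate(p, drive = 1e6, duration = 100, dt = 0.5,
                             init = rep(50, 7)),
               regexp = "non-finite|step")
})

test_that("the baseline operating point reports its regime and the DCN rate", {
  p <- default_params()
  b <- cctc_baseline(p, duration = 12)
  expect_true(b$type %in% c("fixed_point", "oscillatory"))
  expect_equal(b$state[["DCN"]], 56.6, tolerance = 1e-3)
  # decoupled system converges to sigmoid(background) exactly
  pd <- p; pd$W[] <- 0
  bd <- cctc_baseline(pd, duration = 4)
  expect_equal(bd$type, "fixed_point")
  expect_lt(bd$residual, 1e-9)
  expect_equal(unname(bd$state), unname(decoupled_fixed_point(pd)),
               tolerance = 1e-9)
})
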