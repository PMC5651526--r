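test_that("Newtonian steady profiles recover Poiseuille flow", {
  newt <- hx_newtonian()
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 40)
  v <- solve_steady_profile(8.333e-5, duct, newt)
  rows <- duct$grid$flow_rows
  u0 <- hemotherm:::.centerline_extrap(duct$grid$y_c[rows], v$u[rows])
  u_mean <- 8.333e-5 / (pi * 0.011^2)
  expect_equal(u0 / u_mean, 2, tolerance = 0.005)
  # profile matches the closed form pointwise
  ua <- poiseuille_profile(8.333e-5, duct$grid$y_c[rows], 0.011)
  expect_lt(max(abs(v$u[rows] - ua)) / max(ua), 0.01)

  ductp <- build_duct_model("planar_channel", lumen_size = 0.022,
                            length = 0.1, resolution = 2, n_fluid = 40,
                            depth = 0.0346)
  vp <- solve_steady_profile(8.333e-5, ductp, newt)
  rp <- ductp$grid$flow_rows
  u0p <- hemotherm:::.centerline_extrap(ductp$grid$y_c[rp], vp$u[rp], 0.011)
  expect_equal(u0p / (8.333e-5 / (0.0346 * 0.022)), 1.5, tolerance = 0.005)
})

test_that("shear-thinning blood gives a blunter-than-parabolic profile", {
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 40)
  v <- solve_steady_profile(8.333e-5, duct, cy_params())
  u_mean <- 8.333e-5 / (pi * 0.011^2)
  expect_lt(max(v$u) / u_mean, 2)
  expect_gt(max(v$u) / u_mean, 1)
})

test_that("flow-rate constraint holds at every saved instant", {
  wf <- hx_waveform()
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 32)
  vu <- solve_unsteady_profile(wf, duct, cy_params(), n_cycles = 3)
  q_target <- waveform_at(wf, vu$times)
  expect_lt(max(abs(vu$q_t - q_target) / max(abs(q_target))), 1e-3)
})

test_that("constant waveform converges to the steady profile", {
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 32)
  wf <- make_inlet_waveform(peak_ratio = 1, reverse_fraction = 0,
                            mean_q = 8.333e-5, seed = 1)
  p <- cy_params()
  vs <- solve_steady_profile(8.333e-5, duct, p)
  vu <- solve_unsteady_profile(wf, duct, p, n_cycles = 8, tol = 1e-8)
  expect_lt(max(abs(vu$U[, ncol(vu$U)] - vs$u)), 1e-6)
})

test_that("pulsatile Newtonian flow matches the Womersley solution", {
  newt <- hx_newtonian()
  R <- 0.011; q0 <- 8.333e-5; q1 <- 0.5 * q0
  tt <- seq(0, 1, length.out = 201)[1:200]
  wf <- structure(list(period = 1, times = tt,
                       q = q0 + q1 * cos(2 * pi * tt), mean_q = q0),
                  class = "flow_waveform")
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = R,
                           length = 0.1, resolution = 2, n_fluid = 48)
  vu <- solve_unsteady_profile(wf, duct, newt, n_cycles = 20, dt = 1e-3,
                               tol = 1e-6)
  rows <- duct$grid$flow_rows
  rc <- duct$grid$y_c[rows]
  err2 <- 0; pk <- 0
  for (k in seq(10, 100, by = 10)) {
    ua <- womersley_profile(q0, complex(real = q1), R, 0.0035, 1050, 1,
                            rc, k * 0.01)
    err2 <- err2 + sum((vu$U[rows, k] - ua)^2)
    pk <- max(pk, max(abs(ua)))
  }
  expect_lt(sqrt(err2 / (10 * length(rc))) / pk, 0.01)

  # wall shear-rate reversal occurs within one output step of the oracle
  shear_num <- vu$wall_shear_t$hi[1, ]
  u_wallcell <- vu$U[rows[length(rows)], ]
  sign_num <- sign(u_wallcell)
  dwall <- R - rc[length(rc)]
  ua_wall <- vapply(vu$times, function(t)
    womersley_profile(q0, complex(real = q1), R, 0.0035, 1050, 1,
                      rc[length(rc)], t), 0)
  flips <- function(s) which(diff(sign(s)) != 0)
  f_num <- flips(u_wallcell); f_ana <- flips(ua_wall)
  expect_equal(length(f_num), length(f_ana))
  expect_true(all(abs(f_num - f_ana) <= 1))
})

test_that("with zero pressure gradient kinetic energy decays monotonically", {
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 32)
  v <- solve_steady_profile(8.333e-5, duct, cy_params())
  ke <- hemotherm:::.flow_free_decay(duct, cy_params(), v$u, dt = 1e-3,
                                     n_steps = 150)
  expect_true(all(diff(ke) < 0))
})

test_that("transverse grid convergence against the Womersley oracle", {
  newt <- hx_newtonian()
  R <- 0.011; q0 <- 8.333e-5; q1 <- 0.5 * q0
  tt <- seq(0, 1, length.out = 201)[1:200]
  wf <- structure(list(period = 1, times = tt,
                       q = q0 + q1 * cos(2 * pi * tt), mean_q = q0),
                  class = "flow_waveform")
  # uniform transverse mesh so refinement is self-similar
  err_at <- function(nf) {
    duct <- build_duct_model("axisymmetric_pipe", lumen_size = R,
                             length = 0.1, resolution = 2, n_fluid = nf,
                             stretch_ratio = 1)
    vu <- solve_unsteady_profile(wf, duct, newt, n_cycles = 15, dt = 2.5e-4,
                                 tol = 1e-7)
    rows <- duct$grid$flow_rows
    rc <- duct$grid$y_c[rows]
    e <- 0
    for (k in seq(20, 100, by = 20)) {
      ua <- womersley_profile(q0, complex(real = q1), R, 0.0035, 1050, 1,
                              rc, k * 0.01)
      e <- max(e, max(abs(vu$U[rows, k] - ua)))
    }
    e
  }
  ratio <- err_at(16) / err_at(32)
  expect_gt(ratio, 2.5)     # ~4 for a second-order transverse scheme
})

test_that("solver errors are informative", {
  duct <- build_duct_model("axisymmetric_pipe")
  expect_error(solve_steady_profile(-1, duct), "positive")
  wf <- make_inlet_waveform(seed = 1)
  expect_error(solve_unsteady_profile(wf, duct, n_cycles = 0), "n_cycles")
  expect_error(solve_unsteady_profile(wf, duct, dt = 0.1), "dt")
})
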