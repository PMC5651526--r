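test_that("zero source power gives a uniform field at the inlet temperature", {
  m <- build_design("base64", resolution = 2,
                    overrides = list(power = 0))
  v <- solve_steady_profile(5.8e-5, m, cy_params())
  ts <- solve_steady_temp(m, v, inlet_T = 37)
  expect_equal(range(ts$T), c(37, 37), tolerance = 1e-9)
  flux <- total_blood_heat_flux(ts, m)
  expect_equal(flux$Q_blood_W, 0, tolerance = 1e-9)
  prof <- interface_temperature_profile(ts, m)
  expect_null(attr(prof, "argmax_pct"))
  os <- outlet_plane_stats(ts, m)
  expect_equal(os$mean_C, 37, tolerance = 1e-9)
  expect_equal(os$sd_C, 0, tolerance = 1e-9)
})

test_that("steady conjugate solve conserves energy and transfers 64 W", {
  run <- hx_run("base64")
  gain <- cycle_avg_enthalpy_gain(run$steady, run$model, run$flow_steady)
  expect_lt(abs(gain - 64) / 64, 0.005)
  flux <- total_blood_heat_flux(run$steady, run$model)
  expect_lt(abs(flux$Q_blood_W - 64) / 64, 0.005)
})

test_that("developed-region Nusselt numbers match the Graetz closed forms", {
  newt <- hx_newtonian()
  alpha <- 0.5 / (1050 * 3650)
  R <- 0.011
  u_m <- 100 * alpha / (2 * R)
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = R,
                           length = 0.3, power = 5, resolution = 2,
                           n_fluid = 48)
  v <- solve_steady_profile(u_m * pi * R^2, duct, newt)
  ts <- solve_steady_temp(duct, v)
  expect_equal(local_nusselt(ts, duct, v, 0.27), graetz_nusselt(),
               tolerance = 0.02)

  H <- 0.022
  u_mp <- 80 * alpha / (2 * H)
  ductp <- build_duct_model("planar_channel", lumen_size = H,
                            length = 0.3, power = 5, resolution = 2,
                            n_fluid = 48, depth = 0.0346)
  vp <- solve_steady_profile(u_mp * 0.0346 * H, ductp, newt)
  tsp <- solve_steady_temp(ductp, vp)
  expect_equal(local_nusselt(tsp, ductp, vp, 0.27),
               graetz_nusselt("planar_channel"), tolerance = 0.02)
})

test_that("temperature excess is linear in source power (steady)", {
  v <- NULL
  excess <- function(p) {
    m <- build_design("base64", resolution = 2,
                      overrides = list(power = p))
    if (is.null(v)) v <<- solve_steady_profile(5.8e-5, m, cy_params())
    solve_steady_temp(m, v)$T[, 1] - 37
  }
  e1 <- excess(32); e2 <- excess(64)
  expect_equal(e2, 2 * e1, tolerance = 1e-9)
})

test_that("steady fluid extrema lie on boundaries/interfaces (max principle)", {
  run <- hx_run("base64")
  sys <- run$steady$sys
  Tb <- run$steady$T[sys$zone == 1, 1]
  expect_gte(min(Tb), 37 - 1e-9)
  expect_lte(max(run$steady$T[, 1]), max(run$steady$T[sys$zone != 1, 1]) + 1e-9)
})

test_that("transient solid conduction matches the 1-D slab series solution", {
  sm <- hx_slab_model()
  sys <- hemotherm:::.thermal_system(sm)
  Tk <- rep(37, sys$ncell)
  dt <- 0.05
  u0 <- rep(0, sm$grid$ny)
  for (s in 1:200) {
    asm <- hemotherm:::.thermal_assemble(sys, u0, 37, dt = dt, Told = Tk)
    Tk <- as.numeric(Matrix::solve(asm$A, asm$rhs))
  }
  mat <- get_material("titanium")
  jmid <- which(sys$ci == 2)
  Ty <- Tk[jmid][order(sys$cj[jmid])]
  Ta <- slab_conduction(sm$L - sm$grid$y_c, 200 * dt, sm$L, mat$k,
                        mat$rho * mat$cp, sm$q, 37)
  expect_lt(max(abs(Ty - Ta)) / (max(Ta) - 37), 0.01)
})

test_that("steady inflow + steady init is a fixed point of the cycle map", {
  m <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                        length = 0.1, power = 5, resolution = 2, n_fluid = 32)
  p <- cy_params()
  wf <- make_inlet_waveform(peak_ratio = 1, reverse_fraction = 0,
                            mean_q = 5.8e-5, seed = 1)
  vs <- solve_steady_profile(5.8e-5, m, p)
  vu <- solve_unsteady_profile(wf, m, p, n_cycles = 5, tol = 1e-8)
  ts <- solve_steady_temp(m, vs)
  tr <- solve_transient_temp(m, vu, ts, max_cycles = 3, tol = 1e-4,
                             save_cycles = 1)
  expect_true(tr$report$converged)
  expect_lt(tr$report$periodicity_residual, 1e-4)
})

test_that("periodic pulsatile base64 heat flux balances the source", {
  run <- hx_run("base64")
  expect_true(run$report$converged)
  expect_lte(run$report$cycles_run, 40)
  flux <- total_blood_heat_flux(run$temperature, run$model)
  expect_lt(abs(mean(flux$Q_blood_W) - 64) / 64, 0.01)
  # instantaneous flux oscillates above and below the source output
  expect_gt(max(flux$Q_blood_W), 64)
  expect_lt(min(flux$Q_blood_W), 64)
  # mixed-temperature rise P0/(rho cp Qbar): exact identity at steady
  # state (no flow reversal ambiguity in the flux weighting)
  mt_s <- outlet_mixed_temperature(run$steady, run$model, run$flow_steady)
  expect_equal(mt_s$T_mixed_C - 37,
               64 / (1050 * 3650 * run$waveform$mean_q), tolerance = 0.01)
  # pulsatile: the cycle-averaged enthalpy-flux-weighted rise (reverse
  # lobes advect inlet-temperature fluid, which the balance accounts for)
  rise <- cycle_avg_enthalpy_gain(run$temperature, run$model, run$flow) /
    (1050 * 3650 * run$waveform$mean_q)
  expect_equal(rise, 64 / (1050 * 3650 * run$waveform$mean_q),
               tolerance = 0.01)
})

test_that("interface profile peaks downstream of the source centre", {
  run <- hx_run("base64")
  prof <- interface_temperature_profile(run$temperature, run$model,
                                        window = 5)
  expect_gt(attr(prof, "argmax_pct"), 50)
  expect_error(interface_temperature_profile(run$temperature, run$model,
                                             window = 50), "window")
})

test_that("singular solid-only steady system raises a configuration error", {
  sm <- hx_slab_model()
  model <- structure(list(grid = sm$grid, source_table = sm$source_table,
                          materials = NULL,
                          geometry = list(x_exchanger = c(0, 0.03),
                                          exchanger_length = 0.03)),
                     class = "hx_model")
  fake_v <- list(u = rep(0, sm$grid$ny), steady = TRUE)
  expect_error(solve_steady_temp(model, fake_v), "configuration error")
})
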