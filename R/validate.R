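# Analytic-oracle validation suites, runnable as a unit via validate_suite().
# Each check compares a solver result against an independent closed form
# from oracles.R at the documented tolerance.

# symmetric quadratic extrapolation of a profile to its centreline:
# u ~ u0 + c s^2 with s the distance from the centre, fitted on the two
# samples closest to it
.centerline_extrap <- function(pos, u, centre = 0) {
  s <- abs(pos - centre)
  o <- order(s)
  s1 <- s[o[1]]
  o2 <- o[which(s[o] > s1 * (1 + 1e-9))[1]]
  s2 <- s[o2]
  (u[o[1]] * s2^2 - u[o2] * s1^2) / (s2^2 - s1^2)
}

.vrow <- function(name, value, reference, tolerance) {
  data.frame(name = name, value = value, reference = reference,
             tolerance = tolerance,
             pass = abs(value - reference) <= tolerance)
}

.validate_flow <- function() {
  newt <- cy_params(mu0 = 0.0035, mu_inf = 0.0035)
  out <- list()

  duct <- build_duct_model("axisymmetric_pipe", lumen_size = 0.011,
                           length = 0.1, resolution = 2, n_fluid = 40)
  v <- solve_steady_profile(8.333e-5, duct, newt)
  u_mean <- 8.333e-5 / (pi * 0.011^2)
  rows <- duct$grid$flow_rows
  u0 <- .centerline_extrap(duct$grid$y_c[rows], v$u[rows])
  out$poise_pipe <- .vrow("poiseuille_pipe_centerline_ratio",
                          u0 / u_mean, 2.0, 0.005 * 2)

  ductp <- build_duct_model("planar_channel", lumen_size = 0.022,
                            length = 0.1, resolution = 2, n_fluid = 40,
                            depth = 0.0346)
  vp <- solve_steady_profile(8.333e-5, ductp, newt)
  u_meanp <- 8.333e-5 / (0.0346 * 0.022)
  rowsp <- ductp$grid$flow_rows
  u0p <- .centerline_extrap(ductp$grid$y_c[rowsp], vp$u[rowsp],
                            centre = 0.011)
  out$poise_chan <- .vrow("poiseuille_channel_centerline_ratio",
                          u0p / u_meanp, 1.5, 0.005 * 1.5)

  # Womersley: sinusoidal waveform, alpha ~ 15.1
  R <- 0.011; mu <- 0.0035; rho <- 1050
  q0 <- 8.333e-5; q1 <- 0.5 * q0
  n_samp <- 200
  tt <- seq(0, 1, length.out = n_samp + 1)[1:n_samp]
  wf <- structure(list(period = 1, times = tt,
                       q = q0 + q1 * cos(2 * pi * tt), mean_q = q0),
                  class = "flow_waveform")
  duct2 <- build_duct_model("axisymmetric_pipe", lumen_size = R,
                            length = 0.1, resolution = 2, n_fluid = 48)
  vu <- solve_unsteady_profile(wf, duct2, newt, n_cycles = 20, dt = 1e-3,
                               tol = 1e-6)
  rows <- duct2$grid$flow_rows
  rc <- duct2$grid$y_c[rows]
  err <- 0; pk <- 0
  for (k in seq(10, 100, by = 10)) {
    ua <- womersley_profile(q0, complex(real = q1), R, mu, rho, 1,
                            rc, k * 0.01)
    un <- vu$U[rows, k]
    err <- err + sum((un - ua)^2)
    pk <- max(pk, max(abs(ua)))
  }
  rms <- sqrt(err / (10 * length(rc)))
  out$womersley <- .vrow("womersley_rms_over_peak", rms / pk, 0, 0.01)
  do.call(rbind, out)
}

.validate_thermal <- function() {
  newt <- cy_params(mu0 = 0.0035, mu_inf = 0.0035)
  out <- list()
  alpha <- 0.5 / (1050 * 3650)

  # pipe, constant wall flux: developed Nu = 48/11
  R <- 0.011
  pe <- 100                              # Pe_D small enough to develop
  u_m <- pe * alpha / (2 * R)
  q <- u_m * pi * R^2
  duct <- build_duct_model("axisymmetric_pipe", lumen_size = R,
                           length = 0.3, power = 5, resolution = 2,
                           n_fluid = 48)
  v <- solve_steady_profile(q, duct, newt)
  ts <- solve_steady_temp(duct, v)
  nu <- local_nusselt(ts, duct, v, 0.27)
  out$graetz_pipe <- .vrow("graetz_pipe_nusselt", nu, 48 / 11,
                           0.02 * 48 / 11)

  # planar channel, one side heated / one adiabatic: Nu = 5.385 on 2H
  H <- 0.022
  u_m <- 80 * alpha / (2 * H)
  qf <- u_m * 0.0346 * H
  ductp <- build_duct_model("planar_channel", lumen_size = H,
                            length = 0.3, power = 5, resolution = 2,
                            n_fluid = 48, depth = 0.0346)
  vp <- solve_steady_profile(qf, ductp, newt)
  tsp <- solve_steady_temp(ductp, vp)
  nup <- local_nusselt(tsp, ductp, vp, 0.27)
  out$graetz_chan <- .vrow("graetz_channel_nusselt", nup, 5.385,
                           0.02 * 5.385)

  # mixed-temperature rise P0/(rho cp Q)
  rise <- outlet_mixed_temperature(ts, duct, v)$T_mixed_C - 37
  out$mixed <- .vrow("mixed_rise_over_P0_rho_cp_Q",
                     rise / (5 / (1050 * 3650 * q)), 1, 0.01)
  do.call(rbind, out)
}

.validate_tracking <- function() {
  out <- list()
  # exponential relaxation from rest in uniform flow vs analytic solution
  tau <- 2e-3; u0 <- 0.3; dt <- 1e-4; nstep <- 200
  x <- 0; v <- 0; verr <- 0
  for (s in seq_len(nstep)) {
    st <- .drag_update(x, v, u0, tau, dt)
    x <- st$x; v <- st$v
    va <- u0 * (1 - exp(-s * dt / tau))
    verr <- max(verr, abs(v - va))
  }
  xa <- u0 * nstep * dt - u0 * tau * (1 - exp(-nstep * dt / tau))
  out$relax_v <- .vrow("drag_relaxation_velocity_relerr", verr / u0, 0, 1e-3)
  out$relax_x <- .vrow("drag_relaxation_position_relerr",
                       abs(x - xa) / xa, 0, 1e-3)

  # specular reflection conserves speed to 1e-12
  worst <- 0
  rng <- .hx_rng(42)
  for (i in 1:1000) {
    vv <- c(rng() - 0.5, rng() - 0.5, rng() - 0.5)
    nn <- c(rng() - 0.5, rng() - 0.5, rng() - 0.5)
    nn <- nn / sqrt(sum(nn^2))
    vr <- reflect(vv, nn)
    worst <- max(worst, abs(sqrt(sum(vr^2)) - sqrt(sum(vv^2))))
  }
  out$reflect <- .vrow("reflection_speed_error", worst, 0, 1e-12)

  # platelet seeding law: KS test against the (r/R)^5 radial CDF
  m <- build_design("base64", resolution = 2)
  plt <- seed_cells("platelet", 20000, m, seed = 7)
  R <- m$geometry$lumen_size
  ks <- .with_seed(1, stats::ks.test((plt$y / R)^5, "punif"))
  out$seed_ks <- .vrow("platelet_seeding_ks_pvalue_above_alpha",
                       as.numeric(ks$p.value > 0.01), 1, 0)
  do.call(rbind, out)
}

.validate_tei <- function() {
  out <- list()
  # trapezoid vs brute-force fine Riemann quadrature of the linear
  # interpolant
  rng <- .hx_rng(11)
  tt <- cumsum(0.005 + vapply(1:80, function(i) rng() * 0.02, 0))
  Tv <- 37 + vapply(1:80, function(i) rng() * 15, 0)
  fine <- seq(tt[1], tt[length(tt)], length.out = 400001)
  Ti <- stats::approx(tt, Tv, xout = fine)$y
  riemann <- sum((Ti[-1] + Ti[-length(Ti)]) / 2) * diff(fine[1:2])
  val <- tei(tt, Tv)
  out$trap <- .vrow("tei_trapezoid_vs_riemann_relerr",
                    abs(val - riemann) / riemann, 0, 1e-6)
  out$single <- .vrow("tei_single_trapezoid", tei(c(0, 1), c(40, 50)), 45, 0)
  do.call(rbind, out)
}

#' Run the analytic validation suites
#'
#' Executes the closed-form oracle checks for the requested suite(s):
#' `flow` (Poiseuille ratios, Womersley RMS), `thermal` (developed Nusselt
#' numbers, mixed-temperature rise), `tracking` (drag relaxation, specular
#' reflection, seeding law), `tei` (quadrature).
#'
#' @param suite One of `"all"`, `"flow"`, `"thermal"`, `"tracking"`,
#'   `"tei"`.
#' @param json Optional path to write the report as JSON.
#' @return A data.frame `(name, value, reference, tolerance, pass)`; the
#'   attribute `"ok"` is `TRUE` when every check passed.
#' @export
validate_suite <- function(suite = c("all", "flow", "thermal", "tracking",
                                     "tei"), json = NULL) {
  suite <- match.arg(suite)
  parts <- list()
  if (suite %in% c("all", "flow")) parts$flow <- .validate_flow()
  if (suite %in% c("all", "thermal")) parts$thermal <- .validate_thermal()
  if (suite %in% c("all", "tracking")) parts$tracking <- .validate_tracking()
  if (suite %in% c("all", "tei")) parts$tei <- .validate_tei()
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "ok") <- all(out$pass)
  if (!is.null(json))
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA)
  out
}
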