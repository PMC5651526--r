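# Reduced momentum solver.
#
# In the surrogate the exchanger section is a straight conduit, so the flow
# is fully developed: u = u(y, t) x_hat, the convective term vanishes
# identically, and the momentum equation reduces to
#     rho du/dt = g(t) + d/dy( mu(|du/dy|) du/dy )
# (with the cylindrical metric in pipe mode).  The axial pressure gradient
# g(t) is not prescribed; it is solved each step as the scalar Lagrange
# multiplier enforcing the instantaneous flow-rate constraint
# integral(u dA) = Q(t), which is how the waveform enters the model.

# contiguous runs of rows usable by the parallel-flow solver
.flow_runs <- function(grid) {
  fr <- grid$flow_rows
  if (!length(fr)) stop("grid has no flow rows")
  breaks <- c(0, which(diff(fr) != 1), length(fr))
  lapply(seq_len(length(breaks) - 1),
         function(k) fr[(breaks[k] + 1):breaks[k + 1]])
}

# per-run static geometry for the transverse FV operator
.run_geom <- function(grid, rows) {
  yf_lo <- grid$y_f[rows[1]]
  yf_hi <- grid$y_f[rows[length(rows)] + 1]
  yc <- grid$y_c[rows]
  M <- length(rows)
  if (grid$mode == "axisymmetric_pipe") {
    A_int <- 2 * pi * grid$y_f[rows[-M] + 1]     # internal faces
    A_lo <- 2 * pi * yf_lo                        # 0 on the axis
    A_hi <- 2 * pi * yf_hi
    V <- pi * (grid$y_f[rows + 1]^2 - grid$y_f[rows]^2)
  } else {
    A_int <- rep(grid$depth, M - 1)
    A_lo <- A_hi <- grid$depth
    V <- grid$depth * grid$dy[rows]
  }
  list(M = M, yc = yc, d_int = diff(yc),
       d_lo = yc[1] - yf_lo, d_hi = yf_hi - yc[M],
       A_int = A_int, A_lo = A_lo, A_hi = A_hi, V = V)
}

# face shear rates |du/dy| for a run profile (internal faces + 2 wall faces)
.run_shear <- function(u, rg) {
  g_int <- if (rg$M > 1) abs(diff(u)) / rg$d_int else numeric(0)
  c(abs(u[1]) / rg$d_lo, g_int, abs(u[rg$M]) / rg$d_hi)
}

# Thomas algorithm; a = sub, b = diag, c = super, r = rhs (matrix of RHS cols)
.tridiag_solve <- function(a, b, c, r) {
  n <- length(b)
  r <- as.matrix(r)
  cp <- numeric(n); rp <- matrix(0, n, ncol(r))
  cp[1] <- c[1] / b[1]; rp[1, ] <- r[1, ] / b[1]
  if (n > 1) for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) c[i] / m else 0
    rp[i, ] <- (r[i, ] - a[i] * rp[i - 1, ]) / m
  }
  x <- rp
  if (n > 1) for (i in (n - 1):1) x[i, ] <- rp[i, ] - cp[i] * x[i + 1, ]
  x
}

# operator coefficients for one run given face viscosities
.run_operator <- function(rg, mu_f) {
  M <- rg$M
  G_lo <- mu_f[1] * rg$A_lo / rg$d_lo
  G_hi <- mu_f[M + 1] * rg$A_hi / rg$d_hi
  G_int <- if (M > 1) mu_f[2:M] * rg$A_int / rg$d_int else numeric(0)
  sub <- c(0, -G_int)
  sup <- c(-G_int, 0)
  dia <- c(G_lo, rep(0, M - 1)) + c(rep(0, M - 1), G_hi)
  if (M > 1) {
    dia <- dia + c(G_int, 0) + c(0, G_int)
  }
  list(sub = sub, dia = dia, sup = sup)
}

#' Steady fully developed velocity profile
#'
#' Solves the steady reduced momentum equation with Carreau-Yasuda
#' viscosity, iterating the axial pressure gradient so that the computed
#' flow rate matches `q_mean` to better than 1e-6 relative (the reduced
#' continuity constraint).
#'
#' @param q_mean Target volumetric flow (m^3/s).
#' @param model An `hx_model` from [build_design()] or [build_duct_model()].
#' @param params [cy_params()] rheology; set `mu0 = mu_inf` for a Newtonian
#'   fluid.
#' @param tol Relative convergence tolerance on the profile.
#' @param max_iter Maximum Picard iterations on the viscosity.
#'
#' @return An object of class `hx_velocity` with fields `u` (velocity on all
#'   grid rows, zero outside the flow passage), `g` (pressure gradient,
#'   Pa/m), `q` (achieved flow), `wall_shear` (shear rate at each passage
#'   wall, 1/s), `steady = TRUE`.
#' @export
solve_steady_profile <- function(q_mean, model, params = cy_params(),
                                 tol = 1e-10, max_iter = 200) {
  if (q_mean <= 0) stop("q_mean must be positive")
  grid <- model$grid
  runs <- .flow_runs(grid)
  rgs <- lapply(runs, .run_geom, grid = grid)
  mu_f <- lapply(rgs, function(rg) rep(params$mu0, rg$M + 1))
  us <- lapply(rgs, function(rg) rep(0, rg$M))
  for (it in seq_len(max_iter)) {
    u1 <- vector("list", length(rgs))
    for (r in seq_along(rgs)) {
      op <- .run_operator(rgs[[r]], mu_f[[r]])
      u1[[r]] <- .tridiag_solve(op$sub, op$dia, op$sup, rgs[[r]]$V)[, 1]
    }
    Q1 <- sum(vapply(seq_along(rgs),
                     function(r) sum(u1[[r]] * rgs[[r]]$V), 0))
    g <- q_mean / Q1
    u_new <- lapply(u1, function(u) g * u)
    delta <- max(vapply(seq_along(rgs), function(r)
      max(abs(u_new[[r]] - us[[r]])), 0))
    scale <- max(vapply(u_new, function(u) max(abs(u)), 0))
    us <- u_new
    mu_f <- lapply(seq_along(rgs), function(r)
      cy_viscosity(.run_shear(us[[r]], rgs[[r]]), params))
    if (delta <= tol * scale) {
      return(.velocity_object(grid, runs, rgs, us, g, q_mean, steady = TRUE))
    }
  }
  stop(sprintf(paste0("solve_steady_profile: viscosity iteration did not ",
                      "converge in %d iterations (residual %.3e m/s)"),
               max_iter, delta))
}

.velocity_object <- function(grid, runs, rgs, us, g, q, steady = FALSE,
                             U = NULL, times = NULL, g_t = NULL, q_t = NULL,
                             period = NULL, residual = NA) {
  u_full <- rep(0, grid$ny)
  for (r in seq_along(runs)) u_full[runs[[r]]] <- us[[r]]
  ws <- lapply(seq_along(runs), function(r) {
    sh <- .run_shear(us[[r]], rgs[[r]])
    c(lo = sh[1], hi = sh[length(sh)])
  })
  structure(list(u = u_full, g = g, q = q, wall_shear = ws,
                 steady = steady, runs = runs,
                 U = U, times = times, g_t = g_t, q_t = q_t,
                 period = period, periodicity_residual = residual),
            class = "hx_velocity")
}

#' @export
print.hx_velocity <- function(x, ...) {
  if (isTRUE(x$steady)) {
    cat(sprintf("hx_velocity (steady): q = %.4g m^3/s, g = %.4g Pa/m, umax = %.4g m/s\n",
                x$q, x$g, max(abs(x$u))))
  } else {
    cat(sprintf("hx_velocity (periodic): %d saved profiles over %.3g s, periodicity residual %.3g m/s\n",
                length(x$times), x$period, x$periodicity_residual))
  }
  invisible(x)
}

#' Unsteady flow-matched velocity profiles
#'
#' Integrates the reduced unsteady momentum equation with a fixed-step
#' second-order implicit scheme (BDF2), choosing the axial pressure
#' gradient `g(t)` each substep so that the instantaneous flow rate matches
#' the waveform.  Cycles are repeated until the saved profiles are periodic
#' (max cycle-to-cycle change below `tol`) or `n_cycles` is reached;
#' profiles are saved on the fixed 1e-2 s output cadence.
#'
#' @inheritParams solve_steady_profile
#' @param waveform A [make_inlet_waveform()] (after [descending_fraction()]).
#' @param n_cycles Maximum number of cardiac cycles.
#' @param dt Integration substep (s); must lie in `[1e-8, 1e-2]`.
#' @param tol Periodicity tolerance (m/s) on saved profiles.
#' @param n_picard Viscosity Picard sweeps per substep.
#' @param out_dt Output cadence (s); the default matches the 1e-2 s save
#'   interval used throughout the package.
#'
#' @return An `hx_velocity` with `U` (ny x n_times matrix of profiles at
#'   `times`), `g_t`, `q_t`, `period`, `periodicity_residual`, and the final
#'   cycle's wall shear-rate histories in `wall_shear_t`.
#' @export
solve_unsteady_profile <- function(waveform, model, params = cy_params(),
                                   n_cycles = 30, dt = 2.5e-3, tol = 1e-5,
                                   n_picard = 2, out_dt = 1e-2) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (dt < 1e-8 || dt > 1e-2) stop("dt must lie within [1e-8, 1e-2] s")
  grid <- model$grid
  runs <- .flow_runs(grid)
  rgs <- lapply(runs, .run_geom, grid = grid)
  nrun <- length(runs)
  period <- waveform$period
  n_sub <- max(1, round(out_dt / dt))
  dt <- out_dt / n_sub
  n_out <- round(period / out_dt)
  if (abs(n_out * out_dt - period) > 1e-9)
    stop("period must be a multiple of the output cadence")

  init <- solve_steady_profile(waveform$mean_q, model, params)
  us <- lapply(runs, function(rr) init$u[rr])
  us_m1 <- us
  rho <- params$rho

  U_prev <- NULL
  U <- matrix(0, grid$ny, n_out)
  g_t <- q_t <- numeric(n_out)
  ws_lo <- ws_hi <- matrix(NA_real_, nrun, n_out)
  residual <- Inf
  cycles_run <- 0

  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(n_out)) {
      for (s in seq_len(n_sub)) {
        t_new <- ((cyc - 1) * period) + (k - 1) * out_dt + s * dt
        q_new <- waveform_at(waveform, t_new)
        first <- (cyc == 1 && k == 1 && s == 1)
        u_it <- us
        for (p in seq_len(n_picard)) {
          u0l <- u1l <- vector("list", nrun)
          for (r in seq_len(nrun)) {
            rg <- rgs[[r]]
            mu_f <- cy_viscosity(.run_shear(u_it[[r]], rg), params)
            op <- .run_operator(rg, mu_f)
            if (first) {       # backward Euler startup
              dia <- op$dia + rho * rg$V / dt
              rhs0 <- rho * rg$V * us[[r]] / dt
            } else {           # BDF2
              dia <- op$dia + 1.5 * rho * rg$V / dt
              rhs0 <- rho * rg$V * (2 * us[[r]] - 0.5 * us_m1[[r]]) / dt
            }
            sol <- .tridiag_solve(op$sub, dia, op$sup, cbind(rhs0, rg$V))
            u0l[[r]] <- sol[, 1]; u1l[[r]] <- sol[, 2]
          }
          Q0 <- sum(vapply(seq_len(nrun), function(r)
            sum(u0l[[r]] * rgs[[r]]$V), 0))
          Q1 <- sum(vapply(seq_len(nrun), function(r)
            sum(u1l[[r]] * rgs[[r]]$V), 0))
          g_new <- (q_new - Q0) / Q1
          u_it <- lapply(seq_len(nrun), function(r) u0l[[r]] + g_new * u1l[[r]])
        }
        us_m1 <- us
        us <- u_it
      }
      for (r in seq_len(nrun)) {
        U[runs[[r]], k] <- us[[r]]
        sh <- .run_shear(us[[r]], rgs[[r]])
        ws_lo[r, k] <- sh[1]; ws_hi[r, k] <- sh[length(sh)]
      }
      g_t[k] <- g_new
      q_t[k] <- sum(vapply(seq_len(nrun), function(r)
        sum(us[[r]] * rgs[[r]]$V), 0))
    }
    cycles_run <- cyc
    if (!is.null(U_prev)) {
      residual <- max(abs(U - U_prev))
      if (residual < tol) break
    }
    U_prev <- U
  }

  out <- .velocity_object(grid, runs, rgs, us, g_new, q_t[n_out],
                          steady = FALSE, U = U,
                          times = seq_len(n_out) * out_dt,
                          g_t = g_t, q_t = q_t, period = period,
                          residual = residual)
  out$wall_shear_t <- list(lo = ws_lo, hi = ws_hi)
  out$cycles_run <- cycles_run
  out
}

# free viscous decay (g = 0) from an initial profile; used by the
# dissipation-consistency tests.  Returns kinetic-energy history.
.flow_free_decay <- function(model, params, u0_full, dt = 1e-3, n_steps = 200) {
  grid <- model$grid
  runs <- .flow_runs(grid)
  rgs <- lapply(runs, .run_geom, grid = grid)
  us <- lapply(runs, function(rr) u0_full[rr])
  rho <- params$rho
  ke <- numeric(n_steps + 1)
  ke_of <- function(us) 0.5 * rho * sum(vapply(seq_along(runs), function(r)
    sum(us[[r]]^2 * rgs[[r]]$V), 0))
  ke[1] <- ke_of(us)
  for (s in seq_len(n_steps)) {
    for (r in seq_along(runs)) {
      rg <- rgs[[r]]
      mu_f <- cy_viscosity(.run_shear(us[[r]], rg), params)
      op <- .run_operator(rg, mu_f)
      us[[r]] <- .tridiag_solve(op$sub, op$dia + rho * rg$V / dt, op$sup,
                                rho * rg$V * us[[r]] / dt)[, 1]
    }
    ke[s + 1] <- ke_of(us)
  }
  ke
}

# velocity profile at an arbitrary time by periodic lookup of the saved
# cadence (profiles are stored at times k*out_dt; index nearest sample)
.u_at_time <- function(vel, t) {
  if (isTRUE(vel$steady)) return(vel$u)
  n <- length(vel$times)
  k <- round((t %% vel$period) / (vel$times[1])) %% n
  if (k == 0) k <- n
  vel$U[, k]
}
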