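# Conjugate energy transport on the zoned surrogate grid.
#
# Finite-volume discretization: first-order upwind for blood advection,
# central differences with harmonic-mean interface conductivities for
# diffusion (exactly conservative, including across the fluid-solid
# interfaces), implicit (backward Euler) time stepping on the 1e-2 s output
# cadence.  Solid zones carry conduction only; external boundaries are
# insulated except for the internal source band, the advective inlet
# (fixed temperature) and the zero-diffusive-flux advective outlet.

# precompute everything that does not depend on the velocity profile
.thermal_system <- function(model) {
  grid <- model$grid
  props <- .zone_props(model$materials)
  zone <- grid$zone
  nx <- grid$nx; ny <- grid$ny
  act <- which(zone > 0)                   # column-major
  ncell <- length(act)
  idx <- matrix(0L, nx, ny)
  idx[act] <- seq_len(ncell)
  sub <- arrayInd(act, c(nx, ny))
  ci <- sub[, 1]; cj <- sub[, 2]
  zn <- zone[act]
  kc <- props$k[zn]
  rcp <- props$rho[zn] * props$cp[zn]
  V <- grid$vol[act]

  # transverse diffusion faces
  ta <- tb <- tg <- numeric(0)
  for (j in seq_len(ny - 1)) {
    a <- idx[, j]; b <- idx[, j + 1]
    ok <- a > 0 & b > 0
    if (!any(ok)) next
    d1 <- grid$y_f[j + 1] - grid$y_c[j]
    d2 <- grid$y_c[j + 1] - grid$y_f[j + 1]
    A_f <- grid$At_fac[j + 1] * grid$dx[ok]
    G <- A_f / (d1 / kc[a[ok]] + d2 / kc[b[ok]])
    ta <- c(ta, a[ok]); tb <- c(tb, b[ok]); tg <- c(tg, G)
  }
  # axial diffusion faces
  for (i in seq_len(nx - 1)) {
    a <- idx[i, ]; b <- idx[i + 1, ]
    ok <- a > 0 & b > 0
    if (!any(ok)) next
    d1 <- grid$dx[i] / 2; d2 <- grid$dx[i + 1] / 2
    G <- grid$Acs[ok] / (d1 / kc[a[ok]] + d2 / kc[b[ok]])
    ta <- c(ta, a[ok]); tb <- c(tb, b[ok]); tg <- c(tg, G)
  }
  # out-of-plane wrap conductances (copper heat guide)
  if (!is.null(grid$wrap) && nrow(grid$wrap)) {
    wa <- idx[cbind(grid$wrap$i, grid$wrap$ja)]
    wb <- idx[cbind(grid$wrap$i, grid$wrap$jb)]
    ok <- wa > 0 & wb > 0
    ta <- c(ta, wa[ok]); tb <- c(tb, wb[ok]); tg <- c(tg, grid$wrap$G[ok])
  }
  Kd <- Matrix::sparseMatrix(
    i = c(ta, tb, ta, tb), j = c(ta, tb, tb, ta),
    x = c(tg, tg, -tg, -tg), dims = c(ncell, ncell))

  # fluid-solid interface faces (for the blood heat-flux history)
  fs <- (zn[ta] == .ZONE_BLOOD) != (zn[tb] == .ZONE_BLOOD)
  blood_first <- zn[ta[fs]] == .ZONE_BLOOD
  iface <- data.frame(
    blood = ifelse(blood_first, ta[fs], tb[fs]),
    solid = ifelse(blood_first, tb[fs], ta[fs]),
    G = tg[fs])

  # advection faces between axially adjacent blood cells
  aa <- ab <- aj <- numeric(0)
  for (j in seq_len(ny)) {
    a <- idx[-nx, j]; b <- idx[-1, j]
    ok <- a > 0 & b > 0 & zone[-nx, j] == .ZONE_BLOOD &
      zone[-1, j] == .ZONE_BLOOD
    if (!any(ok)) next
    aa <- c(aa, a[ok]); ab <- c(ab, b[ok]); aj <- c(aj, rep(j, sum(ok)))
  }
  rcp_b <- props$rho[.ZONE_BLOOD] * props$cp[.ZONE_BLOOD]
  in_j <- which(zone[1, ] == .ZONE_BLOOD)
  out_j <- which(zone[nx, ] == .ZONE_BLOOD)
  in_cell <- idx[cbind(1L, in_j)]
  out_cell <- idx[cbind(nx, out_j)]

  # source injection: split each face power between the adjacent cells
  st <- model$source_table
  src_cell <- integer(0); src_p <- numeric(0)
  for (r in seq_len(nrow(st))) {
    i <- st$i[r]; jf <- st$jf[r]
    lo <- if (jf - 1 >= 1 && zone[i, jf - 1] > 0) idx[i, jf - 1] else 0L
    hi <- if (jf <= ny && zone[i, jf] > 0) idx[i, jf] else 0L
    tgt <- c(lo, hi); tgt <- tgt[tgt > 0]
    if (!length(tgt)) stop("source face with no adjacent active cell")
    src_cell <- c(src_cell, tgt)
    src_p <- c(src_p, rep(st$flux[r] * st$area[r] / length(tgt), length(tgt)))
  }
  src_blood <- zn[src_cell] == .ZONE_BLOOD

  list(ncell = ncell, idx = idx, ci = ci, cj = cj, zone = zn,
       k = kc, rcp = rcp, V = V, Kd = Kd, iface = iface,
       adv_a = aa, adv_b = ab, adv_j = aj, rcp_b = rcp_b,
       in_j = in_j, out_j = out_j, in_cell = in_cell, out_cell = out_cell,
       Acs = grid$Acs, src_cell = src_cell, src_p = src_p,
       src_blood = src_blood, props = props)
}

# assemble A and rhs for one solve; dt = NULL gives the steady system
.thermal_assemble <- function(sys, u_row, inlet_T, dt = NULL, Told = NULL) {
  m <- sys$rcp_b * sys$Acs[sys$adv_j] * u_row[sys$adv_j]
  up <- ifelse(m >= 0, sys$adv_a, sys$adv_b)
  ii <- c(sys$adv_a, sys$adv_b)
  jj <- c(up, up)
  xx <- c(m, -m)
  rhs <- numeric(sys$ncell)
  rhs[sys$src_cell] <- rhs[sys$src_cell] + sys$src_p
  # inlet faces
  m_in <- sys$rcp_b * sys$Acs[sys$in_j] * u_row[sys$in_j]
  pos <- m_in > 0
  rhs[sys$in_cell[pos]] <- rhs[sys$in_cell[pos]] + m_in[pos] * inlet_T
  if (any(!pos)) {
    ii <- c(ii, sys$in_cell[!pos]); jj <- c(jj, sys$in_cell[!pos])
    xx <- c(xx, -m_in[!pos])
  }
  # outlet faces
  m_out <- sys$rcp_b * sys$Acs[sys$out_j] * u_row[sys$out_j]
  pos <- m_out > 0
  if (any(pos)) {
    ii <- c(ii, sys$out_cell[pos]); jj <- c(jj, sys$out_cell[pos])
    xx <- c(xx, m_out[pos])
  }
  rhs[sys$out_cell[!pos]] <- rhs[sys$out_cell[!pos]] - m_out[!pos] * inlet_T
  A <- sys$Kd + Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                     dims = c(sys$ncell, sys$ncell))
  if (!is.null(dt)) {
    A <- A + Matrix::Diagonal(x = sys$rcp * sys$V / dt)
    rhs <- rhs + sys$rcp * sys$V * Told / dt
  }
  list(A = A, rhs = rhs)
}

.new_temperature <- function(Tmat, times, sys, inlet_T, steady, period = NA) {
  structure(list(T = Tmat, times = times, sys = sys, inlet_T = inlet_T,
                 steady = steady, period = period),
            class = "hx_temperature")
}

#' @export
print.hx_temperature <- function(x, ...) {
  if (x$steady)
    cat(sprintf("hx_temperature (steady): %d cells, range [%.2f, %.2f] C\n",
                nrow(x$T), min(x$T), max(x$T)))
  else
    cat(sprintf("hx_temperature: %d cells x %d saved times, range [%.2f, %.2f] C\n",
                nrow(x$T), ncol(x$T), min(x$T), max(x$T)))
  invisible(x)
}

#' Steady conjugate temperature field
#'
#' Solves the steady energy balance on the zoned grid: upwind advection in
#' blood with the supplied steady velocity profile, conduction everywhere,
#' source power on the internal source band, insulated external boundaries,
#' fixed inlet temperature, advective outflow.
#'
#' @param model An `hx_model`.
#' @param velocity A steady `hx_velocity` from [solve_steady_profile()].
#' @param inlet_T Inlet blood temperature (degC), default 37.
#'
#' @return An `hx_temperature` (single snapshot).
#' @export
solve_steady_temp <- function(model, velocity, inlet_T = 37) {
  sys <- .thermal_system(model)
  asm <- .thermal_assemble(sys, velocity$u, inlet_T)
  Tvec <- tryCatch(
    as.numeric(Matrix::solve(asm$A, asm$rhs)),
    error = function(e) stop(
      "configuration error: singular steady thermal system ",
      "(fully insulated domain with no outflow?): ", conditionMessage(e)))
  resid <- max(abs(asm$A %*% Tvec - asm$rhs))
  if (!all(is.finite(Tvec)) || resid > 1e-6 * (max(abs(asm$rhs)) + 1))
    stop("configuration error: singular steady thermal system ",
         "(fully insulated domain with no outflow?)")
  .new_temperature(matrix(Tvec, ncol = 1), NA, sys, inlet_T, steady = TRUE)
}

#' Transient conjugate temperature field to periodicity
#'
#' Runs whole cardiac cycles of the implicit energy solve with the periodic
#' velocity profiles, starting from a steady field (the two-step
#' steady-to-transient procedure), until the maximum cell-wise change
#' between consecutive end-of-cycle states falls below `tol` or
#' `max_cycles` is reached.  The slow solid-storage mode (thermal time
#' constant of the metal blocks is hundreds of cycles) is removed by
#' dominant-mode Aitken extrapolation of the end-of-cycle states, applied
#' every few cycles; this accelerates convergence to the same discrete
#' periodic fixed point.
#'
#' @param model An `hx_model`.
#' @param velocity An unsteady `hx_velocity` from [solve_unsteady_profile()].
#' @param init An `hx_temperature` to start from (typically
#'   [solve_steady_temp()] at the mean flow).
#' @param inlet_T Inlet blood temperature (degC).
#' @param max_cycles Maximum number of cycles to run.
#' @param tol Periodicity tolerance (degC) on the end-of-cycle state.
#' @param drift_tol Additional convergence requirement: the net heat-storage
#'   drift per cycle (`sum(rho cp V dT) / period`) must fall below
#'   `drift_tol` times the source power, so the reported cycle-averaged
#'   energy balance is meaningful.
#' @param save_cycles Number of final cycles of fields to keep (at the
#'   1e-2 s cadence).
#' @param accelerate Apply Aitken extrapolation between cycles?
#'
#' @return A list with elements `temperature` (an `hx_temperature` holding
#'   the last `save_cycles` cycles) and `report` (cycles run, periodicity
#'   residual in degC, energy-balance error as a fraction of source power,
#'   cell count).
#' @export
solve_transient_temp <- function(model, velocity, init, inlet_T = 37,
                                 max_cycles = 40, tol = 0.02,
                                 drift_tol = 0.005, save_cycles = 5,
                                 accelerate = TRUE) {
  if (isTRUE(velocity$steady))
    stop("velocity must come from solve_unsteady_profile()")
  if (!inherits(init, "hx_temperature"))
    stop("init must be an hx_temperature (two-step: use solve_steady_temp)")
  sys <- init$sys
  n_out <- ncol(velocity$U)
  dt <- velocity$times[1]
  Tcur <- init$T[, ncol(init$T)]
  residual <- Inf
  cycles <- 0
  Tsave <- matrix(NA_real_, sys$ncell, n_out)

  step_cycle <- function(T0) {
    Tk <- T0
    for (k in seq_len(n_out)) {
      asm <- .thermal_assemble(sys, velocity$U[, k], inlet_T,
                               dt = dt, Told = Tk)
      Tk <- as.numeric(Matrix::solve(asm$A, asm$rhs))
      if (any(!is.finite(Tk)))
        stop(sprintf("thermal solver diverged at cycle time %.3f s (cell %d)",
                     k * dt, which(!is.finite(Tk))[1]))
      Tsave[, k] <<- Tk
    }
    Tk
  }

# Anderson acceleration (type II, depth 4) of the end-of-cycle fixed
  # point T -> G(T); for the linear cycle map this acts like GMRES and
  # removes the slow solid-storage mode that plain cycling relaxes with a
  # time constant of hundreds of cycles.
  depth <- if (accelerate) 4L else 0L
  dX <- dF <- NULL
  X <- Tcur; Fprev <- NULL; Xprev <- NULL
  while (cycles < max_cycles) {
    G <- step_cycle(X)
    cycles <- cycles + 1
    Fk <- G - X
    residual <- max(abs(Fk))
    drift_W <- sum(sys$rcp * sys$V * Fk) / velocity$period
    if (residual < tol &&
        abs(drift_W) <= drift_tol * max(sum(sys$src_p), 1e-12)) {
      Tcur <- G
      break
    }
    if (depth > 0L && !is.null(Fprev)) {
      dX <- cbind(dX, X - Xprev)
      dF <- cbind(dF, Fk - Fprev)
      if (ncol(dF) > depth) { dX <- dX[, -1, drop = FALSE]
                              dF <- dF[, -1, drop = FALSE] }
      gam <- tryCatch(qr.solve(dF, Fk), error = function(e) NULL)
      Xnew <- if (!is.null(gam)) G - (dX + dF) %*% gam else G
    } else Xnew <- G
    Xprev <- X; Fprev <- Fk
    X <- as.numeric(Xnew)
    Tcur <- X
  }

  # save the final `save_cycles` cycles (periodic, so re-run from the
  # converged state; keeps memory bounded and the saved window consistent)
  nsave <- max(1, save_cycles)
  Tall <- matrix(NA_real_, sys$ncell, n_out * nsave)
  for (c0 in seq_len(nsave)) {
    Tcur <- step_cycle(Tcur)
    Tall[, (c0 - 1) * n_out + seq_len(n_out)] <- Tsave
  }
  times <- seq_len(n_out * nsave) * dt
  temp <- .new_temperature(Tall, times, sys, inlet_T, steady = FALSE,
                           period = velocity$period)
  gain <- cycle_avg_enthalpy_gain(temp, model, velocity)
  p0 <- sum(sys$src_p)
  report <- list(cycles_run = cycles + nsave,
                 periodicity_residual = residual,
                 energy_balance_error = if (p0 > 0) abs(gain - p0) / p0 else NA,
                 converged = residual < tol,
                 cell_count = sys$ncell)
  list(temperature = temp, report = report)
}

#' Total heat flux carried into the blood
#'
#' Sums the conductive flux over every fluid-solid interface face (plus any
#' source faces applied directly to the lumen wall) at each saved time.
#'
#' @param temp An `hx_temperature`.
#' @param model The `hx_model` the field was computed on.
#' @return A data.frame with columns `t_s` and `Q_blood_W`.
#' @export
total_blood_heat_flux <- function(temp, model) {
  sys <- temp$sys
  direct <- sum(sys$src_p[sys$src_blood])
  q <- vapply(seq_len(ncol(temp$T)), function(k) {
    Tk <- temp$T[, k]
    sum(sys$iface$G * (Tk[sys$iface$solid] - Tk[sys$iface$blood])) + direct
  }, 0)
  data.frame(t_s = if (temp$steady) NA_real_ else temp$times, Q_blood_W = q)
}

# instantaneous enthalpy gain (outflow minus inflow enthalpy flux, W)
.enthalpy_gain_at <- function(sys, Tk, u_row, inlet_T) {
  m_out <- sys$rcp_b * sys$Acs[sys$out_j] * u_row[sys$out_j]
  m_in <- sys$rcp_b * sys$Acs[sys$in_j] * u_row[sys$in_j]
  out_flux <- sum(ifelse(m_out > 0, m_out * Tk[sys$out_cell],
                         m_out * inlet_T))
  in_flux <- sum(ifelse(m_in > 0, m_in * inlet_T, m_in * Tk[sys$in_cell]))
  out_flux - in_flux
}

#' Cycle-averaged blood enthalpy gain
#'
#' Averages the outlet-minus-inlet enthalpy flux over the saved cycles; at
#' the periodic state this equals the source power (the surrogate's global
#' energy balance).
#'
#' @inheritParams total_blood_heat_flux
#' @param velocity The `hx_velocity` used for the solve.
#' @return Enthalpy gain in W (scalar).
#' @export
cycle_avg_enthalpy_gain <- function(temp, model, velocity) {
  sys <- temp$sys
  if (temp$steady)
    return(.enthalpy_gain_at(sys, temp$T[, 1], velocity$u, temp$inlet_T))
  n_out <- ncol(velocity$U)
  vals <- vapply(seq_len(ncol(temp$T)), function(k) {
    uk <- velocity$U[, ((k - 1) %% n_out) + 1]
    .enthalpy_gain_at(sys, temp$T[, k], uk, temp$inlet_T)
  }, 0)
  mean(vals)
}

#' Time-averaged interface temperature profile
#'
#' Averages the blood-contacting interface temperature over a window of
#' saved cycles and reports it against the axial position expressed as a
#' percentage of the exchanger length from its inlet.  In planar mode both
#' the near-side (source side) and far-side lumen walls are reported; the
#' axisymmetric surrogate has a single wall.  Interface temperatures are
#' conductance-weighted between the adjacent fluid and solid cells (exact
#' for the discrete conjugate flux).
#'
#' @inheritParams total_blood_heat_flux
#' @param window Number of cycles to average over (must not exceed the
#'   number of saved cycles); ignored for steady fields.
#' @return A data.frame `(x_pct, T_near_C, T_far_C)` with attributes
#'   `argmax_pct` and `Tmax_C` for the near-side profile (`NULL` when the
#'   profile is flat, e.g. at zero power).
#' @export
interface_temperature_profile <- function(temp, model, window = 5) {
  sys <- temp$sys
  grid <- model$grid
  if (!temp$steady) {
    n_out <- round(temp$period / (temp$times[1]))
    avail <- ncol(temp$T) / n_out
    if (window > avail + 1e-9)
      stop(sprintf("window of %d cycles exceeds the %g saved cycles",
                   window, avail))
    cols <- (ncol(temp$T) - window * n_out + 1):ncol(temp$T)
  } else cols <- 1L
  Tbar <- rowMeans(temp$T[, cols, drop = FALSE])

  fl <- grid$fluid_rows
  j_lo <- fl[1]; j_hi <- fl[length(fl)]
  wall_profile <- function(j_fluid, j_solid, face_y) {
    ii <- which(grid$zone[, j_fluid] == .ZONE_BLOOD &
                  grid$zone[, j_solid] > .ZONE_BLOOD)
    if (!length(ii)) return(NULL)
    cf <- sys$idx[cbind(ii, j_fluid)]
    cs <- sys$idx[cbind(ii, j_solid)]
    df <- abs(grid$y_c[j_fluid] - face_y)
    ds <- abs(grid$y_c[j_solid] - face_y)
    wf <- sys$k[cf] / df; ws <- sys$k[cs] / ds
    data.frame(i = ii,
               T = (wf * Tbar[cf] + ws * Tbar[cs]) / (wf + ws))
  }
  near <- wall_profile(j_hi, j_hi + 1, grid$y_f[j_hi + 1])
  far <- if (grid$mode == "planar_channel")
    wall_profile(j_lo, j_lo - 1, grid$y_f[j_lo]) else NULL
  if (is.null(near)) stop("no blood-contacting interface found")

  x0 <- model$geometry$x_exchanger[1]
  Lex <- model$geometry$exchanger_length
  out <- data.frame(x_pct = (grid$x_c[near$i] - x0) / Lex * 100,
                    T_near_C = near$T,
                    T_far_C = if (!is.null(far)) far$T[match(near$i, far$i)]
                    else NA_real_)
  if (diff(range(out$T_near_C)) > 1e-9) {
    attr(out, "argmax_pct") <- out$x_pct[which.max(out$T_near_C)]
    attr(out, "Tmax_C") <- max(out$T_near_C)
  }
  out
}

#' Outlet-plane temperature statistics
#'
#' Unweighted (area-average, not flux-weighted) mean temperature and
#' area-weighted standard deviation over the outlet fluid cells at each
#' saved time.
#'
#' @inheritParams total_blood_heat_flux
#' @return A data.frame `(t_s, mean_C, sd_C)`.
#' @export
outlet_plane_stats <- function(temp, model) {
  sys <- temp$sys
  A <- sys$Acs[sys$out_j]
  stats <- vapply(seq_len(ncol(temp$T)), function(k) {
    Tv <- temp$T[sys$out_cell, k]
    m <- sum(A * Tv) / sum(A)
    s <- sqrt(sum(A * (Tv - m)^2) / sum(A))
    c(m, s)
  }, c(0, 0))
  data.frame(t_s = if (temp$steady) NA_real_ else temp$times,
             mean_C = stats[1, ], sd_C = stats[2, ])
}

#' Flux-weighted (mixed) outlet temperature history
#'
#' The bulk temperature whose rise over the inlet, multiplied by
#' `rho_b cp_b Q`, gives the instantaneous enthalpy gain.
#'
#' @inheritParams cycle_avg_enthalpy_gain
#' @return A data.frame `(t_s, T_mixed_C)`.
#' @export
outlet_mixed_temperature <- function(temp, model, velocity) {
  sys <- temp$sys
  n_out <- if (temp$steady) 1L else ncol(velocity$U)
  vals <- vapply(seq_len(ncol(temp$T)), function(k) {
    uk <- if (temp$steady) velocity$u else
      velocity$U[, ((k - 1) %% n_out) + 1]
    m <- sys$Acs[sys$out_j] * uk[sys$out_j]
    sum(m * temp$T[sys$out_cell, k]) / sum(m)
  }, 0)
  data.frame(t_s = if (temp$steady) NA_real_ else temp$times,
             T_mixed_C = vals)
}
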