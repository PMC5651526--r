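# Lagrangian platelet / red-blood-cell tracking.
#
# Cells obey d(m_p v)/dt = F_t with the Stokes-drag force
# F_t = m_p (u - v) / tau_p and response time tau_p = rho_p d_p^2 / (18 mu_b).
# tau_p (~1e-7 s) is far below any stable flow step, so the linear drag
# equation is integrated with its exact exponential update per step (no
# sub-stepping, no stiffness).  Wall collisions are resolved by specular
# reflection, which conserves the collision speed exactly.

# exact exponential update of the linear drag equation over one step with
# frozen local fluid velocity u: returns the new position and velocity.
# Used by track_cells() and exercised directly by the validation suite.
.drag_update <- function(x, v, u, tau, dt) {
  e <- exp(-dt / tau)
  list(x = x + u * dt + tau * (1 - e) * (v - u),
       v = u + (v - u) * e)
}

#' Blood cell description
#'
#' @param kind `"platelet"` or `"rbc"`.
#' @param d_p Cell diameter (m); defaults 3 um (platelet) and 7 um (rbc).
#' @param rho_p Cell density (kg/m^3), default 1050.
#' @return An object of class `blood_cell` with the mass
#'   `m_p = rho_p pi d_p^3 / 6`.
#' @export
blood_cell <- function(kind = c("platelet", "rbc"), d_p = NULL, rho_p = 1050) {
  kind <- match.arg(kind)
  if (is.null(d_p)) d_p <- if (kind == "platelet") 3e-6 else 7e-6
  if (d_p <= 0) stop("cell diameter must be positive")
  if (rho_p <= 0) stop("cell density must be positive")
  structure(list(kind = kind, d_p = d_p, rho_p = rho_p,
                 m_p = rho_p * pi * d_p^3 / 6),
            class = "blood_cell")
}

#' Particle response time
#'
#' `tau_p = rho_p d_p^2 / (18 mu)`.
#'
#' @param cell A [blood_cell()].
#' @param mu Local dynamic viscosity (Pa s).
#' @return Response time (s).
#' @examples
#' response_time(blood_cell("platelet"), 0.0035)   # 1.5e-7 s
#' @export
response_time <- function(cell, mu) {
  stopifnot(inherits(cell, "blood_cell"))
  if (any(mu <= 0)) stop("viscosity must be positive")
  if (cell$d_p <= 0) stop("cell diameter must be positive")
  cell$rho_p * cell$d_p^2 / (18 * mu)
}

#' Specular wall reflection
#'
#' Post-collision velocity `v = v_c - 2 (n . v_c) n`; the speed and the
#' tangential velocity component are preserved exactly.
#'
#' @param v_c Velocity vector at impact.
#' @param normal Unit surface normal.
#' @return Reflected velocity vector.
#' @export
reflect <- function(v_c, normal) {
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9)
    stop("normal must be a unit vector")
  v_c - 2 * sum(normal * v_c) * normal
}

# run a block of code with an isolated, seeded RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seed cells on the exchanger-inlet cross-section
#'
#' Platelets are seeded with areal density proportional to the cube of the
#' distance from the vessel centre (margination): in the pipe the radial
#' CDF is `(r/R)^5`; in the planar channel the distance-from-centreline CDF
#' is `(d/(H/2))^4`.  Red blood cells are seeded uniformly over the
#' cross-section.  Positions falling inside the fin splitter are
#' resampled.  Deterministic for a fixed seed.
#'
#' @param kind `"platelet"` or `"rbc"`.
#' @param n Number of cells (>= 0).
#' @param model An `hx_model`.
#' @param seed Integer seed.
#' @param law `"areal"` (default, density prop. to r^3) or `"marginal"`
#'   (radial marginal pdf prop. to r^3, CDF `(r/R)^4`), selecting how the
#'   cubic seeding law is read.
#' @return A data.frame with columns `id`, `kind`, `x`, `y` (m).
#' @export
seed_cells <- function(kind = c("platelet", "rbc"), n, model, seed = 1,
                       law = c("areal", "marginal")) {
  kind <- match.arg(kind)
  law <- match.arg(law)
  if (n < 0) stop("n must be non-negative")
  grid <- model$grid
  x0 <- model$geometry$x_exchanger[1]
  if (n == 0)
    return(data.frame(id = integer(0), kind = character(0),
                      x = numeric(0), y = numeric(0)))
  runs <- .flow_runs(grid)
  lo <- grid$y_f[runs[[1]][1]]
  hi <- grid$y_f[runs[[length(runs)]][length(runs[[length(runs)]])] + 1]
  in_gap <- function(y) {
    bad <- rep(FALSE, length(y))
    if (length(runs) > 1) for (r in seq_len(length(runs) - 1)) {
      g_lo <- grid$y_f[runs[[r]][length(runs[[r]])] + 1]
      g_hi <- grid$y_f[runs[[r + 1]][1]]
      bad <- bad | (y > g_lo & y < g_hi)
    }
    bad
  }
  y <- .with_seed(seed, {
    draw <- function(m) {
      u <- stats::runif(m)
      if (grid$mode == "axisymmetric_pipe") {
        if (kind == "platelet")
          grid$y_f[1] + (hi - lo) * u^(1 / if (law == "areal") 5 else 4)
        else (hi - lo) * sqrt(u)
      } else {
        ctr <- (lo + hi) / 2
        half <- (hi - lo) / 2
        if (kind == "platelet") {
          d <- half * u^(1 / if (law == "areal") 4 else 3)
          ctr + d * sample(c(-1, 1), m, replace = TRUE)
        } else lo + (hi - lo) * u
      }
    }
    y <- draw(n)
    for (it in 1:100) {
      bad <- in_gap(y)
      if (!any(bad)) break
      y[bad] <- draw(sum(bad))
    }
    y
  })
  data.frame(id = seq_len(n), kind = kind, x = x0, y = y)
}

# interpolation knots (walls + cell centres) for profiles over the flow runs
.flow_knots <- function(grid) {
  runs <- .flow_runs(grid)
  yk <- numeric(0); rows <- integer(0); is_wall <- logical(0)
  run_id <- integer(0)
  for (r in seq_along(runs)) {
    rr <- runs[[r]]
    yk <- c(yk, grid$y_f[rr[1]], grid$y_c[rr], grid$y_f[rr[length(rr)] + 1])
    rows <- c(rows, NA, rr, NA)
    is_wall <- c(is_wall, TRUE, rep(FALSE, length(rr)), TRUE)
    run_id <- c(run_id, rep(r, length(rr) + 2))
  }
  list(y = yk, rows = rows, is_wall = is_wall, run_id = run_id, runs = runs)
}

# profile values on knots (zero at walls) for one saved time column
.knot_profile <- function(knots, u_full) {
  v <- numeric(length(knots$y))
  inner <- !knots$is_wall
  v[inner] <- u_full[knots$rows[inner]]
  v
}

#' Track cells through the periodic flow and temperature fields
#'
#' Integrates the drag equation with the exact exponential update per
#' 1e-2 s output step, advances positions, resolves wall crossings by
#' specular reflection at the crossing point, samples the fluid temperature
#' at the cell location by bilinear interpolation, and stops a cell when it
#' reaches a domain outlet.  The response time uses the local
#' Carreau-Yasuda viscosity by default.
#'
#' @param cells A data.frame from [seed_cells()] (rows of both kinds may be
#'   concatenated).
#' @param velocity A periodic `hx_velocity` from [solve_unsteady_profile()].
#' @param temp An `hx_temperature` from [solve_transient_temp()].
#' @param model The `hx_model`.
#' @param params [cy_params()] rheology for the local viscosity.
#' @param n_cycles Total cycles of tracking horizon (default 10).
#' @param discard_first Release the cells at the start of cycle 2 and track
#'   for the remaining `n_cycles - 1` cycles (the analysed cycles).
#' @param mu_mode `"local"` (Carreau-Yasuda at the cell location) or
#'   `"constant"` (infinite-shear viscosity).
#' @return An object of class `hx_trajectories`: lists `times`, matrices
#'   `x`, `y`, `T` (cells x samples, `NA` after exit), the `cells` table,
#'   `exit_status` (`"outlet"` or `"max_time"`) and `exit_time`.
#' @export
track_cells <- function(cells, velocity, temp, model, params = cy_params(),
                        n_cycles = 10, discard_first = TRUE,
                        mu_mode = c("local", "constant")) {
  mu_mode <- match.arg(mu_mode)
  if (isTRUE(velocity$steady)) stop("velocity must be periodic (unsteady)")
  if (temp$steady) stop("temperature field must be transient (periodic)")
  grid <- model$grid
  period <- velocity$period
  dt <- velocity$times[1]
  n_out <- ncol(velocity$U)
  knots <- .flow_knots(grid)
  nk <- length(knots$y)

  # temperature sampler: last saved cycle, values on (x_c, knots) grid
  last <- (ncol(temp$T) - n_out + 1):ncol(temp$T)
  Tarr <- array(NA_real_, c(grid$nx, nk, n_out))
  sys <- temp$sys
  for (kk in seq_len(n_out)) {
    Tc <- temp$T[, last[kk]]
    M <- matrix(NA_real_, grid$nx, nk)
    for (q in which(!knots$is_wall))
      M[, q] <- Tc[sys$idx[cbind(seq_len(grid$nx), knots$rows[q])]]
    for (q in which(knots$is_wall)) {
      adj <- if (q == 1 || knots$is_wall[q - 1]) q + 1 else q - 1
      j_f <- knots$rows[adj]
      j_s <- knots$rows[adj] + if (adj < q) 1L else -1L
      Tw <- M[, adj]
      if (j_s >= 1 && j_s <= grid$ny) {
        has_solid <- grid$zone[, j_s] > .ZONE_BLOOD
        if (any(has_solid)) {
          cf <- sys$idx[cbind(which(has_solid), j_f)]
          cs <- sys$idx[cbind(which(has_solid), j_s)]
          df <- abs(grid$y_c[j_f] - knots$y[q])
          ds <- abs(grid$y_c[j_s] - knots$y[q])
          wf <- sys$k[cf] / df; ws <- sys$k[cs] / ds
          Tw[has_solid] <- (wf * Tc[cf] + ws * Tc[cs]) / (wf + ws)
        }
      }
      M[, q] <- Tw
    }
    Tarr[, , kk] <- M
  }

  n_cells <- nrow(cells)
  t0 <- if (discard_first) period else 0
  t_end <- n_cycles * period
  n_steps <- round((t_end - t0) / dt)
  times <- t0 + (0:n_steps) * dt

  x <- cells$x; y <- cells$y
  run_of <- vapply(y, function(yy) {
    r <- which(vapply(knots$runs, function(rr)
      yy >= grid$y_f[rr[1]] - 1e-15 &&
        yy <= grid$y_f[rr[length(rr)] + 1] + 1e-15, TRUE))
    if (!length(r)) stop("seeded cell outside the flow passage")
    r[1]
  }, 0L)
  wall_lo <- vapply(knots$runs, function(rr) grid$y_f[rr[1]], 0)
  wall_hi <- vapply(knots$runs, function(rr) grid$y_f[rr[length(rr)] + 1], 0)
  tau_ref <- vapply(seq_len(n_cells), function(c0)
    response_time(blood_cell(cells$kind[c0]), params$mu_inf), 0)
  d_p <- ifelse(cells$kind == "platelet", 3e-6, 7e-6)
  rho_p <- 1050

  col_at <- function(t) {
    k <- round((t %% period) / dt) %% n_out
    if (k == 0) n_out else k
  }
  u_knots_at <- function(t) .knot_profile(knots, velocity$U[, col_at(t)])
  sample_T <- function(xs, ys, t) {
    kk <- col_at(t)
    ix <- findInterval(xs, grid$x_c, all.inside = TRUE)
    wx <- pmin(1, pmax(0, (xs - grid$x_c[ix]) /
                         (grid$x_c[ix + 1] - grid$x_c[ix])))
    iy <- findInterval(ys, knots$y, all.inside = TRUE)
    wy <- pmin(1, pmax(0, (ys - knots$y[iy]) /
                         (knots$y[iy + 1] - knots$y[iy])))
    T00 <- Tarr[cbind(ix, iy, kk)]; T10 <- Tarr[cbind(ix + 1, iy, kk)]
    T01 <- Tarr[cbind(ix, iy + 1, kk)]; T11 <- Tarr[cbind(ix + 1, iy + 1, kk)]
    (1 - wx) * (1 - wy) * T00 + wx * (1 - wy) * T10 +
      (1 - wx) * wy * T01 + wx * wy * T11
  }

  uk0 <- u_knots_at(t0)
  u_loc <- stats::approx(knots$y, uk0, xout = y, rule = 2)$y
  vx <- u_loc; vy <- rep(0, n_cells)

  X <- Y <- TT <- matrix(NA_real_, n_cells, n_steps + 1)
  X[, 1] <- x; Y[, 1] <- y; TT[, 1] <- sample_T(x, y, t0)
  active <- rep(TRUE, n_cells)
  exit_time <- rep(NA_real_, n_cells)
  exit_status <- rep("max_time", n_cells)
  L <- model$geometry$domain_length

  for (s in seq_len(n_steps)) {
    if (!any(active)) break
    t_new <- t0 + s * dt
    uk <- u_knots_at(t_new)
    a <- which(active)
    u_loc <- stats::approx(knots$y, uk, xout = y[a], rule = 2)$y
    if (mu_mode == "local") {
      iy <- findInterval(y[a], knots$y, all.inside = TRUE)
      gdot <- abs(uk[iy + 1] - uk[iy]) / (knots$y[iy + 1] - knots$y[iy])
      mu_loc <- cy_viscosity(gdot, params)
    } else mu_loc <- rep(params$mu_inf, length(a))
    tau <- rho_p * d_p[a]^2 / (18 * mu_loc)
    upd_x <- .drag_update(x[a], vx[a], u_loc, tau, dt)
    x[a] <- upd_x$x; vx[a] <- upd_x$v
    upd_y <- .drag_update(y[a], vy[a], 0, tau, dt)
    y_new <- upd_y$x; vy_new <- upd_y$v
    # specular reflection at the run walls
    lo <- wall_lo[run_of[a]]; hi <- wall_hi[run_of[a]]
    for (it in 1:50) {
      below <- y_new < lo; above <- y_new > hi
      if (!any(below | above)) break
      y_new[below] <- 2 * lo[below] - y_new[below]
      vy_new[below] <- -vy_new[below]
      y_new[above] <- 2 * hi[above] - y_new[above]
      vy_new[above] <- -vy_new[above]
    }
    y[a] <- y_new; vy[a] <- vy_new
    gone <- x[a] >= L | x[a] <= 0
    if (any(gone)) {
      gi <- a[gone]
      exit_time[gi] <- t_new
      exit_status[gi] <- "outlet"
      active[gi] <- FALSE
    }
    keep <- a[!gone]
    if (length(keep)) {
      X[keep, s + 1] <- x[keep]
      Y[keep, s + 1] <- y[keep]
      TT[keep, s + 1] <- sample_T(x[keep], y[keep], t_new)
    }
  }
  exit_time[is.na(exit_time)] <- t_end
  structure(list(times = times, x = X, y = Y, T = TT, cells = cells,
                 exit_status = exit_status, exit_time = exit_time,
                 t0 = t0, period = period),
            class = "hx_trajectories")
}

#' @export
print.hx_trajectories <- function(x, ...) {
  cat(sprintf("hx_trajectories: %d cells, %d samples at %.3g s cadence; %d exited, %d reached max time\n",
              nrow(x$cells), length(x$times), diff(x$times[1:2]),
              sum(x$exit_status == "outlet"), sum(x$exit_status == "max_time")))
  invisible(x)
}

#' @export
as.data.frame.hx_trajectories <- function(x, ...) {
  n <- nrow(x$cells)
  out <- do.call(rbind, lapply(seq_len(n), function(c0) {
    ok <- !is.na(x$x[c0, ])
    data.frame(cell_id = x$cells$id[c0], kind = x$cells$kind[c0],
               t_s = x$times[ok], x_m = x$x[c0, ok], y_m = x$y[c0, ok],
               T_C = x$T[c0, ok])
  }))
  rownames(out) <- NULL
  out
}
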