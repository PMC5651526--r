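# Closed-form references used by the test-suite.  These are kept strictly
# independent of the solver modules: nothing here calls the finite-volume
# code, so a test comparing the two is a genuine cross-check.

# complex Bessel J0/J1 by power series (adequate for |z| <~ 30, which
# covers Womersley numbers up to ~20)
.cbesselJ <- function(z, nu = 0) {
  s <- 0 + 0i
  term <- if (nu == 0) 1 + 0i else z / 2
  k <- 0
  repeat {
    s <- s + term
    k <- k + 1
    term <- term * (-(z / 2)^2) / (k * (k + nu))
    if (abs(term) < 1e-18 * (abs(s) + 1e-300) || k > 200) break
  }
  s
}

#' Poiseuille profile oracle
#'
#' Exact fully developed Newtonian profile carrying flow `q`: parabolic with
#' centreline/mean ratio 2 (pipe) or 1.5 (planar channel).
#'
#' @param q Volumetric flow (m^3/s).
#' @param y Transverse evaluation points: radius in `[0, R]` (pipe) or
#'   height in `[0, H]` (channel).
#' @param lumen_size Pipe radius `R` or channel height `H` (m).
#' @param mode `"axisymmetric_pipe"` or `"planar_channel"`.
#' @param depth Out-of-plane depth (planar mode).
#' @return Velocity (m/s) at `y`.
#' @export
poiseuille_profile <- function(q, y, lumen_size,
                               mode = c("axisymmetric_pipe", "planar_channel"),
                               depth = 1) {
  mode <- match.arg(mode)
  if (mode == "axisymmetric_pipe") {
    R <- lumen_size
    u_mean <- q / (pi * R^2)
    2 * u_mean * (1 - (y / R)^2)
  } else {
    H <- lumen_size
    u_mean <- q / (depth * H)
    1.5 * u_mean * (1 - (2 * y / H - 1)^2)
  }
}

#' Womersley pulsatile pipe-flow oracle
#'
#' Analytic oscillatory laminar profile in a rigid pipe for a flow waveform
#' given as harmonics `Q(t) = q0 + sum_n Re(Qn exp(i n w t))`.  Each
#' harmonic uses the Bessel-function solution with Womersley number
#' `alpha_n = R sqrt(n w rho / mu)`; the zero-frequency part is Poiseuille.
#'
#' @param q0 Mean flow (m^3/s).
#' @param q_harm Complex vector of harmonic flow amplitudes `Qn`
#'   (n = 1, 2, ...); may be empty.
#' @param R Pipe radius (m).
#' @param mu Dynamic viscosity (Pa s), Newtonian.
#' @param rho Density (kg/m^3).
#' @param period Fundamental period (s).
#' @param r Radial evaluation points in `[0, R]`.
#' @param t Evaluation time (s).
#' @return Velocity (m/s) at `r`.
#' @export
womersley_profile <- function(q0, q_harm, R, mu, rho, period, r, t) {
  w <- 2 * pi / period
  u <- poiseuille_profile(q0, r, R, "axisymmetric_pipe")
  for (n in seq_along(q_harm)) {
    if (q_harm[n] == 0) next
    lam <- complex(modulus = 1, argument = 3 * pi / 4) *
      R * sqrt(n * w * rho / mu)
    J0l <- .cbesselJ(lam, 0)
    J1l <- .cbesselJ(lam, 1)
    f <- 1 - vapply(r, function(rr) .cbesselJ(lam * rr / R, 0), 0i) / J0l
    I <- pi * R^2 * (1 - 2 * J1l / (lam * J0l))
    u <- u + Re(q_harm[n] * f / I * exp(1i * n * w * t))
  }
  u
}

#' Developed-region Nusselt numbers (Graetz oracle)
#'
#' Classical constant-property laminar values: `48/11 = 4.364` for a pipe
#' with constant wall flux, `5.385` for parallel plates with one side at
#' constant flux and the other adiabatic (hydraulic diameter `2H`).  Both
#' are independent of the flow rate.
#'
#' @param mode `"axisymmetric_pipe"` or `"planar_channel"`.
#' @return The Nusselt number.
#' @export
graetz_nusselt <- function(mode = c("axisymmetric_pipe", "planar_channel")) {
  mode <- match.arg(mode)
  if (mode == "axisymmetric_pipe") 48 / 11 else 5.385
}

#' Transient slab-conduction oracle
#'
#' 1-D slab `0 <= x <= l`, uniform initial temperature `T0`, constant flux
#' `q` applied at `x = 0`, insulated at `x = l`:
#' `T = T0 + (q l / k) [Fo + (3 (1 - x/l)^2 - 1)/6
#'    - (2/pi^2) sum e^{-n^2 pi^2 Fo} cos(n pi x / l) / n^2]`
#' with Fourier number `Fo = alpha t / l^2`.
#'
#' @param x Positions (m), measured from the heated face.
#' @param t Time (s).
#' @param l Slab thickness (m).
#' @param k Thermal conductivity (W/m/K).
#' @param rho_cp Volumetric heat capacity (J/m^3/K).
#' @param q Applied flux (W/m^2).
#' @param T0 Initial temperature (degC).
#' @param n_terms Series terms (truncation error < 1e-8 with the default).
#' @return Temperature (degC) at `x`.
#' @export
slab_conduction <- function(x, t, l, k, rho_cp, q, T0 = 37, n_terms = 5000) {
  alpha <- k / rho_cp
  Fo <- alpha * t / l^2
  xi <- x / l
  n <- seq_len(n_terms)
  series <- vapply(xi, function(z)
    sum(exp(-n^2 * pi^2 * Fo) * cos(n * pi * z) / n^2), 0)
  T0 + (q * l / k) * (Fo + (3 * (1 - xi)^2 - 1) / 6 - 2 / pi^2 * series)
}

#' Local Nusselt number from a steady duct solution
#'
#' Measures the discrete local Nusselt number of a heated fluid-only duct
#' model at axial station `x_eval`: wall flux from the source table, wall
#' temperature extrapolated from the wall-adjacent cell, bulk temperature
#' flux-weighted over the cross-section.  Pipe: `Nu = q'' D /(k (Tw - Tb))`;
#' planar one-side-heated: hydraulic diameter `2H`.
#'
#' @param temp Steady `hx_temperature` on a [build_duct_model()] grid.
#' @param model The duct `hx_model`.
#' @param velocity The steady `hx_velocity` used.
#' @param x_eval Axial position (m).
#' @return The local Nusselt number.
#' @export
local_nusselt <- function(temp, model, velocity, x_eval) {
  grid <- model$grid
  sys <- temp$sys
  i <- which.min(abs(grid$x_c - x_eval))
  Tv <- temp$T[, 1]
  kb <- get_material("blood", model$materials$blood)$k
  st <- model$source_table
  qpp <- st$flux[match(i, st$i)]
  if (is.na(qpp)) stop("x_eval lies outside the heated band")
  jw <- grid$ny                       # heated wall-adjacent row (top wall)
  cw <- sys$idx[i, jw]
  delta <- grid$y_f[grid$ny + 1] - grid$y_c[jw]
  Tw <- Tv[cw] + qpp * delta / kb
  rows <- seq_len(grid$ny)
  cc <- sys$idx[cbind(i, rows)]
  m <- velocity$u[rows] * grid$Acs[rows]
  Tb <- sum(m * Tv[cc]) / sum(m)
  Dh <- if (grid$mode == "axisymmetric_pipe") 2 * model$geometry$lumen_size
        else 2 * model$geometry$lumen_size
  qpp * Dh / (kb * (Tw - Tb))
}
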