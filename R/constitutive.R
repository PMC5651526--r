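#' Carreau-Yasuda blood rheology parameters
#'
#' Container for the five Carreau-Yasuda constants plus blood density.
#' Defaults are the standard literature values for human blood used
#' throughout this package: zero-shear viscosity 0.16 Pa s, infinite-shear
#' viscosity 0.0035 Pa s, time constant 8.2 s, power index 0.2128,
#' transition exponent 0.64, density 1050 kg/m^3.
#'
#' @param mu0 Zero-shear-rate viscosity (Pa s).
#' @param mu_inf Infinite-shear-rate viscosity (Pa s).
#' @param lambda Relaxation time constant (s).
#' @param n Power-law index (dimensionless, 0 < n < 1).
#' @param a Yasuda transition exponent (dimensionless, > 0).
#' @param rho Blood density (kg/m^3).
#'
#' @return An object of class `cy_params`.
#' @examples
#' p <- cy_params()
#' cy_viscosity(c(0.01, 1, 100), p)
#' @export
cy_params <- function(mu0 = 0.16, mu_inf = 0.0035, lambda = 8.2,
                      n = 0.2128, a = 0.64, rho = 1050) {
  stopifnot(is.numeric(mu0), is.numeric(mu_inf), is.numeric(lambda),
            is.numeric(n), is.numeric(a), is.numeric(rho))
  if (!(mu0 >= mu_inf && mu_inf > 0))
    stop("cy_params: require mu0 >= mu_inf > 0")
  if (lambda <= 0) stop("cy_params: lambda must be positive")
  if (a <= 0) stop("cy_params: a must be positive")
  if (n <= 0 || n > 1) stop("cy_params: require 0 < n <= 1")
  if (rho <= 0) stop("cy_params: rho must be positive")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda,
                 n = n, a = a, rho = rho),
            class = "cy_params")
}

#' @export
print.cy_params <- function(x, ...) {
  cat("Carreau-Yasuda parameters:\n")
  cat(sprintf("  mu0 = %g Pa s, mu_inf = %g Pa s\n", x$mu0, x$mu_inf))
  cat(sprintf("  lambda = %g s, n = %g, a = %g, rho = %g kg/m^3\n",
              x$lambda, x$n, x$a, x$rho))
  invisible(x)
}

#' Carreau-Yasuda apparent viscosity
#'
#' Shear-thinning viscosity
#' `mu = mu_inf + (mu0 - mu_inf) * (1 + (lambda*gdot)^a)^((n-1)/a)`.
#' Continuous and non-increasing in the shear rate, bounded by the two
#' asymptotic viscosities.  Vectorised over `gamma_dot`.
#'
#' @param gamma_dot Scalar shear rate(s), 1/s, non-negative.
#' @param params A [cy_params()] object.
#'
#' @return Apparent viscosity in Pa s, same length as `gamma_dot`.
#' @export
cy_viscosity <- function(gamma_dot, params = cy_params()) {
  if (!inherits(params, "cy_params")) stop("params must be a cy_params object")
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("cy_viscosity: shear rate must be finite and non-negative")
  with(params, mu_inf + (mu0 - mu_inf) *
         (1 + (lambda * gamma_dot)^a)^((n - 1) / a))
}

# Table of thermal material properties.  Heat capacity and conductivity of
# all four materials and the blood density come from the problem's standard
# data; solid densities are handbook defaults (steady fields do not depend
# on them, only transient solid heat storage does).
.hx_materials <- data.frame(
  name = c("aluminum", "titanium", "copper", "blood"),
  rho  = c(2700, 4506, 8960, 1050),
  cp   = c(900, 710, 385, 3650),
  k    = c(238, 7.5, 400, 0.5),
  stringsAsFactors = FALSE
)

#' Thermal material properties
#'
#' Looks up density, specific heat, and thermal conductivity for one of the
#' four materials in the conjugate model (aluminum, titanium, copper, blood).
#' Individual values may be overridden, e.g. to change a solid density.
#'
#' @param name One of `"aluminum"`, `"titanium"`, `"copper"`, `"blood"`.
#' @param overrides Optional named list with any of `rho`, `cp`, `k`.
#'
#' @return An object of class `material_props` with fields `name`, `rho`
#'   (kg/m^3), `cp` (J/kg/K), `k` (W/m/K).
#' @examples
#' get_material("titanium")$k   # 7.5 W/(m K)
#' @export
get_material <- function(name, overrides = NULL) {
  i <- match(name, .hx_materials$name)
  if (is.na(i))
    stop("unknown material '", name, "'; supported: ",
         paste(.hx_materials$name, collapse = ", "))
  m <- as.list(.hx_materials[i, ])
  for (f in intersect(names(overrides), c("rho", "cp", "k")))
    m[[f]] <- overrides[[f]]
  if (any(unlist(m[c("rho", "cp", "k")]) <= 0))
    stop("material properties must be positive")
  structure(m, class = "material_props")
}

# zone ids used on grids
.ZONE_VOID <- 0L
.ZONE_BLOOD <- 1L
.ZONE_TITANIUM <- 2L
.ZONE_ALUMINUM <- 3L
.ZONE_COPPER <- 4L

.zone_names <- c("blood", "titanium", "aluminum", "copper")

.zone_id <- function(material) {
  match(material, .zone_names)
}

# per-zone property vectors indexed by zone id (1..4)
.zone_props <- function(material_overrides = NULL) {
  mats <- lapply(.zone_names, function(nm)
    get_material(nm, overrides = material_overrides[[nm]]))
  list(rho = vapply(mats, `[[`, 0, "rho"),
       cp  = vapply(mats, `[[`, 0, "cp"),
       k   = vapply(mats, `[[`, 0, "k"))
}
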