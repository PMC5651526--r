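#' Heat-source specification
#'
#' The implanted power source is a cylinder; its surface ejects a total
#' power `P0` so the physical surface flux is `P0/A` with `A` the lateral
#' cylinder area `pi * d * h` (end caps excluded by default, configurable).
#'
#' @param power Total heat output (W), e.g. 64 (TAH-rated) or 24 (LVAD-rated).
#' @param diameter Source cylinder diameter (m).
#' @param height Source cylinder height (m).
#' @param include_caps Include the two end caps in the source area?
#'
#' @return An object of class `heat_source_spec` with fields `power`,
#'   `diameter`, `height`, `area` (m^2), `flux` (W/m^2).
#' @examples
#' heat_source_spec(64, 0.046, 0.01)$flux    # ~4.43e4 W/m^2
#' @export
heat_source_spec <- function(power, diameter, height, include_caps = FALSE) {
  if (power < 0) stop("power must be non-negative")
  if (diameter <= 0 || height <= 0) stop("source dimensions must be positive")
  area <- pi * diameter * height
  if (include_caps) area <- area + 2 * pi * diameter^2 / 4
  structure(list(power = power, diameter = diameter, height = height,
                 area = area, flux = power / area),
            class = "heat_source_spec")
}

#' Surface heat flux of a source specification
#' @param spec A [heat_source_spec()].
#' @return Flux `power/area` in W/m^2.
#' @export
source_flux <- function(spec) {
  stopifnot(inherits(spec, "heat_source_spec"))
  if (spec$area <= 0) stop("source area must be positive")
  spec$power / spec$area
}

# ---- design tables -------------------------------------------------------

.design_table <- list(
  base64     = list(power = 64, src_d = 0.046, src_h = 0.01,
                    hc_thick = 0.031, fins = FALSE, guide = FALSE,
                    mode = "axisymmetric_pipe"),
  base24     = list(power = 24, src_d = 0.028, src_h = 0.01,
                    hc_thick = 0.031, fins = FALSE, guide = FALSE,
                    mode = "axisymmetric_pipe"),
  fins64     = list(power = 64, src_d = 0.046, src_h = 0.01,
                    hc_thick = 0.031, fins = TRUE, guide = FALSE,
                    mode = "planar_channel"),
  finsguide64 = list(power = 64, src_d = 0.046, src_h = 0.01,
                    hc_thick = 0.043, fins = TRUE, guide = TRUE,
                    mode = "planar_channel")
)

# one-sided stretched faces on [a, b]; fine end at `a` if fine == "lo"
.stretch_faces <- function(a, b, n, ratio = 1.25, fine = "lo") {
  if (n == 1) return(c(a, b))
  if (abs(ratio - 1) < 1e-9) return(seq(a, b, length.out = n + 1))
  f <- (ratio^(0:n) - 1) / (ratio^n - 1)
  if (fine == "hi") f <- 1 - rev(f)
  a + (b - a) * f
}

# two-sided (fine at both ends) faces on [a, b] with n cells (n rounded even)
.stretch_faces2 <- function(a, b, n, ratio = 1.25) {
  n2 <- max(2, ceiling(n / 2))
  mid <- (a + b) / 2
  lo <- .stretch_faces(a, mid, n2, ratio, fine = "lo")
  hi <- .stretch_faces(mid, b, n2, ratio, fine = "hi")
  c(lo, hi[-1])
}

# ---- surrogate geometry + grid ------------------------------------------

#' Build the reduced-dimension surrogate model for a heat-exchanger design
#'
#' Constructs the zoned finite-volume grid, the geometry description, and
#' the heat-source specification for one of the four configurations:
#' `base64`, `base24` (axisymmetric pipe surrogates by default), `fins64`
#' and `finsguide64` (planar channel surrogates).  The planar surrogate has
#' independent near-side (source) and far-side solid blocks and carries the
#' full descending-aorta flow and source power with an effective
#' out-of-plane depth of half the mean lumen perimeter per side, which
#' preserves the mixed-temperature rise `P0/(rho_b cp Q)`.
#'
#' The source cylinder stands on the near side with its axis normal to the
#' vessel, so its axial footprint is its diameter, centred at 50% of the
#' exchanger length; the power is injected on an internal face band at a
#' standoff depth inside the aluminum housing (default 0.8 cm from the
#' lumen).
#'
#' @param design One of `"base64"`, `"base24"`, `"fins64"`, `"finsguide64"`.
#' @param resolution Axial grid resolution in cells per cm (>= 2).
#' @param mode Optional override of the surrogate mode
#'   (`"axisymmetric_pipe"` or `"planar_channel"`).  Base designs may be
#'   run in planar mode to expose the near/far-side asymmetry; fins
#'   designs require the planar mode.
#' @param overrides Named list of geometry overrides: `lumen_diameter`,
#'   `exchanger_length`, `inlet_run`, `outlet_run`, `ti_wall`,
#'   `hc_thickness`, `far_al`, `power`, `source_diameter`, `source_height`,
#'   `source_standoff`, `fin_thickness`, `guide_thickness`,
#'   `guide_standoff_lumen`, `guide_standoff_source`, `guide_margin`,
#'   `n_fluid`, `stretch_ratio`, `materials` (see [get_material()]).
#'
#' @return An object of class `hx_model`: a list with elements `geometry`,
#'   `grid`, `source` (the `heat_source_spec`), and `source_table` (the
#'   per-face flux table from [map_power_to_surrogate()]).
#' @examples
#' m <- build_design("base64", resolution = 3)
#' m$geometry$exchanger_length      # 0.10 m
#' @export
build_design <- function(design = c("base64", "base24", "fins64", "finsguide64"),
                         resolution = 4, mode = NULL, overrides = list()) {
  design <- match.arg(design)
  if (resolution < 2) stop("resolution must be at least 2 cells/cm")
  d <- .design_table[[design]]
  ov <- function(key, default) if (!is.null(overrides[[key]])) overrides[[key]] else default

  mode <- if (!is.null(mode)) mode else d$mode
  mode <- match.arg(mode, c("axisymmetric_pipe", "planar_channel"))
  fins <- d$fins
  if (fins && mode == "axisymmetric_pipe")
    stop("configuration error: fins designs require the planar_channel mode")

  Dlum  <- ov("lumen_diameter", 0.022)
  Lex   <- ov("exchanger_length", 0.10)
  run_i <- ov("inlet_run", 0.065)
  run_o <- ov("outlet_run", 0.065)
  t_ti  <- ov("ti_wall", 0.0015)
  t_hc  <- ov("hc_thickness", d$hc_thick)
  t_far <- ov("far_al", 0.010)
  power <- ov("power", d$power)
  src_d <- ov("source_diameter", d$src_d)
  src_h <- ov("source_height", d$src_h)
  stand <- ov("source_standoff", 0.008)
  t_fin <- ov("fin_thickness", 0.002)
  t_cu  <- ov("guide_thickness", 0.0025)
  cu_sl <- ov("guide_standoff_lumen", 0.0015)
  cu_ss <- ov("guide_standoff_source", 0.0025)
  cu_mg <- ov("guide_margin", 0.01)
  ratio <- ov("stretch_ratio", 1.25)
  n_fl  <- ov("n_fluid", max(24, 8 * round(resolution)))

  if (t_hc <= stand + t_ti)
    stop("hc_thickness must exceed source standoff plus titanium wall")
  if (d$guide && cu_sl < 0.0015 - 1e-12)
    stop("heat guide must keep a >= 0.15 cm standoff from the lumen")

  x0 <- run_i
  x1 <- run_i + Lex
  L  <- run_i + Lex + run_o
  xc <- (x0 + x1) / 2
  band <- c(max(x0, xc - src_d / 2), min(x1, xc + src_d / 2))

  depth <- if (mode == "planar_channel") ov("depth", pi * Dlum / 2) else NA_real_

  geometry <- structure(list(
    design = design, mode = mode,
    lumen_size = if (mode == "axisymmetric_pipe") Dlum / 2 else Dlum,
    lumen_diameter = Dlum,
    exchanger_length = Lex, inlet_run = run_i, outlet_run = run_o,
    domain_length = L, x_exchanger = c(x0, x1),
    source_band = band, source_standoff = stand,
    ti_wall = t_ti, hc_thickness = t_hc, far_al = t_far,
    fins = fins, fin_thickness = t_fin,
    heat_guide = d$guide, guide_thickness = t_cu,
    guide_standoff_lumen = cu_sl, guide_standoff_source = cu_ss,
    guide_margin = cu_mg, depth = depth), class = "hx_geometry")

  spec <- heat_source_spec(power, src_d, src_h)

  grid <- .build_grid(geometry, resolution, n_fl, ratio)
  model <- structure(list(geometry = geometry, grid = grid, source = spec,
                          materials = ov("materials", NULL)),
                     class = "hx_model")
  model$source_table <- map_power_to_surrogate(spec, model)
  model
}

# segment descriptor: y-extent, cell count, zone inside the exchanger
# window, zone outside it (VOID for solids, BLOOD for fluid), optional
# x-range restriction replacing the window zone elsewhere by `alt`.
.seg <- function(h, n, zone_in, zone_out = .ZONE_VOID,
                 fluid = FALSE, faces = NULL, x_range = NULL, alt = NULL) {
  list(h = h, n = n, zone_in = zone_in, zone_out = zone_out,
       fluid = fluid, faces = faces, x_range = x_range, alt = alt)
}

.build_grid <- function(geom, resolution, n_fluid, ratio) {
  res_m <- resolution * 100              # cells per metre
  L <- geom$domain_length
  nx <- max(4, ceiling(L * res_m))
  x_f <- seq(0, L, length.out = nx + 1)
  x_c <- (x_f[-1] + x_f[-(nx + 1)]) / 2
  dx <- diff(x_f)

  nsolid <- function(th) max(2, ceiling(th * res_m / 2))
  H <- geom$lumen_size                   # pipe radius or channel height
  t_ti <- geom$ti_wall

  segs <- list()
  if (geom$mode == "axisymmetric_pipe") {
    segs <- c(segs, list(.seg(NA, n_fluid, .ZONE_BLOOD, .ZONE_BLOOD,
                              fluid = TRUE,
                              faces = .stretch_faces(0, H, n_fluid, ratio,
                                                     fine = "hi"))))
    al_a <- geom$source_standoff - t_ti
    al_b <- geom$hc_thickness - geom$source_standoff
    segs <- c(segs, list(
      .seg(t_ti, nsolid(t_ti), .ZONE_TITANIUM),
      .seg(al_a, nsolid(al_a), .ZONE_ALUMINUM),
      .seg(al_b, nsolid(al_b), .ZONE_ALUMINUM)))
    src_face_after_seg <- 3              # source plane at outer face of seg 3
  } else {
    gx <- c(geom$x_exchanger[1] + geom$guide_margin,
            geom$x_exchanger[2] - geom$guide_margin)
    # far-side block (outermost first), then fluid, then near-side block
    if (geom$heat_guide) {
      segs <- c(segs, list(
        .seg(geom$far_al, nsolid(geom$far_al), .ZONE_ALUMINUM),
        .seg(geom$guide_thickness, nsolid(geom$guide_thickness),
             .ZONE_COPPER, x_range = gx, alt = .ZONE_ALUMINUM),
        .seg(t_ti, nsolid(t_ti), .ZONE_TITANIUM)))
    } else {
      segs <- c(segs, list(
        .seg(geom$far_al, nsolid(geom$far_al), .ZONE_ALUMINUM),
        .seg(t_ti, nsolid(t_ti), .ZONE_TITANIUM)))
    }
    if (geom$fins) {
      h_sub <- (H - geom$fin_thickness) / 2
      n_sub <- max(16, ceiling(n_fluid / 2))
      segs <- c(segs, list(
        .seg(NA, n_sub, .ZONE_BLOOD, .ZONE_BLOOD, fluid = TRUE,
             faces = .stretch_faces2(0, h_sub, n_sub, ratio)),
        .seg(geom$fin_thickness, 2, .ZONE_TITANIUM, .ZONE_BLOOD),
        .seg(NA, n_sub, .ZONE_BLOOD, .ZONE_BLOOD, fluid = TRUE,
             faces = .stretch_faces2(0, h_sub, n_sub, ratio))))
    } else {
      segs <- c(segs, list(
        .seg(NA, n_fluid, .ZONE_BLOOD, .ZONE_BLOOD, fluid = TRUE,
             faces = .stretch_faces2(0, H, n_fluid, ratio))))
    }
    al_a <- geom$source_standoff - t_ti
    segs <- c(segs, list(
      .seg(t_ti, nsolid(t_ti), .ZONE_TITANIUM),
      .seg(al_a, nsolid(al_a), .ZONE_ALUMINUM)))
    src_face_after_seg <- length(segs)
    if (geom$heat_guide) {
      al_rest <- geom$hc_thickness - geom$source_standoff -
        geom$guide_standoff_source - geom$guide_thickness
      segs <- c(segs, list(
        .seg(geom$guide_standoff_source, nsolid(geom$guide_standoff_source),
             .ZONE_ALUMINUM),
        .seg(geom$guide_thickness, nsolid(geom$guide_thickness),
             .ZONE_COPPER, x_range = gx, alt = .ZONE_ALUMINUM),
        .seg(al_rest, nsolid(al_rest), .ZONE_ALUMINUM)))
    } else {
      al_rest <- geom$hc_thickness - geom$source_standoff
      segs <- c(segs, list(.seg(al_rest, nsolid(al_rest), .ZONE_ALUMINUM)))
    }
  }

  # assemble transverse faces and per-row segment bookkeeping
  y_f <- 0
  seg_rows <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    sg <- segs[[s]]
    f <- if (!is.null(sg$faces)) sg$faces else
      seq(0, sg$h, length.out = sg$n + 1)
    j0 <- length(y_f)                     # row index offset
    y_f <- c(y_f, y_f[length(y_f)] + f[-1])
    seg_rows[[s]] <- j0:(j0 + length(f) - 2)
  }
  ny <- length(y_f) - 1
  y_c <- (y_f[-1] + y_f[-(ny + 1)]) / 2
  dy <- diff(y_f)

  in_window <- x_c >= geom$x_exchanger[1] - 1e-12 &
               x_c <= geom$x_exchanger[2] + 1e-12
  zone <- matrix(.ZONE_VOID, nx, ny)
  fluid_rows <- integer(0)
  for (s in seq_along(segs)) {
    sg <- segs[[s]]
    rows <- seg_rows[[s]]
    zcol <- ifelse(in_window, sg$zone_in, sg$zone_out)
    if (!is.null(sg$x_range)) {
      sub <- in_window & !(x_c >= sg$x_range[1] - 1e-12 &
                           x_c <= sg$x_range[2] + 1e-12)
      zcol[sub] <- sg$alt
    }
    zone[, rows] <- matrix(zcol, nx, length(rows))
    if (sg$fluid) fluid_rows <- c(fluid_rows, rows)
  }

  # rows usable by the 1-D parallel-flow solver: fluid at every axial station
  flow_rows <- sort(fluid_rows)
  flow_rows <- flow_rows[apply(zone[, flow_rows, drop = FALSE] == .ZONE_BLOOD,
                               2, all)]

  # geometric factors
  if (geom$mode == "axisymmetric_pipe") {
    Acs <- pi * (y_f[-1]^2 - y_f[-(ny + 1)]^2)      # axial cross-sections
    At_fac <- 2 * pi * y_f                          # transverse area per dx
  } else {
    Acs <- geom$depth * dy
    At_fac <- rep(geom$depth, ny + 1)
  }
  vol <- outer(dx, Acs)

  # internal source-plane faces: transverse face index (row boundary) above
  # segment `src_face_after_seg`, axial cells inside the source band
  jf_src <- seg_rows[[src_face_after_seg]][length(seg_rows[[src_face_after_seg]])] + 1L
  i_src <- which(x_c >= geom$source_band[1] - 1e-12 &
                 x_c <= geom$source_band[2] + 1e-12)
  source_faces <- data.frame(i = i_src, jf = jf_src,
                             area = At_fac[jf_src] * dx[i_src])

  # out-of-plane copper wrap conductances (fins+guide design only)
  wrap <- NULL
  if (isTRUE(geom$heat_guide)) {
    cu_rows <- which(apply(zone == .ZONE_COPPER, 2, any))
    y_lum <- range(y_c[sort(fluid_rows)])
    far_cu <- cu_rows[y_c[cu_rows] < y_lum[1]]
    near_cu <- cu_rows[y_c[cu_rows] > y_lum[2]]
    if (length(far_cu) && length(near_cu)) {
      ja <- near_cu[ceiling(length(near_cu) / 2)]
      jb <- far_cu[ceiling(length(far_cu) / 2)]
      ii <- which(zone[, ja] == .ZONE_COPPER & zone[, jb] == .ZONE_COPPER)
      k_cu <- get_material("copper")$k
      L_wrap <- pi * geom$lumen_diameter
      wrap <- data.frame(i = ii, ja = ja, jb = jb,
                         G = k_cu * geom$guide_thickness * dx[ii] / L_wrap)
    }
  }

  structure(list(mode = geom$mode, nx = nx, ny = ny,
                 x_f = x_f, x_c = x_c, dx = dx,
                 y_f = y_f, y_c = y_c, dy = dy,
                 zone = zone, depth = geom$depth,
                 Acs = Acs, At_fac = At_fac, vol = vol,
                 flow_rows = flow_rows, fluid_rows = sort(fluid_rows),
                 source_faces = source_faces, wrap = wrap),
            class = "hx_grid")
}

#' @export
print.hx_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("hx_model '%s' (%s)\n", g$design, g$mode))
  cat(sprintf("  domain %.3g m, exchanger [%.3g, %.3g] m, lumen %s %.3g m\n",
              g$domain_length, g$x_exchanger[1], g$x_exchanger[2],
              if (g$mode == "axisymmetric_pipe") "radius" else "height",
              g$lumen_size))
  cat(sprintf("  source %g W over band [%.3g, %.3g] m at standoff %.3g m\n",
              x$source$power, g$source_band[1], g$source_band[2],
              g$source_standoff))
  cat(sprintf("  grid %d x %d cells (%d active)\n", x$grid$nx, x$grid$ny,
              sum(x$grid$zone > 0)))
  invisible(x)
}

#' Map the source power onto the surrogate grid
#'
#' Distributes the total source power uniformly over the internal source
#' face band of the surrogate grid.  The face fluxes integrate to exactly
#' `spec$power` (the face areas already include the axisymmetric `2*pi*r`
#' factor or the effective planar depth), which preserves the global energy
#' balance of the reduction.
#'
#' @param spec A [heat_source_spec()].
#' @param model An `hx_model` from [build_design()] (or a bare `hx_grid`).
#' @return A data.frame with columns `i` (axial cell), `jf` (transverse face
#'   index), `area` (m^2) and `flux` (W/m^2), satisfying
#'   `sum(flux * area) == spec$power` to round-off.
#' @export
map_power_to_surrogate <- function(spec, model) {
  stopifnot(inherits(spec, "heat_source_spec"))
  grid <- if (inherits(model, "hx_model")) model$grid else model
  sf <- grid$source_faces
  if (is.null(sf) || nrow(sf) == 0)
    stop("configuration error: surrogate grid has an empty source band")
  sf$flux <- spec$power / sum(sf$area)
  sf
}

# ---- duct models for validation -----------------------------------------

#' Fluid-only duct surrogate with wall heating (validation geometry)
#'
#' Builds a pipe or channel grid with no solid layers and a constant heat
#' flux applied directly on the lumen wall over an axial band.  Used by the
#' Graetz/Nusselt validation suite; in the planar mode only the near-side
#' (`y = H`) wall is heated, the other wall is adiabatic.
#'
#' @param mode `"axisymmetric_pipe"` or `"planar_channel"`.
#' @param lumen_size Pipe radius or channel height (m).
#' @param length Duct length (m).
#' @param power Total power applied on the heated band (W).
#' @param band Axial interval of the heated band (m); default whole duct.
#' @param resolution Axial cells per cm.
#' @param n_fluid Transverse fluid cells.
#' @param depth Effective depth for the planar mode (m).
#' @param stretch_ratio Transverse wall-clustering ratio.
#' @return An `hx_model` (with `geometry` reduced to the duct description).
#' @export
build_duct_model <- function(mode = c("axisymmetric_pipe", "planar_channel"),
                             lumen_size = 0.011, length = 0.23, power = 1,
                             band = NULL, resolution = 4, n_fluid = 32,
                             depth = 0.0346, stretch_ratio = 1.25) {
  mode <- match.arg(mode)
  if (is.null(band)) band <- c(0, length)
  res_m <- resolution * 100
  nx <- max(4, ceiling(length * res_m))
  x_f <- seq(0, length, length.out = nx + 1)
  x_c <- (x_f[-1] + x_f[-(nx + 1)]) / 2
  dx <- diff(x_f)
  y_f <- if (mode == "axisymmetric_pipe")
    .stretch_faces(0, lumen_size, n_fluid, stretch_ratio, fine = "hi")
  else
    .stretch_faces2(0, lumen_size, n_fluid, stretch_ratio)
  ny <- length(y_f) - 1
  y_c <- (y_f[-1] + y_f[-(ny + 1)]) / 2
  dy <- diff(y_f)
  zone <- matrix(.ZONE_BLOOD, nx, ny)
  if (mode == "axisymmetric_pipe") {
    Acs <- pi * (y_f[-1]^2 - y_f[-(ny + 1)]^2)
    At_fac <- 2 * pi * y_f
  } else {
    Acs <- depth * dy
    At_fac <- rep(depth, ny + 1)
  }
  i_src <- which(x_c >= band[1] - 1e-12 & x_c <= band[2] + 1e-12)
  source_faces <- data.frame(i = i_src, jf = ny + 1L,
                             area = At_fac[ny + 1L] * dx[i_src])
  grid <- structure(list(mode = mode, nx = nx, ny = ny,
                         x_f = x_f, x_c = x_c, dx = dx,
                         y_f = y_f, y_c = y_c, dy = dy,
                         zone = zone,
                         depth = if (mode == "planar_channel") depth else NA,
                         Acs = Acs, At_fac = At_fac, vol = outer(dx, Acs),
                         flow_rows = seq_len(ny), fluid_rows = seq_len(ny),
                         source_faces = source_faces, wrap = NULL),
                    class = "hx_grid")
  geometry <- structure(list(design = "duct", mode = mode,
                             lumen_size = lumen_size,
                             lumen_diameter = if (mode == "axisymmetric_pipe")
                               2 * lumen_size else lumen_size,
                             exchanger_length = band[2] - band[1],
                             inlet_run = band[1],
                             outlet_run = length - band[2],
                             domain_length = length,
                             x_exchanger = band, source_band = band,
                             source_standoff = 0, ti_wall = 0,
                             fins = FALSE, heat_guide = FALSE,
                             depth = if (mode == "planar_channel") depth else NA),
                        class = "hx_geometry")
  spec <- structure(list(power = power, diameter = NA, height = NA,
                         area = sum(source_faces$area),
                         flux = power / sum(source_faces$area)),
                    class = "heat_source_spec")
  model <- structure(list(geometry = geometry, grid = grid, source = spec,
                          materials = NULL),
                     class = "hx_model")
  model$source_table <- map_power_to_surrogate(spec, model)
  model
}
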