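# Shared fixtures.  Heavy periodic conjugate runs are cached per session so
# several test files (and the acceptance blocks) can share one solve.

.hx_cache <- new.env(parent = emptyenv())

hx_newtonian <- function(mu = 0.0035) cy_params(mu0 = mu, mu_inf = mu)

# the stated-world descending-aorta waveform (5 L/min inlet, fraction 0.7)
hx_waveform <- function(seed = 102) {
  descending_fraction(make_inlet_waveform(seed = seed), 0.7)
}

# full two-step periodic run for one design; cached
hx_run <- function(design, mode = NULL, resolution = 4, seed = 102) {
  key <- paste(design, mode %||% "default", resolution, seed, sep = "_")
  if (!is.null(.hx_cache[[key]])) return(.hx_cache[[key]])
  params <- cy_params()
  wf <- hx_waveform(seed)
  m <- build_design(design, resolution = resolution, mode = mode)
  vs <- solve_steady_profile(wf$mean_q, m, params)
  vu <- solve_unsteady_profile(wf, m, params, n_cycles = 30)
  ts <- solve_steady_temp(m, vs)
  tr <- solve_transient_temp(m, vu, ts)
  res <- list(model = m, waveform = wf, params = params,
              flow_steady = vs, flow = vu, steady = ts,
              temperature = tr$temperature, report = tr$report)
  .hx_cache[[key]] <- res
  res
}

# tracked 500 + 500 population on a cached run
hx_tracked <- function(run, seed = 203) {
  key <- paste0("trk_", run$model$geometry$design, "_",
                run$model$geometry$mode, "_", seed)
  if (!is.null(.hx_cache[[key]])) return(.hx_cache[[key]])
  plt <- seed_cells("platelet", 500, run$model, seed = seed)
  rbc <- seed_cells("rbc", 500, run$model, seed = seed + 1)
  rbc$id <- rbc$id + nrow(plt)
  tj <- track_cells(rbind(plt, rbc), run$flow, run$temperature, run$model,
                    run$params)
  .hx_cache[[key]] <- tj
  tj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# solid-only slab model (titanium), flux on the y = L face; used by the
# transient-conduction oracle test
hx_slab_model <- function(L = 0.02, ny = 60, q = 1000) {
  nx <- 3L
  x_f <- seq(0, 0.03, length.out = nx + 1)
  y_f <- seq(0, L, length.out = ny + 1)
  grid <- structure(list(
    mode = "planar_channel", nx = nx, ny = ny,
    x_f = x_f, x_c = (x_f[-1] + x_f[-(nx + 1)]) / 2, dx = diff(x_f),
    y_f = y_f, y_c = (y_f[-1] + y_f[-(ny + 1)]) / 2, dy = diff(y_f),
    zone = matrix(2L, nx, ny), depth = 1,
    Acs = diff(y_f), At_fac = rep(1, ny + 1),
    vol = outer(diff(x_f), diff(y_f)),
    flow_rows = integer(0), fluid_rows = integer(0),
    source_faces = data.frame(i = seq_len(nx), jf = ny + 1L,
                              area = diff(x_f)),
    wrap = NULL), class = "hx_grid")
  list(grid = grid,
       source_table = data.frame(i = seq_len(nx), jf = ny + 1L,
                                 area = diff(x_f), flux = q),
       materials = NULL, geometry = list(), q = q, L = L)
}
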