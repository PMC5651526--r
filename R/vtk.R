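# Minimal legacy-ASCII VTK writer for the structured surrogate grids.
# (No pre-installed R package writes VTK; the legacy rectilinear format is
# a few lines of plain text.)

#' Write a surrogate grid (with cell data) as a legacy VTK file
#'
#' Emits an ASCII `RECTILINEAR_GRID` dataset with the grid faces as
#' coordinates and any number of per-cell scalar fields (zone id is always
#' included).  Fields may be given as `nx x ny` matrices or as vectors over
#' the active cells (void cells are written as `NaN`).
#'
#' @param model An `hx_model` (or bare `hx_grid`).
#' @param path Output file path.
#' @param celldata Named list of fields.
#' @param sys Optional thermal system (from a solved field) used to expand
#'   active-cell vectors onto the full grid.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(model, path, celldata = list(), sys = NULL) {
  grid <- if (inherits(model, "hx_model")) model$grid else model
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hemotherm surrogate grid", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", grid$nx + 1, grid$ny + 1)), con)
  writeLines(sprintf("X_COORDINATES %d double", grid$nx + 1), con)
  writeLines(paste(format(grid$x_f, digits = 9), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", grid$ny + 1), con)
  writeLines(paste(format(grid$y_f, digits = 9), collapse = " "), con)
  writeLines(c("Z_COORDINATES 1 double", "0"), con)
  ncell <- grid$nx * grid$ny
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  fields <- c(list(zone = grid$zone), celldata)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!is.matrix(f)) {
      if (is.null(sys)) stop("need `sys` to expand a cell vector field")
      M <- matrix(NaN, grid$nx, grid$ny)
      M[sys$idx > 0] <- f[sys$idx[sys$idx > 0]]
      f <- M
    }
    writeLines(sprintf("SCALARS %s double 1", nm), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(format(as.vector(f), digits = 9), collapse = " "), con)
  }
  invisible(path)
}

#' Write a temperature time series as numbered VTK files
#'
#' @param temp An `hx_temperature`.
#' @param model The `hx_model`.
#' @param dir Output directory.
#' @param stride Write every `stride`-th saved time.
#' @return Character vector of written paths, invisibly.
#' @export
write_vtk_series <- function(temp, model, dir, stride = 10) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- if (temp$steady) 1L else seq(1, ncol(temp$T), by = stride)
  paths <- character(0)
  for (k in cols) {
    p <- file.path(dir, sprintf("temperature_%04d.vtk", k))
    write_vtk_grid(model, p, celldata = list(temperature_C = temp$T[, k]),
                   sys = temp$sys)
    paths <- c(paths, p)
  }
  invisible(paths)
}
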