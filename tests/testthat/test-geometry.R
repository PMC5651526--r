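test_that("design defaults match the device dimensions", {
  m <- build_design("base64", resolution = 3)
  expect_equal(m$geometry$exchanger_length, 0.10)
  expect_equal(m$source$height, 0.01)
  expect_equal(m$source$power, 64)
  expect_equal(m$geometry$lumen_diameter, 0.022)
  expect_equal(m$geometry$domain_length, 0.23)
  m24 <- build_design("base24", resolution = 3)
  expect_equal(m24$source$power, 24)
  expect_equal(m24$source$diameter, 0.028)
  g <- build_design("finsguide64", resolution = 3)$geometry
  expect_equal(g$hc_thickness, 0.043)
  expect_equal(g$guide_thickness, 0.0025)
  expect_equal(g$guide_standoff_lumen, 0.0015)
  expect_equal(g$guide_standoff_source, 0.0025)
})

test_that("fluid cell volumes integrate to the cylinder volume", {
  m <- build_design("base64", resolution = 4)
  vol <- sum(m$grid$vol[m$grid$zone == 1])
  expect_equal(vol, pi * 0.011^2 * 0.23, tolerance = 5e-3)
})

test_that("doubling the resolution quadruples the cell count (2-D grid)", {
  n1 <- sum(build_design("base64", resolution = 4)$grid$zone > 0)
  n2 <- sum(build_design("base64", resolution = 8)$grid$zone > 0)
  expect_gt(n2 / n1, 3.0)
  expect_lt(n2 / n1, 5.0)
})

test_that("source flux is power over lateral cylinder area", {
  s64 <- heat_source_spec(64, 0.046, 0.01)
  expect_equal(s64$area, pi * 0.046 * 0.01, tolerance = 1e-12)
  expect_equal(source_flux(s64), 64 / (pi * 0.046 * 0.01), tolerance = 1e-12)
  expect_equal(source_flux(s64), 4.429e4, tolerance = 1e-3)
  expect_equal(source_flux(heat_source_spec(24, 0.028, 0.01)), 2.728e4,
               tolerance = 1e-3)
  expect_equal(source_flux(heat_source_spec(0, 0.046, 0.01)), 0)
})

test_that("surrogate source mapping conserves power exactly and is linear", {
  m <- build_design("base64", resolution = 4)
  st <- m$source_table
  expect_lt(abs(sum(st$flux * st$area) - 64) / 64, 1e-10)
  st24 <- map_power_to_surrogate(heat_source_spec(24, 0.046, 0.01), m)
  expect_equal(st$flux / st24$flux, rep(64 / 24, nrow(st)), tolerance = 1e-12)
  # halving the band doubles the local flux density
  m_half <- build_design("base64", resolution = 4,
                         overrides = list(source_diameter = 0.023))
  f_ratio <- m_half$source_table$flux[1] / st$flux[1]
  expect_equal(f_ratio, 2, tolerance = 0.1)   # band snaps to cell faces
  expect_lt(abs(sum(m_half$source_table$flux * m_half$source_table$area) - 64),
            1e-10 * 64)
})

test_that("zone topology: connected blood, copper never touches blood", {
  for (design in c("base64", "fins64", "finsguide64")) {
    m <- build_design(design, resolution = 4)
    z <- m$grid$zone
    # copper standoff: no copper cell is adjacent to a blood cell
    cu <- which(z == 4L, arr.ind = TRUE)
    if (nrow(cu)) {
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb <- cbind(pmin(pmax(cu[, 1] + d[1], 1), nrow(z)),
                    pmin(pmax(cu[, 2] + d[2], 1), ncol(z)))
        expect_false(any(z[nb] == 1L))
      }
    }
    # blood zone is one connected component (flood fill)
    blood <- z == 1L
    lab <- matrix(FALSE, nrow(z), ncol(z))
    start <- which(blood, arr.ind = TRUE)[1, ]
    stack <- list(start)
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (lab[p[1], p[2]]) next
      lab[p[1], p[2]] <- TRUE
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(z) && q[2] >= 1 && q[2] <= ncol(z) &&
            blood[q[1], q[2]] && !lab[q[1], q[2]])
          stack[[length(stack) + 1]] <- q
      }
    }
    expect_equal(sum(lab), sum(blood))
  }
})

test_that("configuration errors are raised", {
  expect_error(build_design("warp9"), "arg")
  expect_error(build_design("fins64", mode = "axisymmetric_pipe"),
               "planar_channel")
  expect_error(build_design("base64", resolution = 1), "resolution")
})
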