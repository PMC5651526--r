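test_that("Poiseuille oracle: ratios and exact flow integral", {
  R <- 0.011; q <- 8.333e-5
  r <- seq(0, R, length.out = 2001)
  u <- poiseuille_profile(q, r, R)
  expect_equal(max(u) / (q / (pi * R^2)), 2, tolerance = 1e-12)
  # integral of u over the cross-section returns q (fine trapezoid)
  integrand <- u * 2 * pi * r
  Q <- sum((integrand[-1] + integrand[-2001]) / 2) * diff(r[1:2])
  expect_equal(Q, q, tolerance = 1e-6)
  H <- 0.022
  y <- seq(0, H, length.out = 1001)
  uc <- poiseuille_profile(q, y, H, "planar_channel", depth = 0.0346)
  expect_equal(max(uc) / (q / (0.0346 * H)), 1.5, tolerance = 1e-9)
})

test_that("Womersley oracle degenerates to Poiseuille at zero frequency", {
  R <- 0.011; q <- 8.333e-5
  r <- seq(0, R, length.out = 21)
  u <- womersley_profile(q, complex(0), R, 0.0035, 1050, 1, r, 0.3)
  expect_equal(u, poiseuille_profile(q, r, R), tolerance = 1e-12)
})

test_that("Womersley oracle integrates to the prescribed harmonic flow", {
  R <- 0.011; q0 <- 8.333e-5; q1 <- 0.4 * q0
  r <- seq(0, R, length.out = 4001)
  for (t in c(0.1, 0.37, 0.8)) {
    u <- womersley_profile(q0, complex(real = q1), R, 0.0035, 1050, 1, r, t)
    integrand <- u * 2 * pi * r
    Q <- sum((integrand[-1] + integrand[-4001]) / 2) * diff(r[1:2])
    expect_lt(abs(Q - (q0 + q1 * cos(2 * pi * t))), 1e-5 * q0)
  }
  # alpha ~ 15 regime: flattened core (centreline below Poiseuille peak of
  # the oscillatory part) and finite wall gradient
  uo <- womersley_profile(0, complex(real = q1), R, 0.0035, 1050, 1,
                          seq(0, R, length.out = 101), 0)
  expect_lt(max(abs(uo)), 2 * q1 / (pi * R^2))
})

test_that("Graetz constants are flow-independent classical values", {
  expect_equal(graetz_nusselt("axisymmetric_pipe"), 48 / 11)
  expect_equal(graetz_nusselt("planar_channel"), 5.385)
})

test_that("slab conduction series satisfies its limits", {
  L <- 0.02; k <- 7.5; rcp <- 4506 * 710; q <- 1000
  x <- seq(0, L, length.out = 41)
  # t -> 0 recovers the initial condition
  expect_equal(slab_conduction(x, 1e-9, L, k, rcp, q, 37), rep(37, 41),
               tolerance = 1e-6)
  # t -> infinity approaches linear-in-time mean rise plus the steady
  # quadratic shape: gradient at the heated face equals -q/k
  t_big <- 5000
  Tb <- slab_conduction(x, t_big, L, k, rcp, q, 37)
  g0 <- (Tb[2] - Tb[1]) / diff(x[1:2])
  expect_equal(g0, -q / k, tolerance = 0.02)
  # mean temperature rises at exactly q/(rcp L)
  expect_equal(mean(Tb) - 37, q * t_big / (rcp * L), tolerance = 1e-3)
})
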