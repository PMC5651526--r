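test_that("response time follows rho d^2 / (18 mu)", {
  plt <- blood_cell("platelet")
  rbc <- blood_cell("rbc")
  expect_equal(response_time(plt, 0.0035), 1050 * 9e-12 / (18 * 0.0035),
               tolerance = 1e-12)
  expect_equal(response_time(plt, 0.0035), 1.5e-7, tolerance = 1e-3)
  expect_equal(response_time(rbc, 0.0035), 8.167e-7, tolerance = 1e-3)
  big <- blood_cell("platelet", d_p = 6e-6)
  expect_equal(response_time(big, 0.0035) / response_time(plt, 0.0035), 4,
               tolerance = 1e-12)
  expect_equal(plt$m_p, 1050 * pi * 27e-18 / 6, tolerance = 1e-12)
  expect_error(response_time(plt, 0), "positive")
})

test_that("specular reflection: worked cases and conservation properties", {
  expect_equal(reflect(c(0, -1), c(0, 1)), c(0, 1))
  expect_equal(reflect(c(1, -1), c(0, 1)), c(1, 1))
  rng <- hemotherm:::.hx_rng(17)
  for (i in 1:1000) {
    v <- c(rng() - 0.5, rng() - 0.5)
    n <- c(rng() - 0.5, rng() - 0.5)
    n <- n / sqrt(sum(n^2))
    r <- reflect(v, n)
    expect_lt(abs(sqrt(sum(r^2)) - sqrt(sum(v^2))), 1e-12)
    tang <- c(-n[2], n[1])
    expect_lt(abs(sum(r * tang) - sum(v * tang)), 1e-12)
  }
  expect_error(reflect(c(1, 0), c(0, 2)), "unit")
})

test_that("seeding laws: r^3 platelet margination and uniform rbc", {
  m <- build_design("base64", resolution = 2)
  expect_equal(nrow(seed_cells("platelet", 0, m)), 0)
  plt <- seed_cells("platelet", 50000, m, seed = 7)
  R <- m$geometry$lumen_size
  # P(r <= R/2) under CDF (r/R)^5 is 1/32
  expect_equal(mean(plt$y <= R / 2), 2^-5, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test((plt$y / R)^5, "punif"))
  expect_gt(ks$p.value, 0.01)
  # rbc uniform over the cross-section: chi-square over equal-area annuli
  rbc <- seed_cells("rbc", 50000, m, seed = 8)
  edges <- R * sqrt(seq(0, 1, length.out = 11))
  counts <- table(cut(rbc$y, edges))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(counts)))
  expect_gt(chi$p.value, 0.01)
  # determinism
  expect_identical(seed_cells("platelet", 100, m, seed = 3),
                   seed_cells("platelet", 100, m, seed = 3))
  expect_error(seed_cells("platelet", -1, m), "non-negative")
})

test_that("planar seeding uses the |d|^4 CDF analog and avoids the splitter", {
  m <- build_design("fins64", resolution = 2)
  plt <- seed_cells("platelet", 20000, m, seed = 9)
  runs <- hemotherm:::.flow_runs(m$grid)
  lo <- m$grid$y_f[runs[[1]][1]]
  hi <- m$grid$y_f[runs[[2]][length(runs[[2]])] + 1]
  ctr <- (lo + hi) / 2
  d <- abs(plt$y - ctr) / ((hi - lo) / 2)
  ks <- suppressWarnings(stats::ks.test(d^4, "punif"))
  expect_gt(ks$p.value, 0.005)
  # none inside the fin splitter
  g_lo <- m$grid$y_f[runs[[1]][length(runs[[1]])] + 1]
  g_hi <- m$grid$y_f[runs[[2]][1]]
  expect_false(any(plt$y > g_lo & plt$y < g_hi))
})

test_that("drag update reproduces the exponential relaxation closed form", {
  tau <- 2e-3; u0 <- 0.3; dt <- 1e-4
  x <- 0; v <- 0
  for (s in 1:300) {
    st <- hemotherm:::.drag_update(x, v, u0, tau, dt)
    x <- st$x; v <- st$v
    va <- u0 * (1 - exp(-s * dt / tau))
    expect_lt(abs(v - va) / u0, 1e-3)
  }
  xa <- u0 * 300 * dt - u0 * tau * (1 - exp(-300 * dt / tau))
  expect_lt(abs(x - xa) / xa, 1e-3)
  # tau -> 0 limit: passive tracer within 10 tau |u|
  st <- hemotherm:::.drag_update(0, 0.5, 0.3, 1e-7, 0.01)
  expect_lt(abs(st$x - 0.3 * 0.01), 10 * 1e-7 * 0.5)
  expect_equal(st$v, 0.3, tolerance = 1e-12)
})

test_that("tracked populations stay in the fluid and terminate cleanly", {
  run <- hx_run("base64")
  plt <- seed_cells("platelet", 60, run$model, seed = 21)
  rbc <- seed_cells("rbc", 60, run$model, seed = 22)
  rbc$id <- rbc$id + 60
  tj <- track_cells(rbind(plt, rbc), run$flow, run$temperature, run$model,
                    run$params, n_cycles = 4)
  expect_true(all(tj$exit_status %in% c("outlet", "max_time")))
  R <- run$model$geometry$lumen_size
  ok <- !is.na(tj$y)
  expect_true(all(tj$y[ok] >= -1e-12 & tj$y[ok] <= R + 1e-12))
  expect_true(all(tj$x[ok] >= 0 & tj$x[ok] <= 0.23 + 1e-12))
  expect_true(all(diff(tj$times) > 0))
  # release starts at the beginning of cycle 2 when discarding the first
  expect_equal(tj$times[1], run$flow$period)
  # sampled temperatures are physical
  expect_true(all(tj$T[!is.na(tj$T)] >= 37 - 1e-6))
})

test_that("platelets sample hotter near-wall temperatures than rbc", {
  run <- hx_run("base64", mode = "planar_channel")
  tj <- hx_tracked(run)
  rec <- tei_records(tj)
  q_plt <- stats::quantile(rec$max_T[rec$kind == "platelet"], 0.9)
  q_rbc <- stats::quantile(rec$max_T[rec$kind == "rbc"], 0.9)
  expect_gt(q_plt, q_rbc)
})
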