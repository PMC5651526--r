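test_that("TEI worked examples", {
  tt <- seq(0, 1, by = 0.01)
  expect_equal(tei(tt, rep(37, length(tt))), 37, tolerance = 1e-12)
  expect_equal(tei(c(0, 1), c(40, 50)), 45)
  expect_error(tei(1, 40), "2 samples")
  expect_error(tei(c(0, 0), c(1, 2)), "increasing")
})

test_that("trapezoidal TEI matches a brute-force fine quadrature", {
  rng <- hemotherm:::.hx_rng(11)
  tt <- cumsum(0.005 + vapply(1:60, function(i) rng() * 0.02, 0))
  Tv <- 37 + vapply(1:60, function(i) rng() * 15, 0)
  fine <- seq(tt[1], tt[length(tt)], length.out = 2000001)
  Ti <- stats::approx(tt, Tv, xout = fine)$y
  riemann <- sum((Ti[-1] + Ti[-length(Ti)]) / 2) * diff(fine[1:2])
  expect_lt(abs(tei(tt, Tv) - riemann) / riemann, 1e-9)
})

test_that("TEI is additive over concatenation and monotone in temperature", {
  rng <- hemotherm:::.hx_rng(5)
  tt <- cumsum(0.01 + vapply(1:40, function(i) rng() * 0.01, 0))
  Tv <- 37 + vapply(1:40, function(i) rng() * 10, 0)
  for (split in c(2, 17, 39)) {
    expect_equal(tei(tt, Tv),
                 tei(tt[1:split], Tv[1:split]) +
                   tei(tt[split:40], Tv[split:40]),
                 tolerance = 1e-12)
  }
  bump <- Tv; bump[23] <- bump[23] + 3
  expect_gt(tei(tt, bump), tei(tt, Tv))
  # a weighting function reweights the integrand
  expect_equal(tei(tt, Tv, w = function(x) 2 * x), 2 * tei(tt, Tv),
               tolerance = 1e-12)
})

test_that("TEI summary table computes the four statistics per kind", {
  rec <- data.frame(kind = rep("platelet", 4), tei = c(10, 20, 30, 40))
  s <- tei_summary(rec)
  expect_equal(s$max, 40)
  expect_equal(s$mean, 25)
  expect_equal(s$median, 25)
  expect_equal(s$min, 10)
  one <- tei_summary(data.frame(kind = "rbc", tei = 45))
  expect_true(all(unlist(one[, c("max", "mean", "median", "min")]) == 45))
  expect_error(tei_summary(data.frame(kind = character(0),
                                      tei = numeric(0))), "empty")
})

test_that("TEI >= 37 x residence time when all samples are >= 37", {
  run <- hx_run("base64")
  tj <- hx_tracked(run)
  rec <- tei_records(tj)
  expect_true(all(rec$tei >= 37 * rec$residence_time - 1e-6))
  expect_true(all(rec$tei > 0))
})

test_that("exposure report accumulates time above each threshold", {
  rules <- hyperthermia_rules()
  expect_true(any(rules$temperature_C == 50 &
                    rules$reference_exposure_s == 3600))
  expect_true(any(rules$temperature_C == 45))
  cool <- list(times = seq(0, 5, by = 0.01),
               T = rep(37.2, 501))
  rep_cool <- exposure_report(cool, rules)
  expect_true(all(rep_cool$exposure_s == 0))
  expect_false(any(rep_cool$flag))
  hot <- list(times = seq(0, 4, by = 0.01),
              T = c(rep(37, 100), rep(46, 201), rep(37, 100)))
  rep_hot <- exposure_report(hot, rules)
  expect_equal(rep_hot$exposure_s[rep_hot$label == "protein_denaturation"],
               2, tolerance = 0.01)
  expect_equal(rep_hot$exposure_s[rep_hot$label == "rbc_hemolysis_6pct"], 0)
})
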