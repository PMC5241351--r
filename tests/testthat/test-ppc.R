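test_that("a flat-baseline rectangular spike integrates to height x duration", {
  spec <- thermogram_spec(c(`7` = 300, `8` = 300), t_start_C = 7,
                          t_end_C = 8.5, spike_model = "rect",
                          rect_height_uW = 10)
  tg <- gen_thermogram(spec)
  r <- integrate_pulse(tg, 1)
  expect_equal(r$dq_uJ, 300, tolerance = 1e-6)
  expect_identical(r$direction, "up")
  expect_true(r$reliable)
  # the paired depressurization mirrors the sign
  r2 <- integrate_pulse(tg, 2)
  expect_equal(r2$dq_uJ, -300, tolerance = 1e-6)
})

test_that("planted areas on a drifting baseline are recovered within 0.5%", {
  areas <- function(T) 500
  for (model in c("gauss", "expdecay")) {
    spec <- thermogram_spec(areas, t_start_C = 7, t_end_C = 9,
                            spike_model = model,
                            baseline_drift_uW_per_C = 0.2,
                            baseline_offset_uW = 3)
    tg <- gen_thermogram(spec)
    dq <- reduce_thermogram(tg, trim = FALSE)
    up <- dq[dq$direction == "up", ]
    expect_equal(up$dq_uJ, rep(500, nrow(up)), tolerance = 5e-3,
                 label = model)
  }
})

test_that("planted areas under noise are recovered within 2%", {
  spec <- thermogram_spec(function(T) -2000 - 100 * T, t_start_C = 7,
                          t_end_C = 12, spike_model = "gauss",
                          baseline_drift_uW_per_C = 0.1, noise_sd_uW = 0.5,
                          seed = 31)
  tg <- gen_thermogram(spec)
  dq <- reduce_thermogram(tg, trim = FALSE)
  up <- dq[dq$direction == "up", ]
  planted <- -2000 - 100 * round(up$temp_C)
  expect_equal(up$dq_uJ, planted, tolerance = 0.02)
})

test_that("reduction trims to the usable temperature range", {
  spec <- thermogram_spec(function(T) 100, t_start_C = 7, t_end_C = 62)
  tg <- gen_thermogram(spec)
  expect_equal(nrow(tg$events), 2L * 56L)  # 7..62 C up/down pairs
  dq_all <- reduce_thermogram(tg, trim = FALSE)
  expect_equal(nrow(dq_all), nrow(tg$events))
  dq <- reduce_thermogram(tg)
  expect_gte(min(dq$temp_C), 9)
  expect_lte(max(dq$temp_C), 61)
  up <- dq[dq$direction == "up", ]
  expect_equal(nrow(up), 53L)  # 9, 10, ..., 61 C
  expect_error(reduce_thermogram(
    thermogram(tg$samples, tg$events[0, ])), "no annotated")
})

test_that("spikes that never settle are flagged unreliable", {
  spec <- thermogram_spec(c(`7` = 1e5, `8` = 1e5), t_start_C = 7,
                          t_end_C = 8.5, spike_model = "expdecay",
                          expdecay_tau_s = 2000)
  tg <- gen_thermogram(spec)
  expect_warning(r <- integrate_pulse(tg, 1), "capped")
  expect_false(r$reliable)
})

test_that("window gradient recovers an exact line and flags poor fits", {
  # dq = -1000 + 20 T at dp = 4 bar: slope of dq/dp vs T is 5 uJ/(bar K)
  d <- data.frame(temp_C = 9:35, dq_uJ = -1000 + 20 * (9:35),
                  direction = "up", dp_bar = 4)
  g <- window_gradient(d, window = c(9, 35))
  expect_equal(g$slope_uJ_bar_K, 5, tolerance = 1e-12)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
  expect_equal(g$n_points, 27L)
  expect_false(g$low_confidence)
  # constant series: zero slope
  d2 <- data.frame(temp_C = 9:35, dq_uJ = 70, direction = "up", dp_bar = 4)
  expect_equal(window_gradient(d2)$slope_uJ_bar_K, 0, tolerance = 1e-12)
  # pure noise: low confidence flag
  withr::local_seed(3)
  d3 <- data.frame(temp_C = 9:35, dq_uJ = rnorm(27), direction = "up",
                   dp_bar = 4)
  expect_true(window_gradient(d3)$low_confidence)
  expect_error(window_gradient(d[1:2, ]), "fewer than 3")
})

test_that("planted slope survives the full schedule at 1% noise", {
  # line through the 9-35 C window; noise sd = 1% of the dq range
  slope_uJ_K <- 80
  areas <- function(T) -5000 + slope_uJ_K * T
  rng <- diff(range(areas(9:35)))
  spec <- thermogram_spec(areas, t_start_C = 7, t_end_C = 37,
                          spike_model = "gauss",
                          noise_sd_uW = 0.01 * rng / 100, seed = 8)
  tg <- gen_thermogram(spec)
  g <- window_gradient(reduce_thermogram(tg), window = c(9, 35))
  expect_equal(g$n_points, 27L)
  expect_equal(g$slope_uJ_bar_K, slope_uJ_K / 4, tolerance = 0.02)
})

test_that("linear-mixing deviation is zero on affine series and on endpoints", {
  d <- data.frame(mole_percent = c(0, 10, 25, 50, 100),
                  dq_uJ = 70 - 300 * c(0, 10, 25, 50, 100))
  out <- delta_delta_q(d)
  expect_equal(out$ddq_uJ, rep(0, 5), tolerance = 1e-9)
  t1 <- load_fixture("table1")
  out2 <- delta_delta_q(t1[, c("mole_percent", "dq_uJ")])
  expect_equal(out2$ddq_uJ[out2$mole_percent == 0], 0)
  expect_equal(out2$ddq_uJ[out2$mole_percent == 100], 0)
  expect_equal(out2$ddq_uJ[out2$mole_percent == 20], -15924.4)
  expect_error(delta_delta_q(d[d$mole_percent < 100, ]), "endpoint")
})
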