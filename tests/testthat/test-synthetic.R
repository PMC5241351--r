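test_that("mixture composition follows round-half-up of the mole percentage", {
  expect_equal(alcohol_count(mixture_spec(100, 10)), 10L)
  expect_equal(alcohol_count(mixture_spec(3000, 2.5)), 75L)
  expect_equal(alcohol_count(mixture_spec(3000, 1)), 30L)
  cfg <- gen_random_mixture(mixture_spec(100, 10, seed = 1))
  expect_equal(sum(cfg$species == "alcohol"), 10L)
  expect_equal(sum(cfg$species == "water"), 90L)
})

test_that("generators are pure functions of (spec, seed)", {
  sp <- mixture_spec(60, 20, seed = 42)
  expect_identical(gen_random_mixture(sp, atomistic = TRUE),
                   gen_random_mixture(sp, atomistic = TRUE))
  cl <- cluster_spec(2, 3, 0.5)
  expect_identical(gen_clustered_mixture(sp, cl),
                   gen_clustered_mixture(sp, cl))
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(gen_random_mixture(sp), gen_random_mixture(sp2)))
})

test_that("zero clustered fraction reduces to the random mixture draw for draw", {
  sp <- mixture_spec(80, 25, seed = 7)
  expect_identical(gen_clustered_mixture(sp, cluster_spec(3, 2, 0)),
                   gen_random_mixture(sp))
})

test_that("fully clustered alcohols concentrate around the single center", {
  sp <- mixture_spec(200, 50, box = simulation_box(40), seed = 11)
  cfg <- gen_clustered_mixture(sp, cluster_spec(1, 2, 1))
  alc <- cfg$points[cfg$species == "alcohol", ]
  # recover the center as the wrapped circular mean of each coordinate
  center <- apply(alc, 2, function(v) {
    th <- v / 40 * 2 * pi
    (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) / (2 * pi) * 40
  })
  d <- row_norms(minimum_image(matrix(center, nrow = 1), alc, cfg$box))
  # p(|N(0, 2^2 I_3)| > 10) is ~1e-6 per molecule
  expect_lt(max(d), 10)
})

test_that("atomistic molecules respect the rigid template geometry", {
  cfg <- gen_random_mixture(mixture_spec(40, 50, seed = 3), atomistic = TRUE)
  at <- cfg$atoms
  for (m in which(cfg$species == "alcohol")[1:3]) {
    rows <- at[at$mol == m, ]
    o <- as.numeric(rows[rows$element == "O", c("x", "y", "z")])
    h <- as.numeric(rows[rows$element == "H", c("x", "y", "z")])
    d_oh <- row_norms(minimum_image(matrix(o, 1), matrix(h, 1), cfg$box))
    expect_equal(unname(d_oh), 0.96, tolerance = 1e-9)
    expect_equal(sum(rows$element == "C"), 3L)
  }
  for (m in which(cfg$species == "water")[1:3]) {
    rows <- at[at$mol == m, ]
    o <- matrix(as.numeric(rows[rows$element == "O", c("x", "y", "z")]), 1)
    hs <- as.matrix(rows[rows$element == "H", c("x", "y", "z")])
    d <- minimum_image(o, hs, cfg$box)
    expect_equal(unname(row_norms(d)), c(0.96, 0.96), tolerance = 1e-9)
    cosang <- sum(d[1, ] * d[2, ]) / prod(row_norms(d))
    expect_equal(acos(cosang) * 180 / pi, 104.5, tolerance = 1e-6)
  }
})

test_that("point-mode occupancy matches the binomial expectation", {
  # scaled-down: 300 molecules at 10 mol%, 100 cells, 400 draws;
  # closed form: N(0) = (1 - 1/100)^30, mean alcohols per cell = 0.30
  n_draws <- 400
  part <- partition_spec(100, c(5, 5, 4))
  sp <- mixture_spec(300, 10, seed = 21)
  null <- sample_null_ensemble(sp, part, n_configs = n_draws)
  n0_expect <- (1 - 1 / 100)^30
  se <- sqrt(n0_expect * (1 - n0_expect) / (100 * n_draws))
  expect_lt(abs(null$fractions[["0"]] - n0_expect), 3 * se)
  expect_equal(occupancy_mean(null), 0.30, tolerance = 0.02)
  expect_equal(sum(null$fractions), 1, tolerance = 1e-12)
})

test_that("planted rectangular spike has the stated height-duration product", {
  spec <- thermogram_spec(c(`7` = 300), t_start_C = 7, t_end_C = 7.5,
                          spike_model = "rect", rect_height_uW = 10)
  tg <- gen_thermogram(spec)
  up_t <- tg$events$time_s[tg$events$direction == "up"][1]
  in_spike <- tg$samples$time_s > up_t & tg$samples$time_s <= up_t + 30
  expect_true(all(tg$samples$power_uW[in_spike] == 10))
  expect_true(all(tg$samples$power_uW[tg$samples$time_s <= up_t] == 0))
  # duration = area / height = 30 s
  expect_equal(sum(in_spike), 30)
})

test_that("thermogram generation is deterministic under a fixed seed", {
  spec <- thermogram_spec(function(T) -100 * T, t_start_C = 7, t_end_C = 9,
                          noise_sd_uW = 0.5, seed = 77)
  expect_identical(gen_thermogram(spec)$samples$power_uW,
                   gen_thermogram(spec)$samples$power_uW)
})

test_that("scheduled pulses alternate up/down starting up at 1 C intervals", {
  spec <- thermogram_spec(function(T) T, t_start_C = 7, t_end_C = 12)
  tg <- gen_thermogram(spec)
  expect_identical(unique(tg$events$direction[c(TRUE, FALSE)]), "up")
  expect_identical(unique(tg$events$direction[c(FALSE, TRUE)]), "down")
  up_times <- tg$events$time_s[tg$events$direction == "up"]
  expect_equal(diff(up_times), rep(600, length(up_times) - 1))
})

test_that("packaged reference tables carry the printed values", {
  t1 <- load_fixture("table1")
  expect_equal(t1$dq_uJ[t1$mole_percent == 14], -18923)
  expect_equal(t1$dq_uJ[t1$mole_percent == 0], 70)
  expect_equal(t1$dq_uJ[t1$mole_percent == 100], -28808)
  t2 <- load_fixture("table2")
  expect_equal(t2$non_ideality[t2$mole_percent == 25], 0.431)
  expect_equal(t2$pct_PP[t2$mole_percent == 25], 50.37)
  expect_error(load_fixture("table9"))
})
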