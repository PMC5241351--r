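test_that("partial-volume expansivity model collapses and inverts exactly", {
  p <- expansivity_params(T_K = 298.65, dp_bar = 4, alpha0 = 2.57e-4,
                          V_part = 1.25e-3, g_s = 5e-4)
  # zero heat difference means the solute expands like the solvent
  expect_equal(alpha_bar_from_deltaq(0, p), p$alpha0)
  # forward-then-invert closure
  withr::local_seed(17)
  for (i in 1:20) {
    ab <- runif(1, -1e-3, 1e-3)
    dq <- deltaq_from_alpha_bar(p, alpha_bar = ab)
    expect_equal(alpha_bar_from_deltaq(dq, p), ab, tolerance = 1e-12)
  }
  # linearity in the pressure step
  p2 <- p
  p2$dp_bar <- 8
  expect_equal(deltaq_from_alpha_bar(p2, alpha_bar = 1e-4),
               2 * deltaq_from_alpha_bar(p, alpha_bar = 1e-4),
               tolerance = 1e-12)
  p3 <- p
  p3$g_s <- 0
  expect_error(alpha_bar_from_deltaq(100, p3), "nonzero")
})

test_that("hydration-layer model collapses correctly in limiting cases", {
  base <- expansivity_params(T_K = 298.15, dp_bar = 4, x_s = 0.01, n = 20,
                             V_b = 1.807e-5, V_h_bar = 1.75e-5,
                             V_s = 7.69e-5, alpha_b = 2.57e-4,
                             alpha_h_bar = 3.1e-4, alpha_s = 1.1e-3,
                             A_prime = 42)
  # no solute: only the empirical offset remains
  p0 <- base; p0$x_s <- 0
  expect_equal(eval_hydration_model(p0), 42)
  # no hydration layer, no offset: bulk-minus-solute expansivity only
  p1 <- base; p1$n <- 0; p1$A_prime <- 0
  expect_equal(eval_hydration_model(p1),
               p1$T_K * p1$dp_bar * 1e5 * p1$x_s *
                 (p1$V_b * p1$alpha_b - p1$V_s * p1$alpha_s) / 1e-6,
               tolerance = 1e-12)
})

test_that("hydration-layer model inverts for each free parameter", {
  withr::local_seed(23)
  for (i in 1:20) {
    p <- expansivity_params(T_K = runif(1, 280, 335), dp_bar = 4,
                            x_s = runif(1, 0.001, 0.03),
                            n = sample(5:40, 1),
                            V_b = 1.807e-5, V_h_bar = runif(1, 1.6e-5, 1.9e-5),
                            V_s = 7.69e-5, alpha_b = 2.57e-4,
                            alpha_h_bar = runif(1, -5e-4, 8e-4),
                            alpha_s = 1.1e-3, A_prime = runif(1, -100, 100))
    dq <- eval_hydration_model(p)
    expect_equal(invert_hydration_model(dq, p, "alpha_h_bar"), p$alpha_h_bar,
                 tolerance = 1e-10)
    expect_equal(invert_hydration_model(dq, p, "n"), p$n, tolerance = 1e-8)
    expect_equal(invert_hydration_model(dq, p, "A_prime"), p$A_prime,
                 tolerance = 1e-8)
  }
  # degenerate: bulk and hydration terms cancel
  pd <- expansivity_params(T_K = 298, dp_bar = 4, x_s = 0.01, n = 10,
                           V_b = 1.8e-5, V_h_bar = 1.8e-5, V_s = 7.7e-5,
                           alpha_b = 2.5e-4, alpha_h_bar = 2.5e-4,
                           alpha_s = 1e-3)
  expect_error(invert_hydration_model(100, pd, "n"), "cancel")
})

test_that("heat-capacity pressure derivative from volume polynomials", {
  # linear V(T): zero curvature
  expect_equal(hepler_gradient(c(1e-3, 2e-6), c(280, 300, 330)),
               rep(0, 3))
  # quadratic V(T) = c0 + c2 T^2: -2 c2 T
  c2 <- 3.5e-9
  expect_equal(hepler_gradient(c(1e-3, 0, c2), 300), -2 * c2 * 300)
  expect_equal(hepler_gradient(c(1e-3, 0, c2), c(280, 310)),
               -2 * c2 * c(280, 310), tolerance = 1e-15)
  # quartic against a central-difference numeric oracle; step chosen near
  # the truncation/roundoff optimum for these magnitudes
  cf <- c(2, 1e-3, 4e-5, 6e-8, 3e-11)
  Ts <- seq(280, 330, by = 10)
  h <- 0.1
  v <- function(tt) sapply(tt, function(s) sum(cf * s^(0:4)))
  oracle <- -Ts * (v(Ts + h) - 2 * v(Ts) + v(Ts - h)) / h^2
  expect_equal(hepler_gradient(cf, Ts), oracle, tolerance = 1e-8)
  # negative wherever V(T) is strictly convex
  expect_true(all(hepler_gradient(c(1, 0, 1e-6), seq(250, 400, 25)) < 0))
})

test_that("tabulated expansivity-product variant matches the analytic form", {
  cf <- c(2e-3, 1e-6, -4e-9, 6e-12)
  Ts <- seq(280, 335, by = 0.25)
  # d(V alpha)/dT with V*alpha := dV/dT gives the second-derivative form
  dv <- sapply(Ts, function(s) sum(cf[2:4] * c(1, 2 * s, 3 * s^2)))
  got <- hepler_gradient_tabulated(Ts, dv)
  want <- hepler_gradient(cf, Ts)
  interior <- 5:(length(Ts) - 4)
  expect_equal(got[interior], want[interior], tolerance = 1e-4)
  expect_error(hepler_gradient_tabulated(c(280, 290), c(1, 2)), "3")
})
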