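#' Parameter set of the expansivity and hydration-layer heat models
#'
#' Collects the symbols of the two pressurization-heat models and the
#' heat-capacity pressure-derivative identities into one validated record.
#' Unit conventions: temperature kelvin, pressure step bar (converted to Pa
#' internally), volumes m^3 per kg (specific, `V_part`) or m^3 per mol
#' (molar, `V_b`, `V_h_bar`, `V_s`), expansion coefficients 1/K, masses kg,
#' heats microjoule at the interface (joule internally).
#'
#' @param T_K Absolute temperature (K).
#' @param dp_bar Pressure step (bar).
#' @param alpha0 Solvent thermal expansion coefficient (1/K).
#' @param alpha_bar Solute partial-volume expansion coefficient (1/K).
#' @param V_part Partial specific volume of the solute (m^3/kg).
#' @param g_s Total solute mass (kg).
#' @param n Waters in the hydration layer of one solute.
#' @param x_s,x_b,x_h Mole fractions of solute, bulk and hydration-layer
#'   solvent.
#' @param V_b,V_h_bar,V_s Molar volumes (m^3/mol) of bulk solvent,
#'   hydration-layer solvent and solute.
#' @param alpha_b,alpha_h_bar,alpha_s Expansion coefficients (1/K) of bulk
#'   water, hydration layer and solute.
#' @param A_prime Empirical heat offset (microjoule); treated as a free
#'   offset, its physical origin being unsettled.
#' @return An object of class `"expansivity_params"` (a validated list).
#' @export
expansivity_params <- function(T_K = 298.15, dp_bar = 4, alpha0 = NA,
                               alpha_bar = NA, V_part = NA, g_s = NA,
                               n = NA, x_s = NA, x_b = NA, x_h = NA,
                               V_b = NA, V_h_bar = NA, V_s = NA,
                               alpha_b = NA, alpha_h_bar = NA, alpha_s = NA,
                               A_prime = 0) {
  stopifnot(T_K > 0, dp_bar > 0)
  for (xf in c(x_s, x_b, x_h))
    if (!is.na(xf) && (xf < 0 || xf > 1)) stop("mole fractions must be in [0, 1]")
  structure(list(T_K = T_K, dp_bar = dp_bar, alpha0 = alpha0,
                 alpha_bar = alpha_bar, V_part = V_part, g_s = g_s, n = n,
                 x_s = x_s, x_b = x_b, x_h = x_h, V_b = V_b,
                 V_h_bar = V_h_bar, V_s = V_s, alpha_b = alpha_b,
                 alpha_h_bar = alpha_h_bar, alpha_s = alpha_s,
                 A_prime = A_prime),
            class = "expansivity_params")
}

.BAR_PA <- 1e5
.UJ_J <- 1e-6

need <- function(p, fields) {
  miss <- fields[vapply(fields, function(f) is.na(p[[f]]), TRUE)]
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
}

#' Partial-volume expansivity model (forward and inverse)
#'
#' The single-population model relating the pressurization heat to the
#' difference between solvent and solute-partial-volume expansivities:
#' `dQ = T dp (alpha0 - alpha_bar) V_part g_s`. `deltaq_from_alpha_bar`
#' evaluates it forward; `alpha_bar_from_deltaq` inverts it,
#' `alpha_bar = alpha0 - dQ / (T dp V_part g_s)`. Valid at low solute
#' concentration where the apparent volume approximates the
#' infinite-dilution partial specific volume.
#'
#' @param dq_uJ Pressurization heat (microjoule).
#' @param p An [expansivity_params()] with `T_K`, `dp_bar`, `alpha0`,
#'   `V_part`, `g_s` set (and `alpha_bar` for the forward direction).
#' @return The expansion coefficient (1/K), or the heat (microjoule).
#' @export
alpha_bar_from_deltaq <- function(dq_uJ, p) {
  need(p, c("alpha0", "V_part", "g_s"))
  denom <- p$T_K * p$dp_bar * .BAR_PA * p$V_part * p$g_s
  if (denom == 0) stop("T * dp * V_part * g_s must be nonzero")
  p$alpha0 - dq_uJ * .UJ_J / denom
}

#' @rdname alpha_bar_from_deltaq
#' @param alpha_bar Solute partial-volume expansivity (1/K); defaults to
#'   the value stored in `p`.
#' @export
deltaq_from_alpha_bar <- function(p, alpha_bar = p$alpha_bar) {
  need(p, c("alpha0", "V_part", "g_s"))
  if (is.na(alpha_bar)) stop("alpha_bar is not set")
  p$T_K * p$dp_bar * .BAR_PA * (p$alpha0 - alpha_bar) * p$V_part * p$g_s /
    .UJ_J
}

#' Discrete hydration-layer heat model (forward and inverse)
#'
#' Treats the `n` hydration-layer waters of each solute as a population
#' with its own molar volume and expansivity, separate from bulk water:
#' `dQ = T dp x_s [(n + 1) V_b alpha_b - n V_h_bar alpha_h_bar
#' - V_s alpha_s] + A_prime`. Applicable while solutes are isolated
#' species in a bulk water phase; it does not describe extended solute
#' networks. `invert_hydration_model` solves the (linear) model for any one
#' of `alpha_h_bar`, `n` or `A_prime`.
#'
#' @param p An [expansivity_params()].
#' @return `eval_hydration_model`: the heat (microjoule).
#' @export
eval_hydration_model <- function(p) {
  need(p, c("x_s", "n", "V_b", "V_h_bar", "V_s", "alpha_b", "alpha_h_bar",
            "alpha_s"))
  bracket <- (p$n + 1) * p$V_b * p$alpha_b -
    p$n * p$V_h_bar * p$alpha_h_bar - p$V_s * p$alpha_s
  (p$T_K * p$dp_bar * .BAR_PA * p$x_s * bracket) / .UJ_J + p$A_prime
}

#' @rdname eval_hydration_model
#' @param dq_uJ Observed heat (microjoule).
#' @param solve_for One of `"alpha_h_bar"`, `"n"`, `"A_prime"`.
#' @export
invert_hydration_model <- function(dq_uJ, p,
                                   solve_for = c("alpha_h_bar", "n",
                                                 "A_prime")) {
  solve_for <- match.arg(solve_for)
  scale <- p$T_K * p$dp_bar * .BAR_PA * p$x_s
  if (solve_for != "A_prime" && (is.na(scale) || scale == 0))
    stop("T * dp * x_s must be nonzero to invert for ", solve_for)
  core <- (dq_uJ - p$A_prime) * .UJ_J / scale
  switch(solve_for,
    A_prime = {
      need(p, c("x_s", "n", "V_b", "V_h_bar", "V_s", "alpha_b",
                "alpha_h_bar", "alpha_s"))
      p$A_prime <- 0
      dq_uJ - eval_hydration_model(p)
    },
    alpha_h_bar = {
      need(p, c("n", "V_b", "V_h_bar", "V_s", "alpha_b", "alpha_s"))
      if (p$n == 0 || p$V_h_bar == 0)
        stop("n * V_h_bar must be nonzero to solve for alpha_h_bar")
      ((p$n + 1) * p$V_b * p$alpha_b - p$V_s * p$alpha_s - core) /
        (p$n * p$V_h_bar)
    },
    n = {
      need(p, c("V_b", "V_h_bar", "V_s", "alpha_b", "alpha_h_bar",
                "alpha_s"))
      coef_n <- p$V_b * p$alpha_b - p$V_h_bar * p$alpha_h_bar
      if (abs(coef_n) < 1e-300)
        stop("bulk and hydration-layer expansivity terms cancel; cannot solve for n")
      (core - p$V_b * p$alpha_b + p$V_s * p$alpha_s) / coef_n
    })
}

#' Heat-capacity pressure derivative from a volume polynomial
#'
#' The thermodynamic identity `[dCp_part/dp]_T = -T d^2(V_part)/dT^2`,
#' evaluated analytically from the coefficients of a polynomial
#' `V(T) = c0 + c1 T + ... + ck T^k` (T in kelvin). Negative wherever
#' `V(T)` is strictly convex.
#'
#' @param coefficients Numeric vector `c0..ck`.
#' @param T_K Temperatures (K) at which to evaluate.
#' @return Numeric vector, in the volume unit of the coefficients times
#'   kelvin^-1.
#' @export
hepler_gradient <- function(coefficients, T_K) {
  stopifnot(length(coefficients) >= 1L, all(T_K > 0))
  k <- seq_along(coefficients) - 1L
  vapply(T_K, function(tt) {
    d2 <- sum(coefficients * k * (k - 1) * tt^(pmax(k - 2L, 0L)))
    -tt * d2
  }, numeric(1))
}

#' @describeIn hepler_gradient Equivalent form via the expansivity product:
#'   `-T d(V_part alpha_bar)/dT`, from a tabulated `(T, V_part * alpha_bar)`
#'   curve by central finite differences (one-sided at the ends). Needs at
#'   least 3 points.
#' @param V_alpha Tabulated `V_part * alpha_bar` values at `T_K`.
#' @export
hepler_gradient_tabulated <- function(T_K, V_alpha) {
  stopifnot(length(T_K) == length(V_alpha))
  if (length(T_K) < 3L) stop("at least 3 tabulated points are required")
  -T_K * pracma::gradient(V_alpha, T_K)
}
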