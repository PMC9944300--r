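# Independent oracles, written directly from the model formulas rather than
# through the package's solvers, for cross-checking roots and geometry.

MMHG <- 133.322387415

# Steady-state balance LHS built from first principles (own theta, cap
# geometry, volume conservation and tension law; no package internals).
oracle_balance_lhs <- function(r, p, n_blebs = 1L) {
  th <- pi - asin(p$a / r)
  R <- (p$R0^3 + n_blebs * 2 * r^3 * (2 + cos(th)) * sin(th / 2)^4)^(1 / 3)
  S <- n_blebs * 2 * pi * r^2 * (1 - cos(th)) + pi * (p$d^2 - n_blebs * p$a^2)
  S0 <- pi * p$d^2
  S_star <- S0 * (1 + p$eps_star)
  Sigma_bar <- if (S <= S_star) p$sigma_0 else
    p$sigma_0 + p$K_m * (exp((S - S_star) / S_star) - 1)
  A0 <- 3 * pi * p$R0^2 - pi * p$d^2
  A <- 3 * pi * R^2 - pi * p$d^2
  A_star <- A0 * (1 + p$eps_star)
  sigma_bar <- if (A <= A_star) p$sigma_0 else
    p$sigma_0 + p$K_m * (exp((A - A_star) / A_star) - 1)
  2 * Sigma_bar / r + 2 * sigma_bar / R
}

# All roots of the balance at a pressure, by dense sign scan + bisection.
oracle_equilibria <- function(delta_p, p, r_max = 30, n_grid = 1e4) {
  rg <- seq(p$a * (1 + 1e-9), r_max, length.out = n_grid)
  f <- vapply(rg, function(r) oracle_balance_lhs(r, p) - delta_p, numeric(1))
  idx <- which(diff(sign(f)) != 0)
  vapply(idx, function(i)
    uniroot(function(r) oracle_balance_lhs(r, p) - delta_p,
            c(rg[i], rg[i + 1]), tol = 1e-12)$root, numeric(1))
}

# Reservoir-exhaustion radius S(r) = S0 (1 + eps*) by direct root finding.
oracle_reservoir_radius <- function(p) {
  uniroot(function(r) {
    th <- pi - asin(p$a / r)
    2 * pi * r^2 * (1 - cos(th)) + pi * (p$d^2 - p$a^2) -
      pi * p$d^2 * (1 + p$eps_star)
  }, c(p$a * (1 + 1e-9), 100), tol = 1e-12)$root
}

# Cap volume / area by numerical quadrature of the solid / surface of
# revolution (sphere of radius r, polar angle 0..theta).
oracle_cap_volume <- function(r, theta) {
  integrate(function(x) pi * (r^2 - x^2), r * cos(theta), r,
            rel.tol = 1e-12)$value
}
oracle_cap_area <- function(r, theta) {
  integrate(function(phi) 2 * pi * r^2 * sin(phi), 0, theta,
            rel.tol = 1e-12)$value
}
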