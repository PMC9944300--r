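# Steady states of the pressure balance delta_p = 2*Sigma_bar(r)/r +
# 2*sigma_bar(r)/R(r), with tensions slaved to their targets. The left-hand
# side is strictly decreasing in r on the cortex branch (Sigma_bar = sigma_0)
# and strictly increasing on the membrane branch (exponential stiffening
# beyond reservoir exhaustion S = S*), so each branch carries at most one
# root and the two meet at the saddle-node r = r*(eps_star).

# Per-bleb radius at which the (shared) patch reservoir is exhausted:
# solves n * 2 pi r^2 (1 - cos theta) + pi (d^2 - n a^2) = pi d^2 (1+eps*),
# i.e. 2 r^2 (1 - cos theta(r)) = d^2 eps*/n + a^2.
reservoir_radius <- function(params, n_blebs = 1L) {
  target <- params$d^2 * params$eps_star / n_blebs + params$a^2
  g <- function(r) 2 * r^2 * (1 - cos(opening_angle(r, params$a))) - target
  if (g(params$a) >= 0)
    stop("membrane reservoir exhausted at or below the pore radius ",
         "(eps_star too small for this pore/patch geometry)")
  hi <- params$a * 2
  while (g(hi) < 0) hi <- hi * 2
  stats::uniroot(g, c(params$a, hi), tol = 1e-12)$root
}

# Steady-state balance LHS F(r) = 2 Sigma_bar/r + 2 sigma_bar/R for n
# identical blebs of radius r (shared patch if n > 1), tensions slaved.
equilibrium_lhs <- function(r, params, n_blebs = 1L, exp_cap = 50) {
  vapply(r, function(ri) {
    rr <- rep(ri, n_blebs)
    ev <- sys_eval(rr, rep(params$sigma_0, n_blebs), params, delta_p = 0,
                   shared = TRUE, active = rep(TRUE, n_blebs),
                   exp_cap = exp_cap)
    Sigma_bar <- target_tension_capped(ev$S[1], pi * params$d^2, params,
                                       exp_cap)
    2 * Sigma_bar / ri + 2 * ev$sigma / ev$R
  }, numeric(1))
}

# Slaved radius velocity used for the stability sign test (fast-tension
# limit: Sigma = Sigma_bar on its branch, sigma = sigma_bar).
slaved_drdt <- function(r, delta_p, params, n_blebs = 1L) {
  r / (4 * params$mu) * (delta_p - equilibrium_lhs(r, params, n_blebs))
}

#' Stability of an equilibrium radius
#'
#' Sign test on the tension-slaved one-dimensional reduced dynamics:
#' the equilibrium is stable iff `d(dr/dt)/dr < 0` at `r_eq` (central finite
#' difference, step `1e-6 * r_eq`). Membrane-branch equilibria are stable,
#' cortex-branch ones unstable.
#'
#' @param r_eq equilibrium radius, um.
#' @param delta_p pressure drop, pN/um^2.
#' @param params a [gv_params()] object.
#' @param n_blebs number of identical blebs sharing the patch.
#' @return `TRUE` (stable), `FALSE` (unstable) or `NA` (marginal: derivative
#'   indistinguishable from zero).
#' @export
equilibrium_stable <- function(r_eq, delta_p, params, n_blebs = 1L) {
  h <- 1e-6 * r_eq
  dd <- (slaved_drdt(r_eq + h, delta_p, params, n_blebs) -
           slaved_drdt(r_eq - h, delta_p, params, n_blebs)) / (2 * h)
  if (abs(dd) < 1e-12) return(NA)
  dd < 0
}

#' Steady-state configurations at a given pressure drop
#'
#' Finds all admissible roots of the steady-state balance
#' `delta_p = 2 Sigma_bar(r)/r + 2 sigma_bar(r)/R(r)` on `r >= a`, bracketing
#' the monotone cortex branch (`[a, r*]`) and membrane branch (`[r*, ...]`)
#' separately, where `r*` is the reservoir-exhaustion radius `S(r*) = S*`.
#' Each root is classified by branch and linear stability.
#'
#' @param delta_p pressure drop, pN/um^2 (use [mmHg_to_pN_um2()] for mmHg).
#' @param params a [gv_params()] object.
#' @param n_blebs number of identical blebs sharing one patch (symmetric
#'   configuration); 1 for the single-vacuole problem.
#' @return a data frame of class `gv_equilibria`, one row per equilibrium,
#'   sorted by radius, with columns `delta_p`, `delta_p_mmHg`, `r`, `R`,
#'   `Sigma`, `sigma`, `branch`, `stable`, `volume` (cap volume, um^3) and
#'   `residual` (relative balance residual). Zero rows is a valid result
#'   (pressure below the nucleation threshold).
#' @examples
#' gv_equilibria(mmHg_to_pN_um2(7), gv_params())
#' @export
gv_equilibria <- function(delta_p, params, n_blebs = 1L) {
  params <- validate_params(params)
  stopifnot(delta_p >= 0)
  r_star <- reservoir_radius(params, n_blebs)
  F <- function(r) equilibrium_lhs(r, params, n_blebs)
  roots <- list()

  # cortex branch: F strictly decreasing on [a, r_star]
  Fa <- F(params$a); Fstar <- F(r_star)
  if (delta_p >= Fstar && delta_p <= Fa) {
    rc <- stats::uniroot(function(r) F(r) - delta_p,
                         c(params$a, r_star), tol = 1e-12)$root
    roots <- c(roots, list(list(r = rc, branch = "cortex")))
  }
  # membrane branch: F strictly increasing beyond r_star
  if (delta_p >= Fstar) {
    hi <- r_star
    repeat {
      hi2 <- hi * 1.5
      val <- tryCatch(F(hi2), error = function(e) NA_real_)
      if (!is.finite(val)) break
      hi <- hi2
      if (val > delta_p) break
    }
    if (is.finite(F(hi)) && F(hi) >= delta_p && hi > r_star) {
      rm_ <- stats::uniroot(function(r) F(r) - delta_p,
                            c(r_star, hi), tol = 1e-12)$root
      # avoid double-reporting the saddle-node point itself
      if (!length(roots) || abs(rm_ - roots[[1]]$r) > 1e-9)
        roots <- c(roots, list(list(r = rm_, branch = "membrane")))
    }
  }

  rows <- lapply(roots, function(rt) {
    rr <- rep(rt$r, n_blebs)
    ev <- sys_eval(rr, rep(params$sigma_0, n_blebs), params, delta_p = 0,
                   shared = TRUE, active = rep(TRUE, n_blebs))
    Sigma_bar <- target_tension_capped(ev$S[1], pi * params$d^2, params)
    data.frame(delta_p = delta_p, delta_p_mmHg = pN_um2_to_mmHg(delta_p),
               r = rt$r, R = ev$R, Sigma = Sigma_bar, sigma = ev$sigma,
               branch = rt$branch,
               stable = equilibrium_stable(rt$r, delta_p, params, n_blebs),
               volume = cap_volume(rt$r, ev$theta[1]),
               residual = abs(equilibrium_lhs(rt$r, params, n_blebs) -
                                delta_p) / max(delta_p, 1))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(delta_p = numeric(0), delta_p_mmHg = numeric(0),
               r = numeric(0), R = numeric(0), Sigma = numeric(0),
               sigma = numeric(0), branch = character(0), stable = logical(0),
               volume = numeric(0), residual = numeric(0))
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gv_equilibria", "data.frame")
  attr(out, "params") <- params
  attr(out, "n_blebs") <- n_blebs
  out
}

#' Nucleation-pressure estimate
#'
#' Closed-form saddle-node estimate of the lower threshold pressure for
#' vacuole formation: `delta_p* = 2 sigma_0 (R + r) / (R r)` evaluated at the
#' reservoir-exhaustion geometry, i.e. the radius `r` where the patch area
#' reaches `S* = pi d^2 (1 + eps_star)` and `R` from volume conservation at
#' that radius. Scales linearly with `sigma_0` and decreases with `eps_star`.
#'
#' @param params a [gv_params()] object.
#' @param n_blebs number of identical blebs sharing the patch.
#' @return threshold pressure in pN/um^2.
#' @export
nucleation_pressure <- function(params, n_blebs = 1L) {
  params <- validate_params(params)
  r_star <- reservoir_radius(params, n_blebs)
  R <- cell_radius(rep(r_star, n_blebs), params$a, params$R0)
  2 * params$sigma_0 * (R + r_star) / (R * r_star)
}

#' Upper threshold pressure for bistability
#'
#' The pressure above which the cortex-branch equilibrium exits the
#' admissible domain (its radius reaches the pore half-width `a`), leaving
#' the single membrane-branch steady state: the cortex-branch balance
#' evaluated at `r = a`, approximately `2 sigma_0 / a + 2 sigma_0 / R0`.
#'
#' @param params a [gv_params()] object.
#' @param n_blebs number of identical blebs sharing the patch.
#' @return threshold pressure in pN/um^2.
#' @export
bistability_pressure <- function(params, n_blebs = 1L) {
  params <- validate_params(params)
  equilibrium_lhs(params$a, params, n_blebs)
}

#' Pressure scan: branch structure and thresholds
#'
#' Tabulates all equilibria across a pressure grid and locates the two
#' threshold pressures: `delta_p*` (smallest pressure with any equilibrium;
#' refined by bisection on root existence to 1e-3 mmHg) and `delta_p_dagger`
#' (cortex root reaches `r = a`; closed form). Between the thresholds the
#' system is bistable (2 equilibria), above `delta_p_dagger` monostable (1),
#' below `delta_p*` vacuole-free (0).
#'
#' @param params a [gv_params()] object.
#' @param delta_p_grid_mmHg increasing grid of pressures, mmHg.
#' @param n_blebs number of identical blebs sharing the patch.
#' @return an object of class `gv_scan`: list with `records` (row-bound
#'   [gv_equilibria()] tables), `delta_p_star_mmHg`, `delta_p_dagger_mmHg`
#'   and `counts` (equilibria per grid pressure).
#' @examples
#' \donttest{
#' sc <- pressure_scan(gv_params(), seq(1, 35, by = 1))
#' sc$delta_p_star_mmHg
#' }
#' @export
pressure_scan <- function(params, delta_p_grid_mmHg = seq(0.5, 35, by = 0.5),
                          n_blebs = 1L) {
  stopifnot(all(diff(delta_p_grid_mmHg) > 0), all(delta_p_grid_mmHg > 0))
  grid <- mmHg_to_pN_um2(delta_p_grid_mmHg)
  recs <- lapply(grid, gv_equilibria, params = params, n_blebs = n_blebs)
  counts <- vapply(recs, nrow, integer(1))

  # delta_p*: bisection on existence between last-empty and first-nonempty
  star <- NA_real_
  i1 <- which(counts > 0)[1]
  if (!is.na(i1)) {
    if (i1 == 1L) {
      star <- delta_p_grid_mmHg[1]  # grid starts above threshold; flag below
      attr(star, "bracketed") <- FALSE
    } else {
      lo <- delta_p_grid_mmHg[i1 - 1]; hi <- delta_p_grid_mmHg[i1]
      while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        if (nrow(gv_equilibria(mmHg_to_pN_um2(mid), params, n_blebs)) > 0)
          hi <- mid else lo <- mid
      }
      star <- (lo + hi) / 2
      attr(star, "bracketed") <- TRUE
    }
  }
  dagger <- pN_um2_to_mmHg(bistability_pressure(params, n_blebs))
  records <- do.call(rbind, lapply(recs, as.data.frame))
  structure(list(records = records, counts = counts,
                 delta_p_grid_mmHg = delta_p_grid_mmHg,
                 delta_p_star_mmHg = star, delta_p_dagger_mmHg = dagger,
                 params = params, n_blebs = n_blebs),
            class = "gv_scan")
}
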