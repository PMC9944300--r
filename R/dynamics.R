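# Coupled dynamics: overdamped Rayleigh-Plesset radius equation per bleb,
# cortical tension relaxation per bleb, with the opening angle, cell radius,
# cell tension, intracellular pressure and membrane-regime tensions slaved
# algebraically at every evaluation. Stiff integration via deSolve::lsodar
# with terminal roots for collapse (r = a) and the lytic overflow guard.

# Evaluate all slaved quantities and the RHS at one state.
# r, Sigma: vectors of length n (collapsed blebs carry r = a, active FALSE).
sys_eval <- function(r, Sigma, params, delta_p, shared, active,
                     frozen_R = FALSE, fixed_Sigma = NULL, exp_cap = 50) {
  n <- length(r)
  r <- pmax(r, params$a)
  theta <- opening_angle(r, params$a)
  k <- if (shared) 1L else n
  ract <- r[active]
  R <- if (frozen_R) params$R0 else cell_radius(ract, params$a, params$R0)
  A0 <- cell_area(params$R0, params$d, k)
  A <- cell_area(R, params$d, k)
  sigma <- target_tension_capped(A, A0, params, exp_cap)
  P <- 2 * sigma / R

  S0 <- pi * params$d^2
  capA <- cap_area(r, theta)
  if (shared) {
    # one patch; pores of collapsed blebs remain excised, caps removed
    S_patch <- sum(capA[active]) + pi * (params$d^2 - n * params$a^2)
    S <- rep(S_patch, n)
  } else {
    S <- capA + pi * (params$d^2 - params$a^2)
  }
  Sigma_eff <- effective_tension(Sigma, S, S0, params, exp_cap)
  if (!is.null(fixed_Sigma)) Sigma_eff <- rep(fixed_Sigma, n)

  drdt <- ifelse(active, r / (4 * params$mu) * (delta_p - P - 2 * Sigma_eff / r), 0)
  dSdt <- ifelse(active, relax_tension_rhs(Sigma, params$sigma_0, params$tau_c), 0)

  S_star <- S0 * (1 + params$eps_star)
  A_star <- A0 * (1 + params$eps_star)
  max_exp <- max((S - S_star) / S_star, (A - A_star) / A_star)

  list(theta = theta, R = R, A = A, sigma = sigma, P = P, S = S,
       Sigma_eff = Sigma_eff, drdt = drdt, dSdt = dSdt,
       eps_B = (S - S0) / S0, eps_C = (A - A0) / A0, max_exp = max_exp)
}

# Core integrator shared by single- and multi-bleb simulation.
# Restarts after each non-final collapse event with the collapsed bleb
# frozen at r = a (its cap removed from the patch area and cell volume).
simulate_blebs <- function(params, protocol, r0, Sigma0 = params$sigma_m,
                           shared = TRUE, n_out = 1001L,
                           rtol = 1e-8, atol = 1e-10,
                           frozen_R = FALSE, fixed_Sigma = NULL,
                           exp_cap = 50) {
  params <- validate_params(params)
  stopifnot(inherits(protocol, "gv_protocol"))
  n <- length(r0)
  Sigma0 <- rep_len(Sigma0, n)
  if (any(r0 < params$a)) stop("initial radius below pore half-width a")
  if (any(Sigma0 < 0)) stop("initial tension must be >= 0")
  delta_p <- applied_delta_p(protocol)

  active <- rep(TRUE, n)
  a_stop <- params$a * (1 - 1e-9)

  rhs <- function(t, y, parms) {
    ev <- sys_eval(y[seq_len(n)], y[n + seq_len(n)], params, delta_p,
                   shared, active, frozen_R, fixed_Sigma, exp_cap)
    list(c(ev$drdt, ev$dSdt))
  }
  rootf <- function(t, y, parms) {
    ev <- sys_eval(y[seq_len(n)], y[n + seq_len(n)], params, delta_p,
                   shared, active, frozen_R, fixed_Sigma, exp_cap)
    c(ifelse(active, y[seq_len(n)] - a_stop, 1), exp_cap - ev$max_exp)
  }

  times <- seq(0, protocol$t_max, length.out = n_out)
  y <- c(r0, Sigma0)
  pieces <- list()
  events <- data.frame(time = numeric(0), kind = character(0),
                       bleb = integer(0))
  t_now <- 0
  repeat {
    tt <- unique(c(t_now, times[times > t_now]))
    out <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "lsodar", rootfunc = rootf,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    pieces[[length(pieces) + 1L]] <- out
    iroot <- attributes(out)$iroot
    t_end <- out[nrow(out), 1]
    if (is.null(iroot) || !any(iroot != 0) || t_end >= protocol$t_max) {
      if (!is.null(iroot) && any(iroot != 0)) {
        hit <- which(iroot != 0)
        for (i in hit[hit <= n])
          events <- rbind(events, data.frame(time = t_end,
                                             kind = "collapsed", bleb = i))
        if (any(hit == n + 1L))
          events <- rbind(events, data.frame(time = t_end, kind = "lytic",
                                             bleb = NA_integer_))
      }
      break
    }
    hit <- which(iroot != 0)
    if (any(hit == n + 1L)) {   # lytic: terminal for the whole system
      events <- rbind(events, data.frame(time = t_end, kind = "lytic",
                                         bleb = NA_integer_))
      break
    }
    y <- out[nrow(out), -1]
    for (i in hit[hit <= n]) {
      events <- rbind(events, data.frame(time = t_end, kind = "collapsed",
                                         bleb = i))
      active[i] <- FALSE
      y[i] <- params$a
      y[n + i] <- y[n + i]   # tension frozen as-is
    }
    if (!any(active)) break
    t_now <- t_end
  }

  raw <- do.call(rbind, lapply(pieces, function(m) m[, , drop = FALSE]))
  raw <- raw[!duplicated(raw[, 1]), , drop = FALSE]
  traj <- build_trajectory(raw, n, params, protocol, delta_p, shared,
                           events, exp_cap)
  traj
}

# Assemble the annotated trajectory table from integrator output.
build_trajectory <- function(raw, n, params, protocol, delta_p, shared,
                             events, exp_cap) {
  t <- raw[, 1]
  rmat <- matrix(raw[, 1 + seq_len(n)], ncol = n)
  smat <- matrix(raw[, 1 + n + seq_len(n)], ncol = n)
  # reconstruct active masks through time from collapse events
  act <- matrix(TRUE, nrow = length(t), ncol = n)
  for (j in seq_len(nrow(events))) {
    if (events$kind[j] == "collapsed")
      act[t > events$time[j], events$bleb[j]] <- FALSE
  }
  cols <- vector("list", length(t))
  for (i in seq_along(t)) {
    ev <- sys_eval(rmat[i, ], smat[i, ], params, delta_p, shared, act[i, ],
                   exp_cap = exp_cap)
    cols[[i]] <- c(ev$theta, ev$Sigma_eff, ev$S, ev$eps_B,
                   ev$R, ev$sigma, ev$P, ev$eps_C[1])
  }
  m <- do.call(rbind, cols)
  nm <- function(base) if (n == 1L) base else paste0(base, "_", seq_len(n))
  df <- data.frame(t = t)
  df[nm("r")] <- as.data.frame(rmat)
  df[nm("theta")] <- as.data.frame(m[, seq_len(n), drop = FALSE])
  df[nm("Sigma")] <- as.data.frame(m[, n + seq_len(n), drop = FALSE])
  df[nm("S")] <- as.data.frame(m[, 2 * n + seq_len(n), drop = FALSE])
  df[nm("eps_B")] <- as.data.frame(m[, 3 * n + seq_len(n), drop = FALSE])
  df$R <- m[, 4 * n + 1]
  df$sigma <- m[, 4 * n + 2]
  df$P <- m[, 4 * n + 3]
  df$eps_C <- m[, 4 * n + 4]
  S0 <- pi * params$d^2
  regime <- ifelse(m[, 2 * n + seq_len(n), drop = FALSE] >
                     S0 * (1 + params$eps_star), "membrane", "cortex")
  df[nm("regime")] <- as.data.frame(regime, stringsAsFactors = FALSE)

  # regime-switch annotations from sign changes of eps_B - eps_star
  for (j in seq_len(n)) {
    eb <- m[, 3 * n + j] - params$eps_star
    cross <- which(diff(sign(eb)) != 0)
    for (i in cross) {
      tc <- t[i] + (t[i + 1] - t[i]) * abs(eb[i]) / (abs(eb[i]) + abs(eb[i + 1]))
      events <- rbind(events,
                      data.frame(time = tc, kind = "regime_switch", bleb = j))
    }
  }
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(states = df, events = events, params = params,
                 protocol = protocol, n_blebs = n, shared = shared),
            class = "gv_trajectory")
}

#' Radius growth rate of an inverse bleb
#'
#' The overdamped Rayleigh-Plesset balance at the cell-bleb interface:
#' `dr/dt = r/(4 mu) * (delta_p - P - 2 Sigma / r)`, with `P` the
#' intracellular gauge pressure (Laplace: `P = 2 sigma / R`) and `Sigma`
#' the bleb surface tension.
#'
#' @param r bleb radius, um (vectorised).
#' @param Sigma bleb surface tension, pN/um.
#' @param P intracellular gauge pressure, pN/um^2.
#' @param delta_p applied pressure drop, pN/um^2.
#' @param params a [gv_params()] object.
#' @return dr/dt in um/s.
#' @export
radius_rhs <- function(r, Sigma, P, delta_p, params) {
  r / (4 * params$mu) * (delta_p - P - 2 * Sigma / r)
}

#' Simulate a single inverse bleb under a perfusion protocol
#'
#' Integrates the coupled system (radius dynamics + cortical tension
#' relaxation, with intracellular pressure, cell radius, opening angle and
#' membrane-regime tension slaved algebraically) from nucleation to `t_max`,
#' collapse (`r = a`) or lytic overflow. The default initial condition is
#' the nucleation state `r0 = a`, `Sigma0 = sigma_m` (locally disrupted
#' cortex).
#'
#' @param params a [gv_params()] object.
#' @param protocol a [gv_protocol()] object.
#' @param r0 initial bleb radius, um.
#' @param Sigma0 initial bleb tension, pN/um.
#' @param n_out number of output sampling times.
#' @param rtol,atol integrator tolerances (stiff, adaptive `lsodar`).
#' @return an object of class `gv_trajectory`: a list with `states` (time
#'   series data frame: `t`, `r`, `theta`, `Sigma`, `S`, `eps_B`, `R`,
#'   `sigma`, `P`, `eps_C`, `regime`), `events` (collapse / lytic /
#'   regime-switch annotations), and the params/protocol used.
#' @examples
#' \donttest{
#' traj <- gv_simulate(gv_params(), gv_protocol(delta_p_mmHg = 30, t_max = 300))
#' summary(traj)
#' }
#' @seealso [gv_collapse()], [time_to_steady()], [gv_simulate_multi()]
#' @export
gv_simulate <- function(params, protocol, r0 = params$a,
                        Sigma0 = params$sigma_m, n_out = 1001L,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(r0) == 1L)
  simulate_blebs(params, protocol, r0, Sigma0, shared = TRUE, n_out = n_out,
                 rtol = rtol, atol = atol)
}

#' Giant-vacuole collapse after pressure removal
#'
#' Prepares the vacuole at its stable (membrane-branch) steady state under
#' `delta_p_prepare`, then removes the pressure drop at `t = 0+` and
#' integrates until the vacuole deflates back to the pore radius `r = a`.
#'
#' @param params a [gv_params()] object.
#' @param delta_p_prepare_mmHg preparation pressure drop, mmHg.
#' @param t_max integration horizon, s.
#' @param ... passed to [gv_simulate()].
#' @return a `gv_trajectory` with attribute `collapse_time_min` (first
#'   passage to `r = a`, minutes).
#' @export
gv_collapse <- function(params, delta_p_prepare_mmHg = 30, t_max = 1800, ...) {
  eq <- gv_equilibria(mmHg_to_pN_um2(delta_p_prepare_mmHg), params)
  stable <- eq[which(eq$stable), , drop = FALSE]
  if (nrow(stable) == 0L)
    stop("no stable equilibrium at ", delta_p_prepare_mmHg,
         " mmHg: cannot prepare the collapse run")
  r_eq <- stable$r[nrow(stable)]
  protocol <- gv_protocol(delta_p_mmHg = delta_p_prepare_mmHg,
                          schedule = "step_to_zero", t_max = t_max)
  traj <- gv_simulate(params, protocol, r0 = r_eq,
                      Sigma0 = params$sigma_0, ...)
  coll <- traj$events[traj$events$kind == "collapsed", , drop = FALSE]
  attr(traj, "collapse_time_min") <-
    if (nrow(coll)) coll$time[1] / 60 else NA_real_
  traj
}

#' Time to reach the steady-state radius
#'
#' First simulated time at which the bleb radius is within `rtol` (relative)
#' of the target steady radius `r_star`, reported in minutes. If `r_star` is
#' not given, the membrane-branch equilibrium radius for the trajectory's
#' own parameters and pressure is used.
#'
#' @param traj a single-bleb `gv_trajectory`.
#' @param r_star target steady radius, um.
#' @param rtol relative closeness criterion (default 1%).
#' @return time in minutes, or `NA` (with a `"reason"` attribute) if the
#'   radius never gets that close within the simulated horizon.
#' @export
time_to_steady <- function(traj, r_star = NULL, rtol = 0.01) {
  stopifnot(inherits(traj, "gv_trajectory"), traj$n_blebs == 1L)
  if (is.null(r_star)) {
    eq <- gv_equilibria(applied_delta_p(traj$protocol), traj$params)
    mem <- eq[eq$branch == "membrane", , drop = FALSE]
    if (nrow(mem) == 0L)
      stop("no membrane-branch equilibrium at this pressure; give r_star")
    r_star <- mem$r[1]
  }
  ok <- abs(traj$states$r - r_star) <= rtol * r_star
  if (!any(ok))
    return(structure(NA_real_, reason = "not reached"))
  traj$states$t[which(ok)[1]] / 60
}
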