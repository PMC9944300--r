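# Two-regime surface-tension law. Below the reservoir threshold strain
# eps_star the area increase is buffered by membrane reservoirs at constant
# target tension sigma_0 (cortex-dominated); beyond it the taut membrane
# stiffens exponentially with excess area (membrane-dominated). The law is
# continuous at the threshold.

#' Target (equilibrated) surface tension of a membrane patch
#'
#' For a patch of current area `S` and resting area `S0` the steady-state
#' tension is `sigma_0` while `S <= S* = S0 (1 + eps_star)` (reservoirs still
#' buffering), and `sigma_0 + K_m * (exp((S - S*)/S*) - 1)` beyond (taut
#' membrane). The same functional form applies to the cell with `A`, `A0` in
#' place of `S`, `S0`.
#'
#' @param S current area, um^2 (vectorised).
#' @param S0 resting area, um^2.
#' @param params a [gv_params()] object.
#' @param exp_cap overflow guard: the exponent `(S - S*)/S*` beyond which the
#'   membrane is considered lytic and an error is raised.
#' @return target tension, pN/um.
#' @export
target_tension <- function(S, S0, params, exp_cap = 50) {
  stopifnot(S0 > 0)
  S_star <- S0 * (1 + params$eps_star)
  x <- (S - S_star) / S_star
  if (any(x > exp_cap))
    stop("lytic overflow: membrane strain exponent ", format(max(x)),
         " exceeds cap ", exp_cap)
  ifelse(S <= S_star, params$sigma_0, params$sigma_0 + params$K_m * expm1(x))
}

# Capped variant used inside the integrator RHS: never errors, the lytic
# condition is detected separately as a terminal integration root.
target_tension_capped <- function(S, S0, params, exp_cap = 50) {
  S_star <- S0 * (1 + params$eps_star)
  x <- pmin((S - S_star) / S_star, exp_cap)
  ifelse(S <= S_star, params$sigma_0, params$sigma_0 + params$K_m * expm1(x))
}

#' Cortical tension relaxation rate
#'
#' Exponential relaxation of a tension `Sigma` toward its target at rate
#' `1/tau`: `dSigma/dt = (target - Sigma) / tau`. In the cortex-dominated
#' regime the bleb's contractile shell is rebuilt with `target = sigma_0`
#' and `tau = tau_c`.
#'
#' @param Sigma current tension, pN/um.
#' @param target target tension, pN/um.
#' @param tau relaxation timescale, s.
#' @return dSigma/dt in pN/(um s).
#' @export
relax_tension_rhs <- function(Sigma, target, tau) {
  stopifnot(tau > 0)
  (target - Sigma) / tau
}

# Effective bleb tension entering the radius dynamics. In the cortex regime
# (S <= S*) the tension is the relaxing dynamic variable Sigma_state; in the
# membrane regime it is algebraically slaved to the target (tau_m -> 0
# limit). max() preserves continuity and monotone loading in the degenerate
# case where the threshold is crossed before cortical relaxation completes.
effective_tension <- function(Sigma_state, S, S0, params, exp_cap = 50) {
  S_star <- S0 * (1 + params$eps_star)
  tgt <- target_tension_capped(S, S0, params, exp_cap)
  ifelse(S <= S_star, Sigma_state, pmax(Sigma_state, tgt))
}
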