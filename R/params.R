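#' Model parameters for the inverse-blebbing model
#'
#' Bundles all physical constants of the coarse-grained giant-vacuole model
#' into a validated `gv_params` object. Defaults are the reference values for
#' a Schlemm's-canal endothelial cell. The derived resting cell surface
#' tension `sigma_0 = sigma_m + sigma_c` is always recomputed and cannot be
#' set directly.
#'
#' @param R0 initial (hemispherical) cell radius, um.
#' @param a basal pore half-width, um; the vacuole mouth is pinned at this
#'   radius by the geometric constraint `r * sin(theta) = a`.
#' @param sigma_m membrane entropic tension, pN/um.
#' @param sigma_c cortical (actomyosin) tension, pN/um.
#' @param K_m membrane area-expansion modulus, pN/um; dominates the tension
#'   once membrane reservoirs are exhausted.
#' @param d tension-equilibration patch radius, um; vacuoles nucleated closer
#'   than `d` compete for the same membrane patch.
#' @param eps_star membrane-reservoir threshold area strain (dimensionless,
#'   in `[0, 3]`); below it area increase is buffered at constant tension.
#' @param tau_c cortex turnover timescale, s.
#' @param mu effective dynamic viscosity of the cell interior, pN s/um^2.
#'
#' @return an object of class `gv_params`: a named list with the fields above
#'   plus `sigma_0`.
#' @examples
#' p <- gv_params()
#' p$sigma_0          # 414 pN/um
#' gv_params(sigma_c = 187)  # reduced cortical contractility
#' @seealso [validate_params()], [gv_protocol()]
#' @export
gv_params <- function(R0 = 10, a = 0.25, sigma_m = 40, sigma_c = 374,
                      K_m = 1e5, d = 10, eps_star = 0.5, tau_c = 1,
                      mu = 2.5e4) {
  p <- list(R0 = R0, a = a, sigma_m = sigma_m, sigma_c = sigma_c,
            K_m = K_m, d = d, eps_star = eps_star, tau_c = tau_c, mu = mu,
            sigma_0 = sigma_m + sigma_c)
  class(p) <- "gv_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every invariant of the model parameters and fails with a message
#' naming the violated constraint. Returns the parameters unchanged on
#' success.
#'
#' @param p a `gv_params` object (or bare named list with the same fields).
#' @return `p`, invisibly unchanged, with class `gv_params`.
#' @export
validate_params <- function(p) {
  fields <- c("R0", "a", "sigma_m", "sigma_c", "K_m", "d", "eps_star",
              "tau_c", "mu", "sigma_0")
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar")
  }
  pos <- setdiff(fields, "eps_star")
  for (f in pos)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be strictly positive")
  if (p$eps_star < 0) stop("eps_star must be >= 0")
  if (p$eps_star > 3)
    stop("eps_star must be <= 3 (300% strain; beyond modelled reservoirs)")
  if (p$a >= p$d) stop("invariant a < d violated (pore wider than patch)")
  if (p$a >= p$R0) stop("invariant a < R0 violated")
  if (p$d > p$R0 * sqrt(3))
    stop("invariant d <= R0*sqrt(3) violated (resting cell area A0 <= 0)")
  if (abs(p$sigma_0 - (p$sigma_m + p$sigma_c)) > 0)
    stop("sigma_0 must equal sigma_m + sigma_c exactly")
  p <- p[fields]
  class(p) <- "gv_params"
  invisible(p)
}

#' Reference parameter set
#'
#' The reference parameter values for a Schlemm's-canal endothelial cell:
#' `R0 = 10`, `a = 0.25`, `sigma_m = 40`, `sigma_c = 374`, `K_m = 1e5`,
#' `d = 10`, `eps_star = 0.5`, `tau_c = 1`, `mu = 2.5e4`
#' (um / pN / s unit system), whence `sigma_0 = 414` pN/um.
#'
#' @return a `gv_params` object.
#' @export
reference_params <- function() gv_params()

#' Perfusion protocol
#'
#' Describes the applied pressure drop `delta_p = p - P_e` across the cell
#' basal surface. All pressures are gauge pressures relative to the canal
#' pressure `P_e` (so `P_e = 0` internally). Two schedules are supported:
#' constant pressure for all `t >= 0`, and `"step_to_zero"` in which a
#' prepared state evolves with the pressure drop removed at `t = 0+`
#' (the collapse protocol).
#'
#' @param delta_p pressure drop in pN/um^2; give exactly one of `delta_p` or
#'   `delta_p_mmHg`.
#' @param delta_p_mmHg pressure drop in mmHg (converted on construction).
#' @param schedule `"constant"` or `"step_to_zero"`.
#' @param t_max simulation horizon, seconds.
#' @return an object of class `gv_protocol`.
#' @examples
#' gv_protocol(delta_p_mmHg = 30, t_max = 300)
#' @export
gv_protocol <- function(delta_p = NULL, delta_p_mmHg = NULL,
                        schedule = c("constant", "step_to_zero"),
                        t_max = 600) {
  schedule <- match.arg(schedule)
  if (is.null(delta_p) == is.null(delta_p_mmHg))
    stop("give exactly one of delta_p (pN/um^2) or delta_p_mmHg")
  if (is.null(delta_p)) delta_p <- mmHg_to_pN_um2(delta_p_mmHg)
  if (!is.numeric(delta_p) || length(delta_p) != 1L || !is.finite(delta_p))
    stop("delta_p must be a finite numeric scalar")
  if (delta_p < 0) stop("delta_p must be >= 0")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    stop("t_max must be > 0")
  structure(list(delta_p = delta_p,
                 delta_p_mmHg = pN_um2_to_mmHg(delta_p),
                 schedule = schedule, t_max = t_max),
            class = "gv_protocol")
}

# Pressure drop actually applied during integration under a protocol.
applied_delta_p <- function(protocol) {
  if (protocol$schedule == "step_to_zero") 0 else protocol$delta_p
}

#' @export
print.gv_params <- function(x, ...) {
  cat("Inverse-blebbing model parameters (um / s / pN units)\n")
  cat(sprintf("  R0 = %g um, a = %g um, d = %g um\n", x$R0, x$a, x$d))
  cat(sprintf("  sigma_m = %g, sigma_c = %g, sigma_0 = %g pN/um\n",
              x$sigma_m, x$sigma_c, x$sigma_0))
  cat(sprintf("  K_m = %g pN/um, eps* = %g, tau_c = %g s, mu = %g pN s/um^2\n",
              x$K_m, x$eps_star, x$tau_c, x$mu))
  invisible(x)
}

#' @export
print.gv_protocol <- function(x, ...) {
  cat(sprintf("Perfusion protocol: %s, delta_p = %.4g pN/um^2 (%.3g mmHg), t_max = %g s\n",
              x$schedule, x$delta_p, x$delta_p_mmHg, x$t_max))
  invisible(x)
}
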