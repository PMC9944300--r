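# Spherical-cap geometry of the inverse bleb. The cap radius r and opening
# angle theta (pi/2 <= theta <= pi) are tied to the basal pore half-width a
# by r*sin(theta) = a; at nucleation the bleb is the hemisphere r = a.

#' Opening angle of an inverse bleb
#'
#' Solves the pore constraint `r * sin(theta) = a` on the physical branch
#' `theta in [pi/2, pi]`: `theta = pi - asin(a / r)`. The bleb cannot be
#' smaller than the hemispherical nucleus, so `r >= a` is required.
#'
#' @param r cap radius, um (vectorised).
#' @param a basal pore half-width, um.
#' @return opening angle in radians.
#' @export
opening_angle <- function(r, a) {
  stopifnot(is.numeric(r), is.numeric(a), length(a) == 1L, a > 0)
  if (any(r < a * (1 - 1e-12)))
    stop("bleb radius r < pore half-width a: no spherical-cap solution")
  pi - asin(pmin(a / r, 1))
}

#' Spherical-cap volume and area
#'
#' Volume `(4*pi/3) * r^3 * (2 + cos(theta)) * sin(theta/2)^4` and lateral
#' area `2*pi*r^2*(1 - cos(theta))` of a spherical cap of radius `r`
#' subtending polar angle `theta` from its apex.
#'
#' @param r cap radius, um (vectorised).
#' @param theta opening angle, rad, in `[pi/2, pi]`.
#' @return volume in um^3 (`cap_volume`) or area in um^2 (`cap_area`).
#' @examples
#' cap_volume(1, pi)     # full sphere, 4*pi/3
#' cap_area(1, pi / 2)   # hemisphere, 2*pi
#' @export
cap_volume <- function(r, theta) {
  check_cap_args(r, theta)
  (4 * pi / 3) * r^3 * (2 + cos(theta)) * sin(theta / 2)^4
}

#' @rdname cap_volume
#' @export
cap_area <- function(r, theta) {
  check_cap_args(r, theta)
  2 * pi * r^2 * (1 - cos(theta))
}

check_cap_args <- function(r, theta) {
  stopifnot(is.numeric(r), is.numeric(theta))
  if (any(r < 0)) stop("cap radius must be >= 0")
  if (any(theta < pi / 2 - 1e-9 | theta > pi + 1e-9))
    stop("opening angle must lie in [pi/2, pi]")
  invisible(TRUE)
}

#' Cell radius from exact volume conservation
#'
#' There is no leakage of intracellular material, so the hemispherical cell
#' swells exactly by the volume of the invaginating caps:
#' `R^3 = R0^3 + sum_i 2 r_i^3 (2 + cos theta_i) sin(theta_i/2)^4`
#' (equivalently `(2*pi/3) R^3 = (2*pi/3) R0^3 + sum_i cap_volume_i`).
#' The volumetric contribution of the basal pore is neglected.
#'
#' @param r vector of bleb cap radii, um (may be empty).
#' @param a basal pore half-width, um.
#' @param R0 resting cell radius, um.
#' @return the cell radius R, um.
#' @export
cell_radius <- function(r, a, R0) {
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0)
  if (length(r) == 0L) return(R0)
  theta <- opening_angle(r, a)
  (R0^3 + sum(2 * r^3 * (2 + cos(theta)) * sin(theta / 2)^4))^(1 / 3)
}

#' Membrane patch area of one tension-equilibration patch
#'
#' The stretchable membrane associated with a patch of radius `d` carrying
#' `n` bleb caps: `S = sum_i 2 pi r_i^2 (1 - cos theta_i) + pi (d^2 - n a^2)`.
#' For a single bleb this is the usual `2 pi r^2 (1 - cos theta) +
#' pi (d^2 - a^2)`; the resting value is `S0 = pi d^2`.
#'
#' @param r vector of cap radii on this patch, um.
#' @param a pore half-width, um.
#' @param d patch radius, um.
#' @return patch area S in um^2.
#' @export
patch_area <- function(r, a, d) {
  n <- length(r)
  if (d^2 <= n * a^2)
    stop("patch geometrically infeasible: d^2 <= n * a^2 (", n,
         " pore footprints exceed the patch)")
  theta <- opening_angle(r, a)
  sum(cap_area(r, theta)) + pi * (d^2 - n * a^2)
}

# Cell area entering the cell strain, with k tension-equilibration patches
# excised: A = 3 pi R^2 - k pi d^2 (resting value at R = R0).
cell_area <- function(R, d, k = 1L) 3 * pi * R^2 - k * pi * d^2

#' Relative area strains
#'
#' The bleb strain `eps_B = (S - S0) / S0` with `S0 = pi d^2` and the cell
#' strain `eps_C = (A - A0) / A0` with `A0 = 3 pi R0^2 - k pi d^2` for `k`
#' tension-equilibration patches. Both regimes of the tension law are keyed
#' on these strains through the reservoir threshold `eps_star`.
#'
#' @param S patch area, um^2.
#' @param A cell area, um^2.
#' @param params a [gv_params()] object.
#' @param n_patches number of independent patches `k`.
#' @return named list with `eps_B` and `eps_C`.
#' @export
area_strains <- function(S, A, params, n_patches = 1L) {
  S0 <- pi * params$d^2
  A0 <- cell_area(params$R0, params$d, n_patches)
  if (A0 <= 0) stop("resting cell area A0 <= 0 for ", n_patches, " patches")
  list(eps_B = (S - S0) / S0, eps_C = (A - A0) / A0)
}
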