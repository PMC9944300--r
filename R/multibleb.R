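# Multiple vacuoles. Blebs nucleated farther apart than the
# tension-equilibration length d grow on independent membrane patches and
# behave exactly like single vacuoles; blebs nucleated closer share one
# patch, hence one stretchable-area budget and one target tension, which
# couples them and drives Ostwald-ripening competition once the shared
# reservoir is exhausted.

#' Simulate several inverse blebs
#'
#' Integrates the coupled radius + tension dynamics for `length(r0)` blebs.
#' With `shared = TRUE` all blebs live on one tension-equilibration patch:
#' they share the patch area `S = sum_i 2 pi r_i^2 (1 - cos theta_i) +
#' pi (d^2 - n a^2)` and therefore one target tension. With
#' `shared = FALSE` each bleb has its own patch and the dynamics decouple
#' (apart from the common cell). Volume conservation sums over all blebs.
#' A bleb whose radius falls to the pore half-width `a` collapses: it is
#' frozen at `r = a` and its cap is removed from the patch area and the
#' cell-volume budget; the survivors continue.
#'
#' @param params a [gv_params()] object.
#' @param protocol a [gv_protocol()] object.
#' @param r0 vector of initial radii, um.
#' @param Sigma0 initial tensions, pN/um (recycled).
#' @param shared do all blebs share one membrane patch?
#' @param ... passed to the integrator (`n_out`, `rtol`, `atol`).
#' @return a `gv_trajectory` with per-bleb columns `r_1, r_2, ...`.
#' @seealso [coarsening_summary()], [ripening_field()]
#' @export
gv_simulate_multi <- function(params, protocol, r0,
                              Sigma0 = params$sigma_m, shared = TRUE, ...) {
  stopifnot(length(r0) >= 1L)
  simulate_blebs(params, protocol, r0, Sigma0, shared = shared, ...)
}

#' Summarise a two-bleb coarsening run
#'
#' Reports the outcome of the vacuole competition: the number of surviving
#' (uncollapsed) blebs, the winner index (the surviving bleb, when exactly
#' one collapsed), and the symmetry-breaking time, defined as the first time
#' the relative radius difference `|r1 - r2| / max(r1, r2)` exceeds 10%.
#'
#' @param traj a two-bleb `gv_trajectory`.
#' @return a list with `survivors`, `winner` (index or `NA`),
#'   `symmetry_breaking_time_min` and `collapse_times_min`.
#' @export
coarsening_summary <- function(traj) {
  stopifnot(inherits(traj, "gv_trajectory"), traj$n_blebs == 2L)
  st <- traj$states
  coll <- traj$events[traj$events$kind == "collapsed", , drop = FALSE]
  survivors <- 2L - nrow(coll)
  winner <- if (nrow(coll) == 1L) setdiff(1:2, coll$bleb) else NA_integer_
  rel <- abs(st$r_1 - st$r_2) / pmax(st$r_1, st$r_2)
  sb <- which(rel > 0.10)[1]
  list(survivors = survivors, winner = winner,
       symmetry_breaking_time_min =
         if (is.na(sb)) NA_real_ else st$t[sb] / 60,
       collapse_times_min = coll$time / 60)
}

#' Quasi-static ripening field dr1/dt over (r1, r2)
#'
#' Evaluates the growth rate of bleb 1 on a grid of the two radii with both
#' tensions slaved to the shared-patch target (`Sigma_1 = Sigma_2 =
#' Sigma_bar(S)`, `sigma = sigma_bar`), the quasi-static limit used to read
#' off the Ostwald-ripening phase portrait. The field is antisymmetric
#' across the diagonal in the sense `dr1/dt(x, y) = dr2/dt(y, x)`.
#'
#' @param params a [gv_params()] object.
#' @param delta_p_mmHg pressure drop, mmHg.
#' @param r_grid vector of radii (um) used for both axes.
#' @return an object of class `gv_ripening`: list with `r_grid` and the
#'   matrix `drdt` (`drdt[i, j]` = dr1/dt at `r1 = r_grid[i]`,
#'   `r2 = r_grid[j]`, um/s).
#' @export
ripening_field <- function(params, delta_p_mmHg, r_grid) {
  params <- validate_params(params)
  stopifnot(all(r_grid >= params$a))
  delta_p <- mmHg_to_pN_um2(delta_p_mmHg)
  n <- length(r_grid)
  drdt <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ev <- sys_eval(c(r_grid[i], r_grid[j]), rep(params$sigma_0, 2), params,
                   delta_p = delta_p, shared = TRUE, active = c(TRUE, TRUE))
    Sigma_bar <- target_tension_capped(ev$S[1], pi * params$d^2, params)
    drdt[i, j] <- radius_rhs(r_grid[i], Sigma_bar, ev$P, delta_p, params)
  }
  structure(list(r_grid = r_grid, drdt = drdt,
                 delta_p_mmHg = delta_p_mmHg, params = params),
            class = "gv_ripening")
}

#' Shared-patch shift of nucleation threshold and vacuole size
#'
#' When two blebs share one tension-equilibration patch, each competes for
#' half the stored membrane: the nucleation threshold pressure rises and the
#' membrane-branch (maximal) vacuole size at a given pressure shrinks
#' relative to the single-vacuole case. This computes both, for the
#' symmetric two-bleb configuration.
#'
#' @param params a [gv_params()] object.
#' @param delta_p_mmHg pressure at which to compare equilibrium sizes, mmHg.
#' @return list with `delta_p_star_1_mmHg`, `delta_p_star_2_mmHg` (one- and
#'   two-bleb nucleation thresholds) and `r_eq_1`, `r_eq_2` (membrane-branch
#'   equilibrium radii, um; `NA` if none exists at that pressure).
#' @export
shared_patch_shift <- function(params, delta_p_mmHg = 7) {
  delta_p <- mmHg_to_pN_um2(delta_p_mmHg)
  mem_r <- function(n) {
    eq <- gv_equilibria(delta_p, params, n_blebs = n)
    mem <- eq[eq$branch == "membrane", , drop = FALSE]
    if (nrow(mem)) mem$r[1] else NA_real_
  }
  list(delta_p_star_1_mmHg = pN_um2_to_mmHg(nucleation_pressure(params, 1L)),
       delta_p_star_2_mmHg = pN_um2_to_mmHg(nucleation_pressure(params, 2L)),
       r_eq_1 = mem_r(1L), r_eq_2 = mem_r(2L))
}
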