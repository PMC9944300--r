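# Seeded multiplicative parameter perturbations (up to a fixed fraction,
# default 20%) emulating physiological tissue variability, and batch runs
# checking that the qualitative model behaviour survives it.

PERTURBABLE_FIELDS <- c("R0", "a", "sigma_m", "sigma_c", "K_m", "d",
                        "eps_star", "tau_c", "mu")

#' Specification of a parameter-perturbation ensemble
#'
#' @param base a [gv_params()] object: the reference point.
#' @param fields character vector of parameter names to perturb
#'   (any of `R0, a, sigma_m, sigma_c, K_m, d, eps_star, tau_c, mu`;
#'   the derived `sigma_0` is always recomputed).
#' @param fraction maximum relative perturbation; each chosen field is
#'   multiplied independently by a factor uniform on
#'   `[1 - fraction, 1 + fraction]`.
#' @param n_draws number of parameter sets to draw.
#' @param seed integer RNG seed; draws are fully reproducible given
#'   `(seed, spec)`.
#' @return an object of class `gv_ensemble_spec`.
#' @export
ensemble_spec <- function(base, fields = c("tau_c", "mu"), fraction = 0.20,
                          n_draws = 100L, seed = 1L) {
  base <- validate_params(base)
  bad <- setdiff(fields, PERTURBABLE_FIELDS)
  if (length(bad))
    stop("cannot perturb field(s): ", paste(bad, collapse = ", "))
  stopifnot(fraction > 0, fraction < 1, n_draws >= 1)
  structure(list(base = base, fields = fields, fraction = fraction,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "gv_ensemble_spec")
}

#' Draw perturbed parameter sets
#'
#' Each field listed in the spec is independently multiplied by a factor
#' uniform on `[1 - fraction, 1 + fraction]`; `sigma_0` is recomputed from
#' the perturbed `sigma_m + sigma_c`. Draws that fail [validate_params()]
#' are rejected and redrawn (the count is recorded in the `"rejected"`
#' attribute). Deterministic given the spec's seed.
#'
#' @param spec a [ensemble_spec()] object.
#' @return list of `n_draws` [gv_params()] objects, with attribute
#'   `"rejected"`.
#' @export
draw_params <- function(spec) {
  stopifnot(inherits(spec, "gv_ensemble_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rejected <- 0L
  draws <- vector("list", spec$n_draws)
  for (i in seq_len(spec$n_draws)) {
    repeat {
      fac <- stats::runif(length(spec$fields),
                          1 - spec$fraction, 1 + spec$fraction)
      p <- unclass(spec$base)
      p[spec$fields] <- mapply(`*`, p[spec$fields], fac)
      p$sigma_0 <- p$sigma_m + p$sigma_c
      ok <- tryCatch({validate_params(p); TRUE}, error = function(e) FALSE)
      if (ok) break
      rejected <- rejected + 1L
    }
    class(p) <- "gv_params"
    draws[[i]] <- p
  }
  attr(draws, "rejected") <- rejected
  draws
}

#' Dynamics ensemble: scenario classification under variability
#'
#' Runs [gv_simulate()] for every drawn parameter set under one protocol and
#' classifies each trajectory as `"shrink"` (collapsed to `r = a`),
#' `"grow-to-steady"` (reached within 1% of its own membrane-branch steady
#' radius) or `"not-converged"`. Used to check that the qualitative growth
#' scenario is robust to ~20% variability in the dynamical parameters.
#'
#' @param spec a [ensemble_spec()] object.
#' @param protocol a [gv_protocol()] object.
#' @param r0,Sigma0 initial condition (defaults: nucleation state).
#' @param ... passed to [gv_simulate()].
#' @return data frame of class `gv_dynamics_ensemble` with one row per draw
#'   (`draw`, `outcome`, `time_to_steady_min`) plus a `counts` attribute.
#' @export
dynamics_ensemble <- function(spec, protocol, r0 = spec$base$a,
                              Sigma0 = spec$base$sigma_m, ...) {
  draws <- draw_params(spec)
  rows <- lapply(seq_along(draws), function(i) {
    p <- draws[[i]]
    out <- tryCatch({
      traj <- gv_simulate(p, protocol, r0 = r0, Sigma0 = Sigma0, ...)
      if (any(traj$events$kind == "collapsed")) {
        list(outcome = "shrink", tts = NA_real_)
      } else {
        tts <- tryCatch(time_to_steady(traj), error = function(e)
          structure(NA_real_, reason = conditionMessage(e)))
        if (is.finite(tts)) list(outcome = "grow-to-steady", tts = as.numeric(tts))
        else list(outcome = "not-converged", tts = NA_real_)
      }
    }, error = function(e) list(outcome = "error", tts = NA_real_))
    data.frame(draw = i, outcome = out$outcome,
               time_to_steady_min = out$tts)
  })
  res <- do.call(rbind, rows)
  attr(res, "counts") <- table(res$outcome)
  class(res) <- c("gv_dynamics_ensemble", "data.frame")
  res
}

#' Steady-state ensemble: branch structure under variability
#'
#' For every drawn parameter set, computes the two threshold pressures and
#' counts equilibria at three probe pressures (below `delta_p*`, midway in
#' the bistable window, above `delta_p_dagger`), recording the count pattern
#' (reference behaviour `"0/2/1"`).
#'
#' @param spec a [ensemble_spec()] object.
#' @return data frame of class `gv_steady_ensemble` with per-draw
#'   `delta_p_star_mmHg`, `delta_p_dagger_mmHg` and `pattern`.
#' @export
steady_ensemble <- function(spec) {
  draws <- draw_params(spec)
  rows <- lapply(seq_along(draws), function(i) {
    p <- draws[[i]]
    star <- pN_um2_to_mmHg(nucleation_pressure(p))
    dagger <- pN_um2_to_mmHg(bistability_pressure(p))
    probes <- c(0.5 * star, (star + dagger) / 2, 1.2 * dagger)
    counts <- vapply(probes, function(dp)
      nrow(gv_equilibria(mmHg_to_pN_um2(dp), p)), integer(1))
    data.frame(draw = i, delta_p_star_mmHg = star,
               delta_p_dagger_mmHg = dagger,
               pattern = paste(counts, collapse = "/"))
  })
  res <- do.call(rbind, rows)
  attr(res, "counts") <- table(res$pattern)
  class(res) <- c("gv_steady_ensemble", "data.frame")
  res
}
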