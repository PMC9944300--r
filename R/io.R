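# JSON run configuration, CSV writers, and a reproducibility manifest.
# mmHg-valued keys carry the "_mmHg" suffix and are converted at load; all
# stored quantities are otherwise in the internal um / s / pN system.

CONFIG_TOP_KEYS <- c("params", "protocol", "init", "seed", "shared",
                     "delta_p", "delta_p_mmHg", "t_max", "package_version")
CONFIG_PROTOCOL_KEYS <- c("delta_p", "delta_p_mmHg", "schedule", "t_max")
CONFIG_INIT_KEYS <- c("r0", "Sigma0")

#' Load a run configuration
#'
#' Reads a JSON configuration (or a run manifest written by
#' [write_manifest()]) into a validated `gv_config`. Unknown keys are an
#' error, never silently ignored. Any missing parameter falls back to the
#' reference value, so a minimal config need only specify a pressure drop;
#' `delta_p_mmHg` may be given at top level as a shorthand for
#' `protocol$delta_p_mmHg`.
#'
#' @param path path to a JSON file.
#' @return an object of class `gv_config`: list with `params`
#'   ([gv_params()]), `protocol` ([gv_protocol()]), `init` (`r0`, `Sigma0`
#'   vectors), `shared` flag and `seed`.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(cfg, CONFIG_TOP_KEYS, "top level")

  pargs <- cfg$params
  if (!is.null(pargs)) {
    check_keys(pargs, PERTURBABLE_FIELDS, "params")
    params <- do.call(gv_params, pargs)
  } else params <- gv_params()

  prot <- if (!is.null(cfg$protocol)) cfg$protocol else list()
  check_keys(prot, CONFIG_PROTOCOL_KEYS, "protocol")
  for (k in c("delta_p", "delta_p_mmHg", "t_max"))
    if (!is.null(cfg[[k]]) && is.null(prot[[k]])) prot[[k]] <- cfg[[k]]
  if (is.null(prot$delta_p) && is.null(prot$delta_p_mmHg))
    stop("config must give a pressure drop (delta_p or delta_p_mmHg)")
  protocol <- do.call(gv_protocol, prot)

  init <- if (!is.null(cfg$init)) cfg$init else list()
  check_keys(init, CONFIG_INIT_KEYS, "init")
  r0 <- if (!is.null(init$r0)) init$r0 else params$a
  Sigma0 <- if (!is.null(init$Sigma0)) init$Sigma0 else params$sigma_m

  structure(list(params = params, protocol = protocol,
                 init = list(r0 = r0, Sigma0 = Sigma0),
                 shared = if (!is.null(cfg$shared)) isTRUE(cfg$shared) else TRUE,
                 seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L),
            class = "gv_config")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Write a trajectory as CSV
#'
#' One row per sampled time, with units fixed in the column names
#' (`t_s`, `r_um`, `theta_rad`, `Sigma_pN_per_um`, `R_um`,
#' `sigma_pN_per_um`, `P_pN_per_um2`, `eps_B`, `eps_C`, `regime`), preceded
#' by `#`-prefixed metadata lines (parameters and protocol as JSON).
#'
#' @param traj a `gv_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gv_trajectory"))
  st <- traj$states
  names(st) <- sub("^t$", "t_s", names(st))
  names(st) <- sub("^(r)(_\\d+)?$", "r\\2_um", names(st))
  names(st) <- sub("^(theta)(_\\d+)?$", "theta\\2_rad", names(st))
  names(st) <- sub("^(Sigma)(_\\d+)?$", "Sigma\\2_pN_per_um", names(st))
  names(st) <- sub("^R$", "R_um", names(st))
  names(st) <- sub("^sigma$", "sigma_pN_per_um", names(st))
  names(st) <- sub("^P$", "P_pN_per_um2", names(st))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# params: ",
                    jsonlite::toJSON(unclass(traj$params), auto_unbox = TRUE,
                                     digits = NA)), con)
  writeLines(paste0("# protocol: ",
                    jsonlite::toJSON(unclass(traj$protocol), auto_unbox = TRUE,
                                     digits = NA)), con)
  utils::write.csv(st, con, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON record of everything needed to reproduce a run bit-for-bit:
#' parameters, protocol, initial condition, patch sharing, seed and package
#' version. A manifest is itself a valid input to [load_config()].
#'
#' @param config a `gv_config` (or compatible list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  params <- unclass(config$params)
  params$sigma_0 <- NULL  # derived; recomputed on load
  manifest <- list(
    params = params,
    protocol = list(delta_p = config$protocol$delta_p,
                    schedule = config$protocol$schedule,
                    t_max = config$protocol$t_max),
    init = config$init,
    shared = config$shared,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gvbleb")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a loaded configuration
#'
#' Executes the simulation described by a `gv_config` (single- or
#' multi-bleb, depending on the length of `init$r0`).
#'
#' @param config a `gv_config` from [load_config()].
#' @param ... passed to the integrator.
#' @return a `gv_trajectory`.
#' @export
run_config <- function(config, ...) {
  stopifnot(inherits(config, "gv_config"))
  simulate_blebs(config$params, config$protocol, r0 = config$init$r0,
                 Sigma0 = config$init$Sigma0, shared = config$shared, ...)
}
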