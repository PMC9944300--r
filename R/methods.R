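# print / summary / plot methods for the classed results.

#' @export
print.gv_trajectory <- function(x, ...) {
  cat(sprintf("Inverse-bleb trajectory: %d bleb(s), %d samples over %.4g s\n",
              x$n_blebs, nrow(x$states), max(x$states$t)))
  print(x$protocol)
  if (nrow(x$events)) {
    cat("Events:\n")
    print(x$events, row.names = FALSE)
  } else cat("Events: none\n")
  invisible(x)
}

#' @export
summary.gv_trajectory <- function(object, ...) {
  st <- object$states
  rcols <- grep("^r(_\\d+)?$", names(st), value = TRUE)
  cat(sprintf("Trajectory over %.4g s (%.3g min), %d bleb(s)\n",
              max(st$t), max(st$t) / 60, object$n_blebs))
  for (rc in rcols)
    cat(sprintf("  %s: %.4g -> %.4g um (max %.4g)\n",
                rc, st[[rc]][1], st[[rc]][nrow(st)], max(st[[rc]])))
  cat(sprintf("  cell radius R: %.4g -> %.4g um\n", st$R[1], st$R[nrow(st)]))
  cat(sprintf("  volume-conservation residual (max relative): %.3g\n",
              max(volume_residual(object))))
  if (nrow(object$events)) {
    cat("Events:\n"); print(object$events, row.names = FALSE)
  }
  invisible(object)
}

#' Relative volume-conservation residual along a trajectory
#'
#' `|(2 pi/3) R^3 - sum_i cap_volume_i - (2 pi/3) R0^3| / ((2 pi/3) R0^3)`
#' at every sampled state, using only the caps of not-yet-collapsed blebs.
#'
#' @param traj a `gv_trajectory`.
#' @return numeric vector, one residual per sampled time.
#' @export
volume_residual <- function(traj) {
  st <- traj$states
  n <- traj$n_blebs
  a <- traj$params$a
  rcols <- if (n == 1L) "r" else paste0("r_", seq_len(n))
  coll <- traj$events[traj$events$kind == "collapsed", , drop = FALSE]
  hemi0 <- (2 * pi / 3) * traj$params$R0^3
  vapply(seq_len(nrow(st)), function(i) {
    caps <- 0
    for (j in seq_len(n)) {
      dead <- any(coll$bleb == j & st$t[i] > coll$time)
      if (!dead) {
        r <- max(st[[rcols[j]]][i], a)
        caps <- caps + cap_volume(r, opening_angle(r, a))
      }
    }
    abs((2 * pi / 3) * st$R[i]^3 - caps - hemi0) / hemi0
  }, numeric(1))
}

#' @export
plot.gv_trajectory <- function(x, ...) {
  st <- x$states
  rcols <- grep("^r(_\\d+)?$", names(st), value = TRUE)
  graphics::matplot(st$t / 60, st[rcols], type = "l", lty = 1,
                    xlab = "time (min)", ylab = "bleb radius r (um)",
                    main = sprintf("delta_p = %.3g mmHg",
                                   x$protocol$delta_p_mmHg), ...)
  if (length(rcols) > 1)
    graphics::legend("topleft", legend = rcols, lty = 1,
                     col = seq_along(rcols), bty = "n")
  invisible(x)
}

#' @export
print.gv_equilibria <- function(x, ...) {
  cat(sprintf("Steady-state configurations (%d found)\n", nrow(x)))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.gv_scan <- function(x, ...) {
  cat("Pressure scan of steady-state branch structure\n")
  cat(sprintf("  delta_p*      = %.4g mmHg (nucleation threshold)\n",
              x$delta_p_star_mmHg))
  cat(sprintf("  delta_p_dagger = %.4g mmHg (end of bistable window)\n",
              x$delta_p_dagger_mmHg))
  cat(sprintf("  equilibria per grid point: %s\n",
              paste(unique(x$counts), collapse = " / ")))
  invisible(x)
}

#' @export
plot.gv_scan <- function(x, log = "y", ...) {
  rec <- x$records
  if (!nrow(rec)) { warning("empty scan"); return(invisible(x)) }
  stab <- rec[which(rec$stable), ]
  unst <- rec[which(!rec$stable), ]
  graphics::plot(rec$delta_p_mmHg, rec$volume, type = "n", log = log,
                 xlab = "pressure drop (mmHg)",
                 ylab = "vacuole volume (um^3)", ...)
  graphics::points(stab$delta_p_mmHg, stab$volume, pch = 16)
  graphics::points(unst$delta_p_mmHg, unst$volume, pch = 1)
  graphics::abline(v = c(x$delta_p_star_mmHg, x$delta_p_dagger_mmHg),
                   lty = 3)
  graphics::legend("bottomright", pch = c(16, 1),
                   legend = c("stable (membrane branch)",
                              "unstable (cortex branch)"), bty = "n")
  invisible(x)
}

#' @export
plot.gv_ripening <- function(x, ...) {
  graphics::filled.contour(x$r_grid, x$r_grid, x$drdt,
                           xlab = "r1 (um)", ylab = "r2 (um)",
                           main = sprintf("dr1/dt (um/s) at %.3g mmHg",
                                          x$delta_p_mmHg), ...)
  invisible(x)
}
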