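# Internal unit system: micrometres, seconds, piconewtons.
# Tensions are pN/um, pressures pN/um^2 (numerically equal to Pa).
# mmHg appears only at the user/config boundary.

#' Pressure unit conversion
#'
#' The model works internally in pN/um^2 (numerically identical to Pa);
#' perfusion pressures are conventionally quoted in mmHg. One mmHg is
#' 133.322387415 Pa.
#'
#' @param p_mmHg,p pressure in mmHg, respectively pN/um^2. Vectorised.
#' @return the converted pressure.
#' @examples
#' mmHg_to_pN_um2(7)    # physiological pressure drop
#' pN_um2_to_mmHg(mmHg_to_pN_um2(30))
#' @export
mmHg_to_pN_um2 <- function(p_mmHg) {
  stopifnot(is.numeric(p_mmHg), all(is.finite(p_mmHg)))
  p_mmHg * 133.322387415
}

#' @rdname mmHg_to_pN_um2
#' @export
pN_um2_to_mmHg <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p / 133.322387415
}
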