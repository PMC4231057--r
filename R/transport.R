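#' Closed-form two-compartment tracer exchange
#'
#' Exact solution of conservative exchange between the luminal (donor) and
#' abluminal (receiver) compartments of a transwell across a barrier of
#' permeability-surface product `ps_total`:
#' \deqn{dC_r/dt = (PS/V_r)(C_d - C_r), \quad dC_d/dt = -(PS/V_d)(C_d - C_r).}
#' Total tracer mass \eqn{C_d V_d + C_r V_r} is conserved; the
#' concentration difference decays as \eqn{\exp(-PS(1/V_d + 1/V_r)\,t)}.
#'
#' @param design An [assay_design()] supplying the two volumes.
#' @param ps_total Barrier permeability-surface product, ul/min (>= 0).
#' @param t Time(s) since the start of the interval, min (vectorized).
#' @param donor_start Donor concentration at t = 0, ug/ml.
#' @param receiver_start Receiver concentration at t = 0, ug/ml
#'   (0 after transfer to a fresh well).
#' @return A list with numeric vectors `donor` and `receiver`, the
#'   concentrations at each requested time.
#' @examples
#' d <- assay_design()
#' two_compartment_solution(d, ps_total = 0.4, t = c(20, 40, 60),
#'                          donor_start = 10)
#' @export
two_compartment_solution <- function(design, ps_total, t, donor_start,
                                     receiver_start = 0) {
  stopifnot(inherits(design, "assay_design"),
            is.numeric(ps_total), length(ps_total) == 1,
            is.numeric(t), is.numeric(donor_start), length(donor_start) == 1,
            is.numeric(receiver_start), length(receiver_start) == 1)
  if (ps_total < 0) stop("`ps_total` must be >= 0")
  if (any(t < 0)) stop("`t` must be >= 0")
  if (donor_start < 0 || receiver_start < 0)
    stop("starting concentrations must be >= 0")
  vd <- design$luminal_volume
  vr <- design$abluminal_volume
  vtot <- vd + vr
  ceq <- (donor_start * vd + receiver_start * vr) / vtot
  d0 <- donor_start - receiver_start
  decay <- exp(-ps_total * (1 / vd + 1 / vr) * t)
  list(
    donor = ceq + d0 * decay * vr / vtot,
    receiver = ceq - d0 * decay * vd / vtot
  )
}

#' Convert a permeability coefficient to a permeability-surface product
#'
#' @param pe Permeability coefficient on the 10^-6 cm/s scale.
#' @param area Membrane area, cm2.
#' @return PS in ul/min (1e-6 cm/s x cm2 x 60 s/min x 1000 ul/cm3).
#' @export
pe_to_ps <- function(pe, area) pe * area * 0.06

#' Convert a permeability-surface product to a permeability coefficient
#'
#' Converts ul/min to cm3/s, divides by the membrane area and reports on
#' the 10^-6 cm/s scale; inverse of [pe_to_ps()].
#'
#' @param ps PS in ul/min.
#' @param area Membrane area, cm2.
#' @return Pe on the 10^-6 cm/s scale.
#' @export
ps_to_pe <- function(ps, area) {
  if (any(area <= 0)) stop("`area` must be > 0")
  ps / (0.06 * area)
}
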