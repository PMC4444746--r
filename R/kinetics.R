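#' Free (unbound) plasma concentration
#'
#' The concentration available to diffuse into saliva is the fraction not
#' bound to plasma proteins: `free = total * fraction_unbound_plasma`.
#'
#' @param total Total plasma concentration (any concentration unit).
#' @param compound A [compound()].
#' @return Free concentration, same units as `total`.
#' @export
free_concentration <- function(total, compound) {
  stopifnot(inherits(compound, "compound"), is.numeric(total))
  total * compound$fraction_unbound_plasma
}

#' Quasi-equilibrium saliva concentration from blood concentration
#'
#' `C_sal = C_bl * P_sal:bl` — saliva equilibrates with blood without lag,
#' so the saliva concentration tracks blood scaled by the partition
#' coefficient.
#'
#' @param blood_conc Blood (plasma) concentration.
#' @param P Saliva:blood partition coefficient (dimensionless), e.g. from
#'   [saliva_blood_partition()].
#' @return Saliva concentration, same units as `blood_conc`.
#' @export
saliva_concentration <- function(blood_conc, P) {
  stopifnot(is.numeric(blood_conc), is.numeric(P), all(P >= 0))
  blood_conc * P
}

#' Saturable (Michaelis-Menten) transport rate
#'
#' Carrier-mediated salivary influx: `Tr = Tmax * Cu / (Km + Cu)`, bounded
#' above by `Tmax`, linear (`~ Tmax/Km * Cu`) well below `Km`.
#'
#' @param Cu Unbound analyte concentration.
#' @param Tmax Maximum transport rate (amount/time), `> 0`.
#' @param Km Transport affinity constant (same concentration units as `Cu`),
#'   `> 0`.
#' @return Transport rate, same units as `Tmax`.
#' @export
michaelis_menten_rate <- function(Cu, Tmax, Km) {
  stopifnot(is.numeric(Cu), all(Cu >= 0), Tmax > 0, Km > 0)
  Tmax * Cu / (Km + Cu)
}

#' Cardiac output under isoflurane anesthesia
#'
#' Allometric cardiac output with the coefficient already reduced ~15% from
#' the standard awake value to reflect isoflurane anesthesia:
#' `QC = 15 * BW^0.75` (L/h, BW in kg). Provided as a physiology utility for
#' flow-limited whole-body models; the one-compartment blood/saliva driver
#' does not use it.
#'
#' @param body_weight Body weight, kg, `> 0`.
#' @return Cardiac output, L/h.
#' @examples
#' anesthetized_cardiac_output(0.25)  # rat, ~5.3 L/h
#' anesthetized_cardiac_output(70)    # human, ~363 L/h
#' @export
anesthetized_cardiac_output <- function(body_weight) {
  stopifnot(is.numeric(body_weight), all(body_weight > 0))
  15 * body_weight^0.75
}
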