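#' Bound:unbound binding strength from an unbound fraction
#'
#' Converts an unbound fraction `f_u = C_u / C_total` into the equivalent
#' bound:unbound concentration ratio `beta = (1 - f_u) / f_u`, the quantity
#' that scales linearly with binding-site (protein) concentration. The
#' inverse is `f_u = 1 / (1 + beta)`.
#'
#' @param f_u Unbound fraction in (0, 1]. `f_u = 0` (infinite binding) is
#'   rejected.
#' @return Dimensionless bound:unbound ratio `beta >= 0`.
#' @examples
#' binding_strength_from_unbound(0.015)  # ~65.7 for a 98.5%-bound compound
#' @export
binding_strength_from_unbound <- function(f_u) {
  if (any(!is.finite(f_u)) || any(f_u <= 0) || any(f_u > 1)) {
    stop("f_u must lie in (0, 1]; f_u = 0 implies infinite binding",
         call. = FALSE)
  }
  (1 - f_u) / f_u
}

# ionization-weighted membrane/protein affinity of the speciation mixture
.ionization_weight <- function(compound, pH) {
  f_n <- neutral_fraction(pH, compound)
  f_n + compound$alpha * (1 - f_n)
}

#' Unbound fraction of a compound in an arbitrary fluid
#'
#' The unbound fraction in a fluid is estimated relative to the measured
#' plasma value: the bound:unbound ratio in plasma is scaled by the ratio of
#' protein volume fractions (interstitial-type fluids resemble plasma with
#' less protein), plus a lipid partitioning term
#' `fraction_lipid * 10^logD(pH)` when the fluid carries lipid. Evaluating
#' with `fluid` equal to `plasma` returns exactly
#' `compound$fraction_unbound_plasma`.
#'
#' Optionally (`ionization_binding = TRUE`, off by default) the protein term
#' is further scaled by the ratio of ionization-weighted affinities
#' `E(pH) = f_n + alpha * (1 - f_n)` between the fluid and plasma, making
#' protein binding pH-sensitive.
#'
#' @param compound A [compound()].
#' @param fluid Target [fluid()].
#' @param plasma Reference plasma [fluid()] in which
#'   `fraction_unbound_plasma` was measured.
#' @param ionization_binding Logical; re-weight protein affinity by
#'   speciation at each fluid's pH. Default `FALSE`.
#' @return Unbound fraction in (0, 1].
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' pl <- fluid("rat plasma", 7.8, 0.915, 0.073)
#' sal <- fluid("rat saliva", 8.9, 0.98, 0.003)
#' unbound_fraction_in_fluid(tcpy, sal, pl)  # ~0.27: far less protein
#' @export
unbound_fraction_in_fluid <- function(compound, fluid, plasma,
                                      ionization_binding = FALSE) {
  stopifnot(inherits(compound, "compound"), inherits(fluid, "fluid"),
            inherits(plasma, "fluid"))
  f_u_p <- compound$fraction_unbound_plasma
  if (f_u_p >= 1) {
    beta_protein <- 0
  } else {
    if (plasma$fraction_protein <= 0) {
      stop("plasma fraction_protein is 0 but the compound is protein-bound ",
           "(f_u < 1): cannot scale binding to other fluids", call. = FALSE)
    }
    beta_protein <- binding_strength_from_unbound(f_u_p) *
      fluid$fraction_protein / plasma$fraction_protein
    if (ionization_binding) {
      beta_protein <- beta_protein *
        .ionization_weight(compound, fluid$pH) /
        .ionization_weight(compound, plasma$pH)
    }
  }
  beta_lipid <- fluid$fraction_lipid * 10^log_d(compound, fluid$pH)
  1 / (1 + beta_protein + beta_lipid)
}

#' Unbound-concentration ratio across a pH gradient (ion trapping)
#'
#' Ionized species permeate membranes far more slowly than the neutral form;
#' `alpha` (the ionized:neutral distribution-coefficient ratio) quantifies
#' the penalty. At steady state the permeation-weighted pool
#' `X = C_neutral + alpha * C_ionized` equilibrates across the membrane,
#' which gives the total-unbound concentration ratio
#' \deqn{U_{sal}/U_{pl} = \frac{(1+R_{sal})/(1+\alpha R_{sal})}
#'                             {(1+R_{pl})/(1+\alpha R_{pl})}}
#' with `R` the ionized:neutral ratio on each side. A weak acid accumulates
#' on the higher-pH side; at `alpha = 1` the ratio is 1 for any pH pair, and
#' as `alpha -> 0` it tends to the classical pH-partition
#' (Rasmussen) ratio `(1 + R_sal) / (1 + R_pl)`.
#'
#' @param compound A [compound()].
#' @param saliva,plasma [fluid()] objects on the two sides of the membrane.
#' @return Dimensionless unbound-concentration ratio saliva/plasma.
#' @examples
#' b <- compound("generic", "base", pKa = 7, logKow_neutral = 2,
#'               alpha = 0.001, fraction_unbound_plasma = 0.5)
#' unbound_trapping_ratio(b,
#'   fluid("human saliva", 6.7, 0.98, 0.003),
#'   fluid("plasma", 7.4, 0.915, 0.073))   # ~2.14: base trapped in acidic saliva
#' @export
unbound_trapping_ratio <- function(compound, saliva, plasma) {
  stopifnot(inherits(compound, "compound"), inherits(saliva, "fluid"),
            inherits(plasma, "fluid"))
  if (compound$ion_class == "neutral") return(1)
  a <- compound$alpha
  R_s <- ionized_to_neutral_ratio(saliva$pH, compound)
  R_p <- ionized_to_neutral_ratio(plasma$pH, compound)
  ((1 + R_s) / (1 + a * R_s)) / ((1 + R_p) / (1 + a * R_p))
}

#' Saliva:blood equilibrium partition coefficient (adapted Schmitt algorithm)
#'
#' Computes the equilibrium ratio of total analyte concentration in saliva
#' to that in plasma from (i) plasma protein binding, scaled to the saliva
#' protein content, (ii) pH-gradient ion trapping weighted by the
#' ionized-species permeation penalty `alpha`, and (iii) the saliva volume
#' fractions. For a cell-free saliva the result reduces to
#' \deqn{P_{sal:bl} = T \cdot \frac{f_u^p}{f_u^{sal}} \cdot F_{int}}
#' where `T` is the unbound trapping ratio. When `fraction_cells > 0` a
#' cellular term `F_cell * T_cell / f_u^cell` is added, evaluated with the
#' same unbound-fraction machinery on the cellular sub-fluid (`cell`
#' argument; defaults to the saliva composition itself).
#'
#' The saliva concentration then follows from the blood concentration as
#' `C_sal = C_bl * P` (see [saliva_concentration()]).
#'
#' @param compound A [compound()].
#' @param physiology A [species_physiology()] (or a list with `plasma` and
#'   `saliva` fluids).
#' @param cell Optional [fluid()] describing the cellular space when the
#'   saliva-side fluid has `fraction_cells > 0`.
#' @param ionization_binding Passed to [unbound_fraction_in_fluid()];
#'   default `FALSE`.
#' @param water_normalization Logical; when `TRUE`, concentrations are
#'   expressed per volume of fluid water rather than per volume of fluid,
#'   multiplying the result by the saliva:plasma water-fraction ratio.
#'   Default `FALSE`.
#' @return An object of class `"partition_result"`: a list with `p_sal_bl`,
#'   `f_u_plasma`, `f_u_saliva`, `trapping_ratio`, and a `diagnostics` list
#'   of intermediates.
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' rat <- species_physiology("rat",
#'   plasma = fluid("rat plasma", 7.8, 0.915, 0.073),
#'   saliva = fluid("rat saliva", 8.9, 0.98, 0.003))
#' saliva_blood_partition(tcpy, rat)  # P ~ 0.058
#' @export
saliva_blood_partition <- function(compound, physiology, cell = NULL,
                                   ionization_binding = FALSE,
                                   water_normalization = FALSE) {
  stopifnot(inherits(compound, "compound"))
  plasma <- physiology$plasma
  saliva <- physiology$saliva
  stopifnot(inherits(plasma, "fluid"), inherits(saliva, "fluid"))

  f_u_p   <- compound$fraction_unbound_plasma
  f_u_sal <- unbound_fraction_in_fluid(compound, saliva, plasma,
                                       ionization_binding)
  trap <- unbound_trapping_ratio(compound, saliva, plasma)

  interstitial_term <- saliva$fraction_interstitial * trap / f_u_sal

  cellular_term <- 0
  f_u_cell <- NA_real_
  trap_cell <- NA_real_
  if (saliva$fraction_cells > 0) {
    cell_fluid <- if (is.null(cell)) saliva else cell
    stopifnot(inherits(cell_fluid, "fluid"))
    f_u_cell <- unbound_fraction_in_fluid(compound, cell_fluid, plasma,
                                          ionization_binding)
    trap_cell <- unbound_trapping_ratio(compound, cell_fluid, plasma)
    cellular_term <- saliva$fraction_cells * trap_cell / f_u_cell
  }

  p <- f_u_p * (interstitial_term + cellular_term)
  if (water_normalization) {
    p <- p * saliva$fraction_water / plasma$fraction_water
  }

  structure(
    list(p_sal_bl = p, f_u_plasma = f_u_p, f_u_saliva = f_u_sal,
         trapping_ratio = trap,
         diagnostics = list(
           compound = compound$name,
           plasma = plasma$name, saliva = saliva$name,
           plasma_pH = plasma$pH, saliva_pH = saliva$pH,
           beta_plasma = (1 - f_u_p) / f_u_p,
           interstitial_term = interstitial_term,
           cellular_term = cellular_term,
           f_u_cell = f_u_cell, trapping_ratio_cell = trap_cell,
           ionization_binding = ionization_binding,
           water_normalization = water_normalization)),
    class = "partition_result"
  )
}

#' @rdname saliva_blood_partition
#' @param x A `partition_result`.
#' @param ... Unused.
#' @export
print.partition_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<partition_result> ", d$compound, ": ", d$saliva, " vs ", d$plasma,
      "\n", sep = "")
  cat("  P_sal:bl        ", format(x$p_sal_bl, digits = 4), "\n",
      "  f_u plasma      ", format(x$f_u_plasma, digits = 4), "\n",
      "  f_u saliva      ", format(x$f_u_saliva, digits = 4), "\n",
      "  trapping ratio  ", format(x$trapping_ratio, digits = 4),
      "  (pH ", d$plasma_pH, " -> ", d$saliva_pH, ")\n", sep = "")
  invisible(x)
}

#' @rdname saliva_blood_partition
#' @export
as.data.frame.partition_result <- function(x, ...) {
  data.frame(compound = x$diagnostics$compound,
             saliva = x$diagnostics$saliva,
             plasma = x$diagnostics$plasma,
             p_sal_bl = x$p_sal_bl,
             f_u_plasma = x$f_u_plasma,
             f_u_saliva = x$f_u_saliva,
             trapping_ratio = x$trapping_ratio,
             stringsAsFactors = FALSE)
}

#' Human-to-rat (or any cross-species) partition-coefficient ratio
#'
#' Ratio of saliva:blood partition coefficients between two physiologies for
#' the same compound — the quantity that drives cross-species extrapolation
#' of salivary biomonitoring. For a pKa near physiological pH the ratio can
#' reach ~3-fold between humans and rats (whose stimulated saliva is far
#' more alkaline); for pKa well away from both saliva pH values the species
#' are comparable.
#'
#' @param compound A [compound()].
#' @param numerator_physiology,denominator_physiology
#'   [species_physiology()] objects (conventionally human over rat).
#' @param ... Passed on to [saliva_blood_partition()].
#' @return Dimensionless ratio of partition coefficients.
#' @export
species_partition_ratio <- function(compound, numerator_physiology,
                                    denominator_physiology, ...) {
  p_num <- saliva_blood_partition(compound, numerator_physiology, ...)
  p_den <- saliva_blood_partition(compound, denominator_physiology, ...)
  p_num$p_sal_bl / p_den$p_sal_bl
}
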