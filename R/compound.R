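#' Define an ionizable (or neutral) compound
#'
#' A `compound` is an immutable physicochemical record of a monoprotic weak
#' acid, weak base, or neutral species: its ionization class and pKa, the
#' lipophilicity of the neutral species, the ionized:neutral affinity ratio
#' `alpha`, and its unbound fraction in plasma. These are the chemical inputs
#' to the saliva:blood partition algorithm and the salivary PK simulator.
#'
#' `alpha` is the ratio of the distribution coefficients of the ionized and
#' non-ionized forms. It stands in for the roughly thousand-fold lower
#' membrane permeation rate of the charged species: `alpha = 1` means ions
#' cross as readily as the neutral form, `alpha = 0.001` means a
#' thousand-fold penalty. The lipophilicity of the ionized species is always
#' the derived quantity `logKow_neutral + log10(alpha)` and is available as
#' `logkow_ionized()`.
#'
#' Only monoprotic ionization is supported: a vector of more than one pKa is
#' rejected rather than silently truncated, because the downstream
#' Henderson-Hasselbalch arithmetic is single-group.
#'
#' @param name Compound label.
#' @param ion_class One of `"acid"`, `"base"`, `"neutral"`.
#' @param pKa Acid dissociation constant, pH units. Must be absent (`NULL`)
#'   for `ion_class = "neutral"` and present (single finite value in
#'   \[0, 14\]) otherwise.
#' @param logKow_neutral log10 octanol-water partition coefficient of the
#'   neutral species.
#' @param alpha Ionized:neutral distribution-coefficient (affinity) ratio in
#'   (0, 1]. Ignored (treated as 1) for neutral compounds.
#' @param fraction_unbound_plasma Fraction of the compound not bound to
#'   plasma proteins, in (0, 1].
#'
#' @return An object of class `"compound"`.
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' logkow_ionized(tcpy)
#' @seealso [derive_alpha()], [saliva_blood_partition()]
#' @export
compound <- function(name, ion_class = c("acid", "base", "neutral"),
                     pKa = NULL, logKow_neutral = 0, alpha = 1,
                     fraction_unbound_plasma = 1) {
  ion_class <- match.arg(ion_class)
  stopifnot(is.character(name), length(name) == 1L)
  if (ion_class == "neutral") {
    if (!is.null(pKa)) {
      stop("a neutral-class compound must not carry a pKa", call. = FALSE)
    }
    alpha <- 1
  } else {
    if (is.null(pKa) || length(pKa) == 0L) {
      stop("ion_class '", ion_class, "' requires a pKa", call. = FALSE)
    }
    if (length(pKa) > 1L) {
      stop("polyprotic compounds are not supported: got ", length(pKa),
           " pKa values; supply a single (monoprotic) pKa", call. = FALSE)
    }
    if (!is.finite(pKa) || pKa < 0 || pKa > 14) {
      stop("pKa must be a finite value in [0, 14]", call. = FALSE)
    }
  }
  if (!is.finite(logKow_neutral)) {
    stop("logKow_neutral must be finite", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(fraction_unbound_plasma) || fraction_unbound_plasma <= 0 ||
      fraction_unbound_plasma > 1) {
    stop("fraction_unbound_plasma must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, ion_class = ion_class,
         pKa = if (ion_class == "neutral") NULL else as.numeric(pKa),
         logKow_neutral = as.numeric(logKow_neutral),
         alpha = as.numeric(alpha),
         fraction_unbound_plasma = as.numeric(fraction_unbound_plasma)),
    class = "compound"
  )
}

#' @rdname compound
#' @param x,object A `compound`.
#' @param ... Unused.
#' @export
print.compound <- function(x, ...) {
  cat("<compound> ", x$name, " (", x$ion_class, ")\n", sep = "")
  if (!is.null(x$pKa)) cat("  pKa:            ", format(x$pKa), "\n", sep = "")
  cat("  logKow neutral: ", format(x$logKow_neutral), "\n",
      "  alpha:          ", format(x$alpha),
      "  (logKow ionized ", format(logkow_ionized(x)), ")\n",
      "  f_u plasma:     ", format(x$fraction_unbound_plasma), "\n", sep = "")
  invisible(x)
}

#' @rdname compound
#' @export
logkow_ionized <- function(object) {
  stopifnot(inherits(object, "compound"))
  object$logKow_neutral + log10(object$alpha)
}

.check_pH <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH))) {
    stop("pH must be finite numeric", call. = FALSE)
  }
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]", call. = FALSE)
  pH
}

#' Ionized:neutral concentration ratio at a given pH
#'
#' Henderson-Hasselbalch speciation for a monoprotic group: for an acid
#' `R = 10^(pH - pKa)`, for a base `R = 10^(pKa - pH)`; a neutral compound
#' returns 0 (no ionized species).
#'
#' @param pH pH of the medium, in \[0, 14\]. Vectorized.
#' @param compound A [compound()].
#' @return Dimensionless ratio of ionized to neutral concentrations.
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' ionized_to_neutral_ratio(7.8, tcpy)  # 10^3.25
#' @export
ionized_to_neutral_ratio <- function(pH, compound) {
  stopifnot(inherits(compound, "compound"))
  .check_pH(pH)
  switch(compound$ion_class,
         acid    = 10^(pH - compound$pKa),
         base    = 10^(compound$pKa - pH),
         neutral = rep(0, length(pH)))
}

#' Neutral (non-ionized) fraction at a given pH
#'
#' `f_n = 1 / (1 + R)` with `R` the ionized:neutral ratio; 1 for a
#' neutral-class compound. Strictly decreasing in pH for acids, increasing
#' for bases.
#'
#' @inheritParams ionized_to_neutral_ratio
#' @return Fraction in (0, 1].
#' @export
neutral_fraction <- function(pH, compound) {
  1 / (1 + ionized_to_neutral_ratio(pH, compound))
}

#' pH-dependent distribution coefficient (logD)
#'
#' Speciation-weighted lipophilicity: the neutral species contributes
#' `10^logKow_neutral`, the ionized species `alpha * 10^logKow_neutral`
#' (i.e. `10^logKow_ionized`), mixed by the neutral fraction at the given
#' pH. Bounded between `logKow_ionized` and `logKow_neutral`.
#'
#' @inheritParams ionized_to_neutral_ratio
#' @return log10 distribution coefficient.
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' log_d(tcpy, 3)   # ~3.19: pH 3 is nearly all-neutral for a pKa 4.55 acid
#' log_d(tcpy, 7)   # approaches logKow_ionized as ionization dominates
#' @export
log_d <- function(compound, pH) {
  f_n <- neutral_fraction(pH, compound)
  compound$logKow_neutral +
    log10(f_n + (1 - f_n) * compound$alpha)
}

#' Derive the ionized:neutral affinity ratio from two logD measurements
#'
#' Given the distribution coefficient measured at a pH where the neutral
#' form dominates and at a pH where the ionized form dominates,
#' `alpha = 10^(logD_ionized_pH - logD_neutral_pH)`. The residual neutral
#' fraction at the ionized-side pH is deliberately ignored: the simple
#' quotient is the field convention for tabulated two-pH lipophilicity data.
#'
#' @param logD_neutral_pH logD measured at the neutral-dominant pH
#'   (effectively logKow of the neutral species).
#' @param logD_ionized_pH logD measured at the ionized-dominant pH. Must not
#'   exceed `logD_neutral_pH` (ions are never more lipophilic than the
#'   neutral form).
#' @return `alpha` in (0, 1].
#' @examples
#' derive_alpha(3.2, 1.3)  # 10^-1.9 = 0.0126, i.e. ~0.013
#' @export
derive_alpha <- function(logD_neutral_pH, logD_ionized_pH) {
  if (!is.finite(logD_neutral_pH) || !is.finite(logD_ionized_pH)) {
    stop("logD inputs must be finite", call. = FALSE)
  }
  if (logD_ionized_pH > logD_neutral_pH) {
    stop("logD at the ionized-dominant pH (", logD_ionized_pH,
         ") exceeds logD at the neutral-dominant pH (", logD_neutral_pH,
         "); the ionized species cannot be the more lipophilic one",
         call. = FALSE)
  }
  10^(logD_ionized_pH - logD_neutral_pH)
}
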